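# Hand-curated SMILES template pools for the synthetic fixture generator.
#
# Family A: ortho donor/acceptor scaffolds (salicylaldehyde-, salicylamide-
# and salicylate-like, with enumerated ring substituents) whose default-seed
# conformer shows at least one intramolecular hydrogen-bond triple at the
# 3.0 Angstrom threshold.
# Family B: matched scaffolds carrying no N-H/O-H/S-H donor at all (O- and
# N-methylated analogues), so they can never produce a triple.
# Every member was verified to parse and embed at the default seed.

# donor scaffolds with a verified intramolecular H-bond
.FAMILY_A <- c(
  "O=Cc1ccc(F)cc1O",
  "O=Cc1ccc(Cl)cc1O",
  "O=Cc1ccc(Br)cc1O",
  "O=Cc1ccc(CCC)cc1O",
  "O=Cc1ccc(C(C)C)cc1O",
  "O=Cc1ccc(C(C)(C)C)cc1O",
  "O=Cc1ccc(OC)cc1O",
  "O=Cc1ccc(OCC)cc1O",
  "O=Cc1ccc(OC(C)C)cc1O",
  "O=Cc1ccc(C(F)(F)F)cc1O",
  "NC(=O)c1ccccc1O",
  "NC(=O)c1ccc(F)cc1O",
  "NC(=O)c1ccc(Cl)cc1O",
  "NC(=O)c1ccc(Br)cc1O",
  "NC(=O)c1ccc(CC)cc1O",
  "NC(=O)c1ccc(CCC)cc1O",
  "NC(=O)c1ccc(C(C)C)cc1O",
  "NC(=O)c1ccc(CCCC)cc1O",
  "NC(=O)c1ccc(C(C)(C)C)cc1O",
  "NC(=O)c1ccc(OC)cc1O",
  "NC(=O)c1ccc(OCC)cc1O",
  "NC(=O)c1ccc(OC(C)C)cc1O",
  "NC(=O)c1ccc(C(F)(F)F)cc1O",
  "COC(=O)c1ccccc1O",
  "COC(=O)c1ccc(F)cc1O",
  "COC(=O)c1ccc(Cl)cc1O",
  "COC(=O)c1ccc(Br)cc1O",
  "COC(=O)c1ccc(C)cc1O",
  "COC(=O)c1ccc(CC)cc1O",
  "COC(=O)c1ccc(CCC)cc1O",
  "COC(=O)c1ccc(C(C)C)cc1O",
  "COC(=O)c1ccc(CCCC)cc1O",
  "COC(=O)c1ccc(OC)cc1O",
  "COC(=O)c1ccc(C(F)(F)F)cc1O",
  "COC(=O)c1ccc(CCl)cc1O",
  "CNC(=O)c1ccccc1O",
  "CNC(=O)c1ccc(F)cc1O",
  "CNC(=O)c1ccc(Cl)cc1O",
  "CNC(=O)c1ccc(Br)cc1O",
  "CNC(=O)c1ccc(C)cc1O",
  "CNC(=O)c1ccc(CC)cc1O",
  "CNC(=O)c1ccc(CCC)cc1O",
  "CNC(=O)c1ccc(C(C)C)cc1O",
  "CNC(=O)c1ccc(CCCC)cc1O",
  "CNC(=O)c1ccc(C(C)(C)C)cc1O",
  "CNC(=O)c1ccc(OC)cc1O",
  "CNC(=O)c1ccc(OCC)cc1O",
  "CNC(=O)c1ccc(OC(C)C)cc1O",
  "CNC(=O)c1ccc(C(F)(F)F)cc1O",
  "CNC(=O)c1ccc(CCl)cc1O",
  "O=Cc1cc(F)ccc1O",
  "O=Cc1cc(Cl)ccc1O",
  "O=Cc1cc(Br)ccc1O",
  "O=Cc1cc(CC)ccc1O",
  "O=Cc1cc(CCC)ccc1O",
  "O=Cc1cc(C(C)C)ccc1O",
  "O=Cc1cc(C(C)(C)C)ccc1O",
  "O=Cc1cc(OC(C)C)ccc1O",
  "O=Cc1cc(CCl)ccc1O",
  "NC(=O)c1cc(F)ccc1O",
  "NC(=O)c1cc(Cl)ccc1O",
  "NC(=O)c1cc(Br)ccc1O",
  "NC(=O)c1cc(C)ccc1O",
  "NC(=O)c1cc(CC)ccc1O",
  "NC(=O)c1cc(CCC)ccc1O",
  "NC(=O)c1cc(C(C)C)ccc1O",
  "NC(=O)c1cc(CCCC)ccc1O",
  "NC(=O)c1cc(C(C)(C)C)ccc1O",
  "NC(=O)c1cc(OC)ccc1O",
  "NC(=O)c1cc(OCC)ccc1O",
  "NC(=O)c1cc(OC(C)C)ccc1O",
  "NC(=O)c1cc(C(F)(F)F)ccc1O",
  "NC(=O)c1cc(CCl)ccc1O",
  "COC(=O)c1cc(F)ccc1O",
  "COC(=O)c1cc(Cl)ccc1O",
  "COC(=O)c1cc(Br)ccc1O",
  "COC(=O)c1cc(C)ccc1O",
  "COC(=O)c1cc(CC)ccc1O",
  "COC(=O)c1cc(C(C)(C)C)ccc1O",
  "COC(=O)c1cc(OC)ccc1O",
  "COC(=O)c1cc(OC(C)C)ccc1O",
  "COC(=O)c1cc(C(F)(F)F)ccc1O",
  "CNC(=O)c1cc(C)ccc1O",
  "CNC(=O)c1cc(CC)ccc1O",
  "CNC(=O)c1cc(C(C)C)ccc1O",
  "CNC(=O)c1cc(CCCC)ccc1O",
  "CNC(=O)c1cc(C(C)(C)C)ccc1O",
  "CNC(=O)c1cc(OC)ccc1O",
  "CNC(=O)c1cc(OCC)ccc1O",
  "CNC(=O)c1cc(OC(C)C)ccc1O",
  "CNC(=O)c1cc(C(F)(F)F)ccc1O",
  "CNC(=O)c1cc(CCl)ccc1O",
  "CCOC(=O)c1ccccc1O",
  "CCOC(=O)c1ccc(Br)cc1O",
  "CCOC(=O)c1ccc(C)cc1O",
  "CCOC(=O)c1ccc(CCC)cc1O",
  "CCOC(=O)c1ccc(CCCC)cc1O",
  "CCOC(=O)c1ccc(C(C)(C)C)cc1O",
  "CCOC(=O)c1ccc(OC)cc1O",
  "CCOC(=O)c1ccc(OC(C)C)cc1O",
  "CCOC(=O)c1ccc(CCl)cc1O",
  "CCNC(=O)c1ccccc1O",
  "CCNC(=O)c1ccc(F)cc1O",
  "CCNC(=O)c1ccc(Cl)cc1O",
  "CCNC(=O)c1ccc(C)cc1O",
  "CCNC(=O)c1ccc(CC)cc1O",
  "CCNC(=O)c1ccc(CCC)cc1O",
  "CCNC(=O)c1ccc(C(C)C)cc1O",
  "CCNC(=O)c1ccc(CCCC)cc1O",
  "CCNC(=O)c1ccc(C(C)(C)C)cc1O",
  "CCNC(=O)c1ccc(OC)cc1O",
  "CCNC(=O)c1ccc(OCC)cc1O",
  "CCNC(=O)c1ccc(OC(C)C)cc1O",
  "CCNC(=O)c1ccc(C(F)(F)F)cc1O",
  "CCNC(=O)c1ccc(CCl)cc1O",
  "CCOC(=O)c1cc(F)ccc1O",
  "CCOC(=O)c1cc(Cl)ccc1O",
  "CCOC(=O)c1cc(Br)ccc1O",
  "CCOC(=O)c1cc(C)ccc1O",
  "CCOC(=O)c1cc(CC)ccc1O",
  "CCOC(=O)c1cc(CCC)ccc1O",
  "CCOC(=O)c1cc(C(C)C)ccc1O",
  "CCOC(=O)c1cc(C(C)(C)C)ccc1O",
  "CCOC(=O)c1cc(OC)ccc1O",
  "CCOC(=O)c1cc(OCC)ccc1O",
  "CCOC(=O)c1cc(CCl)ccc1O",
  "CCNC(=O)c1cc(F)ccc1O",
  "CCNC(=O)c1cc(Cl)ccc1O",
  "CCNC(=O)c1cc(Br)ccc1O",
  "CCNC(=O)c1cc(C)ccc1O",
  "CCNC(=O)c1cc(CC)ccc1O",
  "CCNC(=O)c1cc(CCC)ccc1O",
  "CCNC(=O)c1cc(C(C)C)ccc1O",
  "CCNC(=O)c1cc(CCCC)ccc1O",
  "CCNC(=O)c1cc(C(C)(C)C)ccc1O",
  "CCNC(=O)c1cc(OC)ccc1O",
  "CCNC(=O)c1cc(OCC)ccc1O",
  "CCNC(=O)c1cc(C(F)(F)F)ccc1O",
  "CCNC(=O)c1cc(CCl)ccc1O")

# donor-free analogues (zero triples by construction)
.FAMILY_B <- c(
  "O=Cc1ccccc1OC",
  "O=Cc1ccc(F)cc1OC",
  "O=Cc1ccc(Cl)cc1OC",
  "O=Cc1ccc(Br)cc1OC",
  "O=Cc1ccc(C)cc1OC",
  "O=Cc1ccc(CC)cc1OC",
  "O=Cc1ccc(CCC)cc1OC",
  "O=Cc1ccc(C(C)C)cc1OC",
  "O=Cc1ccc(CCCC)cc1OC",
  "O=Cc1ccc(C(C)(C)C)cc1OC",
  "O=Cc1ccc(OC)cc1OC",
  "O=Cc1ccc(OCC)cc1OC",
  "O=Cc1ccc(OC(C)C)cc1OC",
  "O=Cc1ccc(C(F)(F)F)cc1OC",
  "O=Cc1ccc(CCl)cc1OC",
  "CN(C)C(=O)c1ccccc1OC",
  "CN(C)C(=O)c1ccc(F)cc1OC",
  "CN(C)C(=O)c1ccc(Cl)cc1OC",
  "CN(C)C(=O)c1ccc(Br)cc1OC",
  "CN(C)C(=O)c1ccc(C)cc1OC",
  "CN(C)C(=O)c1ccc(CC)cc1OC",
  "CN(C)C(=O)c1ccc(CCC)cc1OC",
  "CN(C)C(=O)c1ccc(C(C)C)cc1OC",
  "CN(C)C(=O)c1ccc(CCCC)cc1OC",
  "CN(C)C(=O)c1ccc(C(C)(C)C)cc1OC",
  "CN(C)C(=O)c1ccc(OC)cc1OC",
  "CN(C)C(=O)c1ccc(OCC)cc1OC",
  "CN(C)C(=O)c1ccc(OC(C)C)cc1OC",
  "CN(C)C(=O)c1ccc(C(F)(F)F)cc1OC",
  "CN(C)C(=O)c1ccc(CCl)cc1OC",
  "COC(=O)c1ccccc1OC",
  "COC(=O)c1ccc(F)cc1OC",
  "COC(=O)c1ccc(Cl)cc1OC",
  "COC(=O)c1ccc(Br)cc1OC",
  "COC(=O)c1ccc(C)cc1OC",
  "COC(=O)c1ccc(CC)cc1OC",
  "COC(=O)c1ccc(CCC)cc1OC",
  "COC(=O)c1ccc(C(C)C)cc1OC",
  "COC(=O)c1ccc(CCCC)cc1OC",
  "COC(=O)c1ccc(C(C)(C)C)cc1OC",
  "COC(=O)c1ccc(OC)cc1OC",
  "COC(=O)c1ccc(OCC)cc1OC",
  "COC(=O)c1ccc(OC(C)C)cc1OC",
  "COC(=O)c1ccc(C(F)(F)F)cc1OC",
  "COC(=O)c1ccc(CCl)cc1OC",
  "CC(=O)c1ccccc1OC",
  "CC(=O)c1ccc(F)cc1OC",
  "CC(=O)c1ccc(Cl)cc1OC",
  "CC(=O)c1ccc(Br)cc1OC",
  "CC(=O)c1ccc(C)cc1OC",
  "CC(=O)c1ccc(CC)cc1OC",
  "CC(=O)c1ccc(CCC)cc1OC",
  "CC(=O)c1ccc(C(C)C)cc1OC",
  "CC(=O)c1ccc(CCCC)cc1OC",
  "CC(=O)c1ccc(C(C)(C)C)cc1OC",
  "CC(=O)c1ccc(OC)cc1OC",
  "CC(=O)c1ccc(OCC)cc1OC",
  "CC(=O)c1ccc(OC(C)C)cc1OC",
  "CC(=O)c1ccc(C(F)(F)F)cc1OC",
  "CC(=O)c1ccc(CCl)cc1OC",
  "O=Cc1cc(F)ccc1OC",
  "O=Cc1cc(Cl)ccc1OC",
  "O=Cc1cc(Br)ccc1OC",
  "O=Cc1cc(C)ccc1OC",
  "O=Cc1cc(CC)ccc1OC",
  "O=Cc1cc(CCC)ccc1OC",
  "O=Cc1cc(C(C)C)ccc1OC",
  "O=Cc1cc(CCCC)ccc1OC",
  "O=Cc1cc(C(C)(C)C)ccc1OC",
  "O=Cc1cc(OC)ccc1OC",
  "O=Cc1cc(OCC)ccc1OC",
  "O=Cc1cc(OC(C)C)ccc1OC",
  "O=Cc1cc(C(F)(F)F)ccc1OC",
  "O=Cc1cc(CCl)ccc1OC",
  "CN(C)C(=O)c1cc(F)ccc1OC",
  "CN(C)C(=O)c1cc(Cl)ccc1OC",
  "CN(C)C(=O)c1cc(Br)ccc1OC",
  "CN(C)C(=O)c1cc(C)ccc1OC",
  "CN(C)C(=O)c1cc(CC)ccc1OC",
  "CN(C)C(=O)c1cc(CCC)ccc1OC",
  "CN(C)C(=O)c1cc(C(C)C)ccc1OC",
  "CN(C)C(=O)c1cc(CCCC)ccc1OC",
  "CN(C)C(=O)c1cc(C(C)(C)C)ccc1OC",
  "CN(C)C(=O)c1cc(OC)ccc1OC",
  "CN(C)C(=O)c1cc(OCC)ccc1OC",
  "CN(C)C(=O)c1cc(OC(C)C)ccc1OC",
  "CN(C)C(=O)c1cc(C(F)(F)F)ccc1OC",
  "CN(C)C(=O)c1cc(CCl)ccc1OC",
  "COC(=O)c1cc(F)ccc1OC",
  "COC(=O)c1cc(Cl)ccc1OC",
  "COC(=O)c1cc(Br)ccc1OC",
  "COC(=O)c1cc(C)ccc1OC",
  "COC(=O)c1cc(CC)ccc1OC",
  "COC(=O)c1cc(CCC)ccc1OC",
  "COC(=O)c1cc(C(C)C)ccc1OC",
  "COC(=O)c1cc(CCCC)ccc1OC",
  "COC(=O)c1cc(C(C)(C)C)ccc1OC",
  "COC(=O)c1cc(OC)ccc1OC",
  "COC(=O)c1cc(OCC)ccc1OC",
  "COC(=O)c1cc(OC(C)C)ccc1OC",
  "COC(=O)c1cc(C(F)(F)F)ccc1OC",
  "COC(=O)c1cc(CCl)ccc1OC",
  "CC(=O)c1cc(F)ccc1OC",
  "CC(=O)c1cc(Cl)ccc1OC",
  "CC(=O)c1cc(Br)ccc1OC",
  "CC(=O)c1cc(C)ccc1OC",
  "CC(=O)c1cc(CC)ccc1OC",
  "CC(=O)c1cc(CCC)ccc1OC",
  "CC(=O)c1cc(C(C)C)ccc1OC",
  "CC(=O)c1cc(CCCC)ccc1OC",
  "CC(=O)c1cc(C(C)(C)C)ccc1OC",
  "CC(=O)c1cc(OC)ccc1OC",
  "CC(=O)c1cc(OCC)ccc1OC",
  "CC(=O)c1cc(OC(C)C)ccc1OC",
  "CC(=O)c1cc(C(F)(F)F)ccc1OC",
  "CC(=O)c1cc(CCl)ccc1OC",
  "CCOC(=O)c1ccccc1OC",
  "CCOC(=O)c1ccc(F)cc1OC",
  "CCOC(=O)c1ccc(Cl)cc1OC",
  "CCOC(=O)c1ccc(Br)cc1OC",
  "CCOC(=O)c1ccc(C)cc1OC",
  "CCOC(=O)c1ccc(CC)cc1OC",
  "CCOC(=O)c1ccc(CCC)cc1OC",
  "CCOC(=O)c1ccc(C(C)C)cc1OC",
  "CCOC(=O)c1ccc(CCCC)cc1OC",
  "CCOC(=O)c1ccc(C(C)(C)C)cc1OC",
  "CCOC(=O)c1ccc(OC)cc1OC",
  "CCOC(=O)c1ccc(OCC)cc1OC",
  "CCOC(=O)c1ccc(OC(C)C)cc1OC",
  "CCOC(=O)c1ccc(C(F)(F)F)cc1OC",
  "CCOC(=O)c1ccc(CCl)cc1OC",
  "CCOC(=O)c1cc(F)ccc1OC",
  "CCOC(=O)c1cc(Cl)ccc1OC",
  "CCOC(=O)c1cc(Br)ccc1OC",
  "CCOC(=O)c1cc(C)ccc1OC",
  "CCOC(=O)c1cc(CC)ccc1OC",
  "CCOC(=O)c1cc(CCC)ccc1OC",
  "CCOC(=O)c1cc(C(C)C)ccc1OC",
  "CCOC(=O)c1cc(CCCC)ccc1OC",
  "CCOC(=O)c1cc(C(C)(C)C)ccc1OC",
  "CCOC(=O)c1cc(OC)ccc1OC",
  "CCOC(=O)c1cc(OCC)ccc1OC",
  "CCOC(=O)c1cc(OC(C)C)ccc1OC",
  "CCOC(=O)c1cc(C(F)(F)F)ccc1OC",
  "CCOC(=O)c1cc(CCl)ccc1OC",
  "CC(=O)c1ccccc1C",
  "CC(=O)c1ccc(F)cc1C",
  "CC(=O)c1ccc(Cl)cc1C",
  "CC(=O)c1ccc(Br)cc1C",
  "CC(=O)c1ccc(C)cc1C",
  "CC(=O)c1ccc(CC)cc1C",
  "CC(=O)c1ccc(CCC)cc1C",
  "CC(=O)c1ccc(C(C)C)cc1C",
  "CC(=O)c1ccc(CCCC)cc1C",
  "CC(=O)c1ccc(C(C)(C)C)cc1C",
  "CC(=O)c1ccc(OC)cc1C",
  "CC(=O)c1ccc(OCC)cc1C",
  "CC(=O)c1ccc(OC(C)C)cc1C",
  "CC(=O)c1ccc(C(F)(F)F)cc1C",
  "CC(=O)c1ccc(CCl)cc1C",
  "CC(=O)c1cc(F)ccc1C",
  "CC(=O)c1cc(Cl)ccc1C",
  "CC(=O)c1cc(Br)ccc1C",
  "CC(=O)c1cc(C)ccc1C",
  "CC(=O)c1cc(CC)ccc1C",
  "CC(=O)c1cc(CCC)ccc1C",
  "CC(=O)c1cc(C(C)C)ccc1C",
  "CC(=O)c1cc(CCCC)ccc1C",
  "CC(=O)c1cc(C(C)(C)C)ccc1C",
  "CC(=O)c1cc(OC)ccc1C",
  "CC(=O)c1cc(OCC)ccc1C",
  "CC(=O)c1cc(OC(C)C)ccc1C",
  "CC(=O)c1cc(C(F)(F)F)ccc1C",
  "CC(=O)c1cc(CCl)ccc1C")
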