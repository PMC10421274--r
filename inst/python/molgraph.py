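"""RDKit helper for the mathqsar R package.

Reads one JSON request from stdin and writes one JSON response to stdout.
Request:
  {"mode": "parse" | "embed" | "canon",
   "smiles": ["CCO", ...],
   "seed": 42,               # embed only
   "max_attempts": 5}        # embed only

Per-molecule response fields (all modes): ok, error, error_type.
parse/embed: canonical_smiles, atoms {element, charge, degree, aromatic,
  in_ring, num_hs}, bonds (1-based heavy-atom index pairs).
embed adds: embedded (bool), coords (all atoms incl. explicit H, Angstrom),
  elements_full, heavy_map (1-based positions of heavy atoms in coords),
  seed_used.
canon: canonical_smiles of the largest fragment (heavy-atom count, ties by
  molecular weight then lexicographic canonical SMILES), n_fragments,
  heavy_atoms, canonical_full (whole input molecule).

Heavy atoms are renumbered by RDKit canonical rank before anything else, so
descriptor matrices are reproducible regardless of the input SMILES form.
"""
import sys
import json

from rdkit import Chem, RDLogger
from rdkit.Chem import AllChem, Descriptors

RDLogger.DisableLog("rdApp.*")


def fail(error_type, msg):
    return {"ok": False, "error_type": error_type, "error": str(msg)}


def parse_mol(smi):
    """Parse and sanitize, distinguishing syntax from valence errors."""
    if not isinstance(smi, str) or smi.strip() == "":
        return None, fail("parse", "empty SMILES")
    mol = Chem.MolFromSmiles(smi, sanitize=False)
    if mol is None:
        return None, fail("parse", "unparsable SMILES: %r" % smi)
    try:
        Chem.SanitizeMol(mol)
    except Exception as exc:
        return None, fail("sanitize", "sanitization failed for %r: %s" % (smi, exc))
    return mol, None


def canonical_order(mol):
    ranks = list(Chem.CanonicalRankAtoms(mol))
    order = sorted(range(mol.GetNumAtoms()), key=lambda i: ranks[i])
    return Chem.RenumberAtoms(mol, order)


def graph_record(mol):
    atoms = {
        "element": [a.GetSymbol() for a in mol.GetAtoms()],
        "charge": [a.GetFormalCharge() for a in mol.GetAtoms()],
        "degree": [a.GetDegree() for a in mol.GetAtoms()],
        "aromatic": [bool(a.GetIsAromatic()) for a in mol.GetAtoms()],
        "in_ring": [bool(a.IsInRing()) for a in mol.GetAtoms()],
        "num_hs": [a.GetTotalNumHs() for a in mol.GetAtoms()],
    }
    bonds = [[b.GetBeginAtomIdx() + 1, b.GetEndAtomIdx() + 1]
             for b in mol.GetBonds()]
    return {"ok": True, "canonical_smiles": Chem.MolToSmiles(mol),
            "atoms": atoms, "bonds": bonds}


def do_parse(smi):
    mol, err = parse_mol(smi)
    if err:
        return err
    return graph_record(canonical_order(mol))


def do_embed(smi, seed, max_attempts):
    mol, err = parse_mol(smi)
    if err:
        return err
    mol = canonical_order(mol)
    rec = graph_record(mol)
    n_heavy = mol.GetNumAtoms()
    molh = Chem.AddHs(mol)
    embedded = False
    seed_used = None
    for k in range(max_attempts):
        params = AllChem.ETKDGv3()
        params.randomSeed = int(seed) + k
        if AllChem.EmbedMolecule(molh, params) >= 0:
            embedded = True
            seed_used = int(seed) + k
            break
    if embedded:
        try:
            AllChem.MMFFOptimizeMolecule(molh)
        except Exception:
            try:
                AllChem.UFFOptimizeMolecule(molh)
            except Exception:
                pass
        conf = molh.GetConformer()
        coords = [[conf.GetAtomPosition(i).x,
                   conf.GetAtomPosition(i).y,
                   conf.GetAtomPosition(i).z]
                  for i in range(molh.GetNumAtoms())]
        rec["coords"] = coords
        rec["elements_full"] = [a.GetSymbol() for a in molh.GetAtoms()]
        # AddHs appends hydrogens after the heavy atoms, preserving order
        rec["heavy_map"] = list(range(1, n_heavy + 1))
        rec["bonds_full"] = [[b.GetBeginAtomIdx() + 1, b.GetEndAtomIdx() + 1]
                             for b in molh.GetBonds()]
        rec["seed_used"] = seed_used
    rec["embedded"] = embedded
    if not embedded:
        rec["error_type"] = "embed"
        rec["error"] = ("conformer embedding failed after %d attempts"
                        % max_attempts)
    return rec


def do_canon(smi):
    mol, err = parse_mol(smi)
    if err:
        return err
    frags = Chem.GetMolFrags(mol, asMols=True, sanitizeFrags=False)
    best = None
    best_key = None
    for f in frags:
        can = Chem.MolToSmiles(f)
        # larger heavy count wins; then higher MW; then lexicographically
        # smaller canonical SMILES (deterministic tie-break)
        key = (-f.GetNumHeavyAtoms(), -Descriptors.MolWt(f), can)
        if best_key is None or key < best_key:
            best_key = key
            best = (f, can)
    f, can = best
    return {"ok": True,
            "canonical_smiles": can,
            "canonical_full": Chem.MolToSmiles(mol),
            "n_fragments": len(frags),
            "heavy_atoms": f.GetNumHeavyAtoms()}


def main():
    req = json.load(sys.stdin)
    mode = req["mode"]
    seed = req.get("seed", 42)
    max_attempts = req.get("max_attempts", 5)
    out = []
    for smi in req["smiles"]:
        if mode == "parse":
            out.append(do_parse(smi))
        elif mode == "embed":
            out.append(do_embed(smi, seed, max_attempts))
        elif mode == "canon":
            out.append(do_canon(smi))
        else:
            raise ValueError("unknown mode: %r" % mode)
    json.dump(out, sys.stdout)


if __name__ == "__main__":
    main()
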