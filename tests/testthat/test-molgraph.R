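test_that("ethanol parses to a 3-atom C-C-O path graph", {
  g <- parse_smiles("CCO")
  expect_s3_class(g, "AtomGraph")
  expect_equal(g$natoms, 3L)
  expect_setequal(g$atoms$element, c("C", "C", "O"))
  A <- build_adjacency(g)
  # a path: two terminal atoms, one centre, 2 bonds
  expect_equal(sort(rowSums(A)), c(1, 1, 2))
  expect_equal(sum(A) / 2, 2)
  expect_equal(A, t(A))
  expect_true(all(diag(A) == 0))
  # terminal O: the oxygen has degree 1
  expect_equal(rowSums(A)[g$atoms$element == "O"], 1, ignore_attr = TRUE)
})

test_that("single-atom molecule gives a 1x1 zero adjacency", {
  g <- parse_smiles("C")
  expect_equal(g$natoms, 1L)
  expect_equal(nrow(g$bonds), 0L)
  expect_equal(build_adjacency(g), matrix(0, 1, 1))
})

test_that("invalid SMILES raise classed errors", {
  expect_error(parse_smiles("C(C"), class = "math_parse_error")
  expect_error(parse_smiles("C(F)(F)(F)(F)F"), class = "math_sanitize_error")
})

test_that("canonical atom ordering makes graphs independent of SMILES form", {
  g1 <- parse_smiles("CCO")
  g2 <- parse_smiles("OCC")
  expect_identical(g1$atoms, g2$atoms)
  expect_identical(g1$bonds, g2$bonds)
  expect_identical(g1$smiles, g2$smiles)
})

test_that("conformer embedding is deterministic and adds explicit hydrogens", {
  e1 <- embed_conformer(parse_smiles("CCO"), seed = 42)
  e2 <- embed_conformer(parse_smiles("CCO"), seed = 42)
  expect_identical(e1$coords3d, e2$coords3d)
  expect_equal(nrow(e1$coords3d), 9L)          # 3 heavy + 6 H
  m <- embed_conformer(parse_smiles("C"), seed = 1)
  expect_equal(nrow(m$coords3d), 5L)           # 1 C + 4 H
  # every heavy atom has exactly one coordinate triple
  expect_equal(length(e1$heavy_index_map), e1$natoms)
  expect_false(any(duplicated(e1$heavy_index_map)))
})

test_that("distance matrix equals the brute-force all-pairs computation", {
  g <- embed_conformer(parse_smiles("O=Cc1ccc(Cl)cc1O"), seed = 42)
  D <- build_distance_matrix(g)
  xyz <- g$coords3d[g$heavy_index_map, ]
  n <- g$natoms
  Dref <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    Dref[i, j] <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
  }
  expect_lt(max(abs(D - Dref)), 1e-9)
  expect_equal(D, t(D))
  expect_true(all(diag(D) == 0))
  # triangle inequality within numerical tolerance
  for (i in 1:n) for (j in 1:n) for (k in 1:n) {
    expect_lte(D[i, j], D[i, k] + D[k, j] + 1e-9)
  }
})

test_that("distance matrix without a conformer raises MissingConformerError", {
  g <- parse_smiles("CCO")
  expect_error(build_distance_matrix(g),
               class = "math_missing_conformer_error")
  expect_error(detect_hbonds(g, 3.0),
               class = "math_missing_conformer_error")
})

test_that("fabricated O-H...O geometry yields one triple at 2.2 A, none at 1.5 A", {
  # O1 at origin carries the hydrogen at (0.96, 0, 0); O2 sits at (2.8, 0, 0)
  # so the H...O2 distance is exactly 1.84 A
  g <- fake_embedded_graph(
    elements_heavy = c("O", "O"),
    bonds_heavy = matrix(integer(0), ncol = 2),
    elements_full = c("O", "O", "H"),
    bonds_full = matrix(c(1L, 3L), ncol = 2, byrow = TRUE),
    coords = matrix(c(0, 0, 0, 2.8, 0, 0, 0.96, 0, 0), ncol = 3,
                    byrow = TRUE),
    heavy_map = c(1L, 2L))
  t22 <- detect_hbonds(g, 2.2)
  expect_equal(nrow(t22), 1L)
  expect_equal(t22$donor, 1L)
  expect_equal(t22$acceptor, 2L)
  expect_equal(t22$distance, 1.84, tolerance = 1e-12)
  expect_equal(nrow(detect_hbonds(g, 1.5)), 0L)
  expect_error(detect_hbonds(g, -1), "positive")
})

test_that("methane has no hydrogen bonds at any threshold", {
  g <- embed_conformer(parse_smiles("C"), seed = 1)
  expect_equal(nrow(detect_hbonds(g, 100)), 0L)
})

test_that("detect_hbonds matches the exhaustive pairwise oracle", {
  for (smi in c("O=Cc1ccc(Cl)cc1O", "NC(=O)c1ccccc1O", XANTHENE_SMILES)) {
    g <- embed_conformer(parse_smiles(smi), seed = 42)
    for (thr in c(2.2, 3.0, 4.0)) {
      got <- detect_hbonds(g, thr)
      ref <- oracle_hbond_scan(g, thr)
      expect_equal(nrow(got), nrow(ref))
      if (nrow(ref)) {
        expect_equal(got$donor, ref$donor, ignore_attr = TRUE)
        expect_equal(got$acceptor, ref$acceptor, ignore_attr = TRUE)
        expect_equal(got$distance, ref$distance, tolerance = 1e-12,
                     ignore_attr = TRUE)
      }
    }
  }
})

test_that("triples are monotone in the threshold and matrices elementwise ordered", {
  g <- embed_conformer(parse_smiles("NC(=O)c1ccccc1O"), seed = 42)
  grid <- seq(2.2, 4.0, by = 0.2)
  prev <- NULL
  prev_m <- NULL
  for (thr in grid) {
    tr <- detect_hbonds(g, thr)
    m <- hbond_matrix(tr, g$natoms)
    if (!is.null(prev)) {
      key <- function(x) paste(x$donor, x$acceptor, round(x$distance, 9))
      expect_true(all(key(prev) %in% key(tr)))
      expect_true(all(m >= prev_m))
    }
    prev <- tr
    prev_m <- m
  }
})

test_that("hbond_matrix builds a symmetric idempotent Boolean matrix", {
  empty <- data.frame(donor = integer(0), acceptor = integer(0),
                      distance = numeric(0))
  expect_equal(hbond_matrix(empty, 3), matrix(0, 3, 3))
  one <- data.frame(donor = 1L, acceptor = 3L, distance = 1.9)
  m <- hbond_matrix(one, 3)
  expect_equal(sum(m), 2)
  expect_equal(m[1, 3], 1)
  expect_equal(m[3, 1], 1)
  dup <- rbind(one, data.frame(donor = 1L, acceptor = 3L, distance = 2.4))
  expect_equal(hbond_matrix(dup, 3), m)
  expect_error(hbond_matrix(data.frame(donor = 5L, acceptor = 1L,
                                       distance = 1), 3), "range")
})

test_that("Boolean matrix nonzeros count distinct donor-acceptor pairs twice", {
  g <- embed_conformer(parse_smiles(XANTHENE_SMILES), seed = 42)
  tr <- detect_hbonds(g, 4.0)
  m <- hbond_matrix(tr, g$natoms)
  pairs <- unique(paste(pmin(tr$donor, tr$acceptor),
                        pmax(tr$donor, tr$acceptor)))
  expect_equal(sum(m != 0), 2 * length(pairs))
})

test_that("featurize returns a consistent descriptor bundle", {
  fs <- featurize("CCO", featurizer_config(dthreshold = 2.2, seed = 42))
  expect_s3_class(fs, "DescriptorSet")
  expect_equal(fs$natoms, 3L)
  expect_equal(dim(fs$node_features), c(3L, node_feature_dim()))
  expect_equal(fs$hbond_bool, matrix(0, 3, 3))
  expect_equal(nrow(fs$hbond_triples), 0L)
  for (m in list(fs$adjacency, fs$distance, fs$hbond_bool)) {
    expect_equal(dim(m), c(3L, 3L))
    expect_equal(m, t(m))
  }
  expect_error(featurize("C(C"), class = "math_parse_error")
})

test_that("featurize is bit-stable across runs for a fixed seed", {
  cfg <- featurizer_config(dthreshold = 3.0, seed = 42)
  f1 <- featurize("NC(=O)c1ccccc1O", cfg)
  clear_molecule_cache()
  f2 <- featurize("NC(=O)c1ccccc1O", cfg)
  expect_identical(f1$distance, f2$distance)
  expect_identical(f1$hbond_bool, f2$hbond_bool)
  expect_identical(f1$node_features, f2$node_features)
})

test_that("node features one-hot blocks are well-formed", {
  fs <- featurize("CC(=O)Nc1ccc(O)cc1", featurizer_config(seed = 42))
  X <- fs$node_features
  n_el <- 11
  expect_true(all(rowSums(X[, 1:n_el]) == 1))            # element one-hot
  expect_true(all(rowSums(X[, n_el + 1:6]) == 1))        # degree one-hot
  expect_true(all(rowSums(X[, n_el + 6 + 1:5]) == 1))    # H-count one-hot
  expect_true(all(rowSums(X[, n_el + 11 + 1:3]) == 1))   # charge one-hot
  expect_true(all(X %in% c(0, 1)))
})
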