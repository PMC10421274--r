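# Independent scalar-loop oracles and hand-built geometry fixtures.
# These deliberately avoid the package's vectorized code paths.

# Eq. 1 oracle: element-by-element scaled-dot-product attention.
oracle_standard_attention <- function(H, wq, wk, wv) {
  n <- nrow(H)
  dk <- ncol(wq)
  Q <- matrix(0, n, dk); K <- matrix(0, n, dk); V <- matrix(0, n, dk)
  for (i in seq_len(n)) for (j in seq_len(dk)) {
    Q[i, j] <- sum(H[i, ] * wq[, j])
    K[i, j] <- sum(H[i, ] * wk[, j])
    V[i, j] <- sum(H[i, ] * wv[, j])
  }
  S <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    S[i, j] <- sum(Q[i, ] * K[j, ]) / sqrt(dk)
  }
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    e <- exp(S[i, ] - max(S[i, ]))
    P[i, ] <- e / sum(e)
  }
  out <- matrix(0, n, dk)
  for (i in seq_len(n)) for (j in seq_len(dk)) {
    out[i, j] <- sum(P[i, ] * V[, j])
  }
  out
}

# Eq. 2 oracle: mixing softmax, normalized distance, adjacency and H-bond
# terms with scalar loops.
oracle_molecule_attention <- function(H, A, D, Hb, wq, wk, wv,
                                      la, ld, lg, lh) {
  n <- nrow(H)
  dk <- ncol(wq)
  Q <- H %*% wq; K <- H %*% wk; V <- H %*% wv  # projections checked by Eq.1
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    s <- numeric(n)
    for (j in seq_len(n)) s[j] <- sum(Q[i, ] * K[j, ]) / sqrt(dk)
    e <- exp(s - max(s))
    P[i, ] <- e / sum(e)
  }
  G <- matrix(0, n, n)
  for (i in seq_len(n)) {
    e <- exp(-D[i, ] - max(-D[i, ]))
    G[i, ] <- e / sum(e)
  }
  M <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    M[i, j] <- la * P[i, j] + ld * G[i, j] + lg * A[i, j] + lh * Hb[i, j]
  }
  out <- matrix(0, n, dk)
  for (i in seq_len(n)) for (j in seq_len(dk)) {
    out[i, j] <- sum(M[i, ] * V[, j])
  }
  out
}

# Brute-force hydrogen-bond scan over every (H, acceptor) pair; mirrors the
# detection rules with plain loops over the raw coordinate set.
oracle_hbond_scan <- function(graph, thr, exclude_13 = TRUE) {
  els <- graph$elements_full
  co <- graph$coords3d
  bonded <- function(i, j) {
    any((graph$bonds_full[, 1] == i & graph$bonds_full[, 2] == j) |
          (graph$bonds_full[, 1] == j & graph$bonds_full[, 2] == i))
  }
  heavy_of <- integer(length(els))
  heavy_of[graph$heavy_index_map] <- seq_along(graph$heavy_index_map)
  found <- list()
  for (h in which(els == "H")) {
    don_full <- NA
    for (j in seq_along(els)) if (j != h && bonded(h, j)) don_full <- j
    if (is.na(don_full) || !(els[don_full] %in% c("N", "O", "S"))) next
    for (a in seq_along(els)) {
      if (a == h || a == don_full) next
      if (!(els[a] %in% c("N", "O", "S")) || heavy_of[a] == 0) next
      if (bonded(a, h) || bonded(a, don_full)) next
      if (exclude_13) {
        common <- FALSE
        for (m in graph$heavy_index_map) {
          if (m != a && m != don_full && bonded(m, don_full) && bonded(m, a))
            common <- TRUE
        }
        if (common) next
      }
      d <- sqrt(sum((co[h, ] - co[a, ])^2))
      if (d <= thr) {
        found[[length(found) + 1]] <-
          c(heavy_of[don_full], heavy_of[a], d)
      }
    }
  }
  if (!length(found)) {
    return(data.frame(donor = integer(0), acceptor = integer(0),
                      distance = numeric(0)))
  }
  out <- as.data.frame(do.call(rbind, found))
  names(out) <- c("donor", "acceptor", "distance")
  out[order(out$donor, out$acceptor, out$distance), ]
}

# Hand-built embedded AtomGraph for fabricated geometries (no toolkit).
fake_embedded_graph <- function(elements_heavy, bonds_heavy, elements_full,
                                bonds_full, coords, heavy_map) {
  atoms <- data.frame(element = elements_heavy,
                      charge = 0L,
                      degree = vapply(seq_along(elements_heavy), function(i) {
                        sum(bonds_heavy == i)
                      }, integer(1)),
                      aromatic = FALSE, in_ring = FALSE, num_hs = 0L,
                      stringsAsFactors = FALSE)
  structure(list(atoms = atoms, bonds = bonds_heavy,
                 natoms = length(elements_heavy), smiles = "<synthetic>",
                 coords3d = coords, elements_full = elements_full,
                 bonds_full = bonds_full, heavy_index_map = heavy_map,
                 embedded = TRUE, fallback = FALSE),
            class = "AtomGraph")
}

# random small DescriptorSet for attention/forward property tests
random_descriptor <- function(n, d_feat = 27) {
  xyz <- matrix(stats::rnorm(n * 3), n, 3)
  A <- matrix(0, n, n)
  if (n > 1) for (i in seq_len(n - 1)) A[i, i + 1] <- A[i + 1, i] <- 1
  Hb <- matrix(0, n, n)
  if (n > 2 && stats::runif(1) < 0.5) {
    Hb[1, n] <- Hb[n, 1] <- 1
  }
  structure(list(node_features = matrix(stats::rnorm(n * d_feat), n, d_feat),
                 adjacency = A,
                 distance = as.matrix(stats::dist(xyz)),
                 hbond_bool = Hb, natoms = n,
                 smiles = "<random>", fallback = FALSE),
            class = "DescriptorSet")
}

# the 26-heavy-atom worked-example compound:
# 2-[(9S)-3-hydroxy-9H-xanthen-9-yl]-2-methyl-N-(1,3-thiazol-2-yl)propanamide
XANTHENE_SMILES <- "CC(C)(C1c2ccccc2Oc2ccc(O)cc21)C(=O)Nc1nccs1"
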