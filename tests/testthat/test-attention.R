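make_params <- function(d_model, heads, dk = d_model %/% heads, seed = 1,
                        ...) {
  init_attention_params(d_model, heads, dk = dk, seed = seed, ...)
}

test_that("standard attention matches the scalar-loop oracle", {
  for (s in 1:40) {
    set.seed(s)
    n <- sample(2:5, 1)
    p <- make_params(d_model = 4, heads = 1, dk = 4, seed = s)
    H <- matrix(rnorm(n * 4), n, 4)
    got <- standard_attention(H, p, 1)
    ref <- oracle_standard_attention(H, p$wq[[1]], p$wk[[1]], p$wv[[1]])
    expect_lt(max(abs(got - ref)), 1e-5)
  }
})

test_that("single-atom attention returns V exactly", {
  p <- make_params(4, 1, 4, seed = 2)
  H <- matrix(rnorm(4), 1, 4)
  expect_equal(standard_attention(H, p, 1), H %*% p$wv[[1]],
               tolerance = 1e-12)
})

test_that("identical hidden rows produce identical attention rows", {
  p <- make_params(6, 2, 3, seed = 3)
  H <- matrix(rep(rnorm(6), each = 3), 3, 6)
  out <- standard_attention(H, p, 2)
  expect_equal(out[1, ], out[2, ])
  expect_equal(out[2, ], out[3, ])
})

test_that("molecule self-attention matches the scalar-loop oracle", {
  for (s in 1:40) {
    set.seed(1000 + s)
    n <- sample(2:5, 1)
    p <- make_params(4, 1, 4, seed = s, lambda_a = 1 / 3, lambda_d = 1 / 3,
                     lambda_g = 1 / 3, lambda_h = 1)
    H <- matrix(rnorm(n * 4), n, 4)
    A <- matrix(rbinom(n * n, 1, 0.4), n, n); A <- 1 * ((A + t(A)) > 0)
    diag(A) <- 0
    D <- as.matrix(stats::dist(matrix(rnorm(n * 3), n, 3)))
    Hb <- matrix(0, n, n); Hb[1, n] <- Hb[n, 1] <- 1; diag(Hb) <- 0
    got <- molecule_self_attention(H, A, D, Hb, p, 1)
    ref <- oracle_molecule_attention(H, A, D, Hb, p$wq[[1]], p$wk[[1]],
                                     p$wv[[1]], 1 / 3, 1 / 3, 1 / 3, 1)
    expect_lt(max(abs(got - ref)), 1e-5)
  }
})

test_that("mixing weights (1,0,0,0) reduce exactly to standard attention", {
  set.seed(7)
  n <- 4
  p <- make_params(8, 2, 4, seed = 7, lambda_a = 1, lambda_d = 0,
                   lambda_g = 0, lambda_h = 0)
  H <- matrix(rnorm(n * 8), n, 8)
  A <- matrix(rbinom(n * n, 1, 0.5), n, n); A <- 1 * ((A + t(A)) > 0)
  diag(A) <- 0
  D <- as.matrix(stats::dist(matrix(rnorm(n * 3), n, 3)))
  Hb <- matrix(0, n, n)
  for (head in 1:2) {
    expect_lt(max(abs(molecule_self_attention(H, A, D, Hb, p, head) -
                        standard_attention(H, p, head))), 1e-6)
  }
})

test_that("pure adjacency routing swaps the two atoms' values", {
  p <- make_params(4, 1, 4, seed = 9, lambda_a = 0, lambda_d = 0,
                   lambda_g = 1, lambda_h = 0)
  H <- matrix(rnorm(8), 2, 4)
  A <- matrix(c(0, 1, 1, 0), 2, 2)
  D <- matrix(c(0, 1.5, 1.5, 0), 2, 2)
  out <- molecule_self_attention(H, A, D, matrix(0, 2, 2), p, 1)
  V <- H %*% p$wv[[1]]
  expect_equal(out[1, ], V[2, ], tolerance = 1e-12)
  expect_equal(out[2, ], V[1, ], tolerance = 1e-12)
})

test_that("softmax rows and the row-softmax distance normalizer are stochastic", {
  set.seed(11)
  D <- as.matrix(stats::dist(matrix(rnorm(15), 5, 3)))
  G <- normalize_distance(D, "row_softmax")
  expect_equal(rowSums(G), rep(1, 5), ignore_attr = TRUE)
  expect_true(all(G >= 0))
  # nearer atoms get more weight than farther ones
  expect_true(all(diag(G) >= apply(G - diag(diag(G)), 1, max)))
  E <- normalize_distance(D, "exp_neg")
  expect_true(all(E >= 0 & E <= 1))
  expect_equal(diag(E), rep(1, 5), ignore_attr = TRUE)
})

test_that("negative mixing weights are rejected", {
  expect_error(make_params(4, 1, 4, lambda_a = -0.1), "non-negative")
  expect_error(math_config("test", lambda_g = -1), ">= 0")
})

test_that("shape mismatches raise ShapeError", {
  p <- make_params(8, 2, 4)
  H <- matrix(rnorm(12), 3, 4)              # wrong width
  expect_error(standard_attention(H, p, 1), class = "math_shape_error")
  H2 <- matrix(rnorm(24), 3, 8)
  expect_error(molecule_self_attention(H2, matrix(0, 2, 2),
                                       matrix(0, 2, 2), matrix(0, 2, 2),
                                       p, 1),
               class = "math_shape_error")
})

test_that("encoder block preserves shape and is deterministic", {
  set.seed(21)
  cfg <- math_config("test", d_model = 16, heads = 4, d_ff = 24)
  w <- math_init_weights(cfg, seed = 5)
  desc <- random_descriptor(5)
  H <- matrix(rnorm(5 * 16), 5, 16)
  out1 <- encoder_block(H, desc, w$blocks[[1]], cfg)
  out2 <- encoder_block(H, desc, w$blocks[[1]], cfg)
  expect_equal(dim(out1), c(5L, 16L))
  expect_identical(out1, out2)
})

test_that("a zeroed feed-forward reduces the block to layer-norm of the attention residual", {
  set.seed(22)
  cfg <- math_config("test", d_model = 16, heads = 2, d_ff = 8)
  w <- math_init_weights(cfg, seed = 6)
  blk <- w$blocks[[1]]
  blk$W1[] <- 0; blk$W2[] <- 0; blk$b1[] <- 0; blk$b2[] <- 0
  desc <- random_descriptor(4)
  H <- matrix(rnorm(4 * 16), 4, 16)
  got <- encoder_block(H, desc, blk, cfg)
  # hand-composed reference: LN2(LN1(H + multi-head attention output))
  p <- attention_params(
    wq = lapply(1:2, function(i) blk$Wq[, (i - 1) * 8 + 1:8]),
    wk = lapply(1:2, function(i) blk$Wk[, (i - 1) * 8 + 1:8]),
    wv = lapply(1:2, function(i) blk$Wv[, (i - 1) * 8 + 1:8]),
    lambda_a = cfg$lambda_a, lambda_d = cfg$lambda_d,
    lambda_g = cfg$lambda_g, lambda_h = cfg$lambda_h)
  att <- do.call(cbind, lapply(1:2, function(i) {
    molecule_self_attention(H, desc$adjacency, desc$distance,
                            desc$hbond_bool, p, i)
  }))
  proj <- sweep(att %*% blk$Wo, 2, blk$bo, "+")
  ln <- function(x, g, b) {
    mu <- rowMeans(x); xc <- x - mu
    xhat <- xc / sqrt(rowMeans(xc^2) + 1e-5)
    sweep(sweep(xhat, 2, g, "*"), 2, b, "+")
  }
  ref <- ln(ln(H + proj, blk$ln1_g, blk$ln1_b), blk$ln2_g, blk$ln2_b)
  expect_lt(max(abs(got - ref)), 1e-9)
})

test_that("forward pass returns probabilities invariant to atom permutation", {
  cfg <- math_config("test", d_model = 32, heads = 4)
  w <- math_init_weights(cfg, seed = 8)
  for (s in 1:10) {
    set.seed(300 + s)
    n <- sample(3:7, 1)
    desc <- random_descriptor(n)
    p0 <- math_forward(desc, w, cfg)
    expect_gte(p0, 0); expect_lte(p0, 1)
    perm <- sample(n)
    desc2 <- desc
    desc2$node_features <- desc$node_features[perm, , drop = FALSE]
    desc2$adjacency <- desc$adjacency[perm, perm]
    desc2$distance <- desc$distance[perm, perm]
    desc2$hbond_bool <- desc$hbond_bool[perm, perm]
    expect_equal(math_forward(desc2, w, cfg), p0, tolerance = 1e-9)
  }
})

test_that("disabling the hydrogen-bond term reproduces the plain structure-attention forward pass", {
  # the ablation baseline must be the same code path with lambda_h = 0
  cfg_math <- math_config("test", d_model = 32, heads = 4, lambda_h = 1)
  cfg_mat <- math_config("test", d_model = 32, heads = 4, lambda_h = 0)
  w <- math_init_weights(cfg_math, seed = 12)
  set.seed(55)
  desc <- random_descriptor(5)
  desc_zero <- desc
  desc_zero$hbond_bool <- matrix(0, 5, 5)
  # lambda_h = 0 with any H-bond matrix == lambda_h = 1 with a zero matrix
  expect_identical(math_forward(desc, w, cfg_mat),
                   math_forward(desc_zero, w, cfg_mat))
  expect_equal(math_forward(desc_zero, w, cfg_math),
               math_forward(desc, w, cfg_mat), tolerance = 1e-12)
})
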