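# The full classifier: embedding -> N encoder blocks (multi-head molecule
# self-attention + position-wise feed-forward, each with residual connection
# and layer normalization) -> masked pooling -> logistic classification head.

#' Model configuration
#'
#' Defaults follow the full-scale training setup: 8 encoder blocks, 16
#' attention heads, hidden size 1024, batch size 64, 100 epochs, Adam with
#' learning rate 1e-4 and betas (0.9, 0.999). `profile = "test"` selects a
#' scaled-down configuration (2 blocks, 4 heads, hidden size 64, 10 epochs,
#' batch size 16, learning rate 1e-3) sized for desk-scale experiments on
#' synthetic fixtures.
#'
#' @param profile `"paper"` (full-scale defaults) or `"test"` (scaled-down).
#' @param n_blocks Encoder repeats.
#' @param heads Attention heads; must divide `d_model`.
#' @param d_model Embedded atomic feature size.
#' @param d_ff Feed-forward inner width (default `2 * d_model`).
#' @param batch_size,epochs,lr,beta1,beta2 Optimizer settings (Adam).
#' @param dropout Dropout rate applied after the attention and feed-forward
#'   sub-layers during training (default 0, keeping runs deterministic).
#' @param pooling `"mean"` or `"sum"` over atom embeddings.
#' @param threshold Classification threshold on P(active).
#' @param lambda_a,lambda_d,lambda_g Attention mixing weights.
#' @param lambda_h Weight on the hydrogen-bond matrix; `lambda_h = 0`
#'   together with a zero hydrogen-bond matrix gives the ablation baseline
#'   without hydrogen-bond information.
#' @param distance_normalizer See [normalize_distance()].
#' @return A list of class `math_config`.
#' @export
math_config <- function(profile = c("paper", "test"),
                        n_blocks = NULL, heads = NULL, d_model = NULL,
                        d_ff = NULL, batch_size = NULL, epochs = NULL,
                        lr = NULL, beta1 = 0.9, beta2 = 0.999,
                        dropout = 0, pooling = c("mean", "sum"),
                        threshold = 0.5,
                        lambda_a = 1 / 3, lambda_d = 1 / 3,
                        lambda_g = 1 / 3, lambda_h = 1,
                        distance_normalizer = c("row_softmax", "exp_neg")) {
  profile <- match.arg(profile)
  base <- if (profile == "paper") {
    list(n_blocks = 8L, heads = 16L, d_model = 1024L, batch_size = 64L,
         epochs = 100L, lr = 1e-4)
  } else {
    list(n_blocks = 2L, heads = 4L, d_model = 64L, batch_size = 16L,
         epochs = 10L, lr = 1e-3)
  }
  cfg <- list(profile = profile,
              n_blocks = as.integer(n_blocks %||% base$n_blocks),
              heads = as.integer(heads %||% base$heads),
              d_model = as.integer(d_model %||% base$d_model),
              batch_size = as.integer(batch_size %||% base$batch_size),
              epochs = as.integer(epochs %||% base$epochs),
              lr = lr %||% base$lr, beta1 = beta1, beta2 = beta2,
              dropout = dropout, pooling = match.arg(pooling),
              threshold = threshold,
              lambda_a = lambda_a, lambda_d = lambda_d,
              lambda_g = lambda_g, lambda_h = lambda_h,
              distance_normalizer = match.arg(distance_normalizer))
  cfg$d_ff <- as.integer(d_ff %||% (2L * cfg$d_model))
  if (cfg$d_model %% cfg$heads != 0L) {
    stop("d_model must be divisible by heads", call. = FALSE)
  }
  if (any(c(lambda_a, lambda_d, lambda_g) < 0)) {
    stop("mixing weights lambda_a, lambda_d, lambda_g must be >= 0",
         call. = FALSE)
  }
  structure(cfg, class = "math_config")
}

#' Initialize model weights
#'
#' Truncated-normal (Glorot-scaled, clamped at two standard deviations)
#' projections, zero biases, unit layer-norm gains.
#'
#' @param config A [math_config()].
#' @param d_feat Node-feature dimension (default [node_feature_dim()]).
#' @param seed RNG seed.
#' @return A list of class `math_weights`.
#' @export
math_init_weights <- function(config, d_feat = node_feature_dim(),
                              seed = 1L) {
  stopifnot(inherits(config, "math_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  d <- config$d_model
  blocks <- lapply(seq_len(config$n_blocks), function(b) {
    list(Wq = .trunc_normal(d, d), Wk = .trunc_normal(d, d),
         Wv = .trunc_normal(d, d), Wo = .trunc_normal(d, d),
         bo = numeric(d),
         ln1_g = rep(1, d), ln1_b = numeric(d),
         W1 = .trunc_normal(d, config$d_ff), b1 = numeric(config$d_ff),
         W2 = .trunc_normal(config$d_ff, d), b2 = numeric(d),
         ln2_g = rep(1, d), ln2_b = numeric(d))
  })
  structure(list(embed = list(W = .trunc_normal(d_feat, d), b = numeric(d)),
                 blocks = blocks,
                 out = list(w = .trunc_normal(d, 1L)[, 1L], b = 0)),
            class = "math_weights")
}

.LN_EPS <- 1e-5

.ln_forward <- function(x, g, b) {
  mu <- rowMeans(x)
  xc <- x - mu
  inv <- 1 / sqrt(rowMeans(xc^2) + .LN_EPS)
  xhat <- xc * inv
  list(y = sweep(sweep(xhat, 2, g, "*"), 2, b, "+"),
       xhat = xhat, inv = inv)
}

.ln_backward <- function(dy, cache, g) {
  dxhat <- sweep(dy, 2, g, "*")
  dx <- cache$inv * (dxhat - rowMeans(dxhat) -
                       cache$xhat * rowMeans(dxhat * cache$xhat))
  list(dx = dx, dg = colSums(dy * cache$xhat), db = colSums(dy))
}

.head_cols <- function(i, dk) ((i - 1L) * dk + 1L):(i * dk)

# Multi-head structure-augmented attention with fused projections.
.mha_forward <- function(H, desc, blk, cfg, gD) {
  d <- cfg$d_model; h <- cfg$heads; dk <- d %/% h
  Q <- H %*% blk$Wq; K <- H %*% blk$Wk; V <- H %*% blk$Wv
  O <- matrix(0, nrow(H), d)
  P <- vector("list", h)
  M <- vector("list", h)
  for (i in seq_len(h)) {
    cols <- .head_cols(i, dk)
    Pi <- .softmax_rows(Q[, cols, drop = FALSE] %*%
                          t(K[, cols, drop = FALSE]) / sqrt(dk))
    Mi <- cfg$lambda_a * Pi + cfg$lambda_d * gD +
      cfg$lambda_g * desc$adjacency + cfg$lambda_h * desc$hbond_bool
    O[, cols] <- Mi %*% V[, cols, drop = FALSE]
    P[[i]] <- Pi; M[[i]] <- Mi
  }
  out <- sweep(O %*% blk$Wo, 2, blk$bo, "+")
  list(out = out, Q = Q, K = K, V = V, O = O, P = P, M = M)
}

.mha_backward <- function(dout, cache, H, blk, cfg) {
  d <- cfg$d_model; h <- cfg$heads; dk <- d %/% h
  gr <- list(Wo = t(cache$O) %*% dout, bo = colSums(dout))
  dO <- dout %*% t(blk$Wo)
  dQ <- matrix(0, nrow(H), d); dK <- dQ; dV <- dQ
  for (i in seq_len(h)) {
    cols <- .head_cols(i, dk)
    dOi <- dO[, cols, drop = FALSE]
    Vi <- cache$V[, cols, drop = FALSE]
    dM <- dOi %*% t(Vi)
    dV[, cols] <- t(cache$M[[i]]) %*% dOi
    dP <- cfg$lambda_a * dM
    Pi <- cache$P[[i]]
    dS <- Pi * (dP - rowSums(dP * Pi))
    dQ[, cols] <- dS %*% cache$K[, cols, drop = FALSE] / sqrt(dk)
    dK[, cols] <- t(dS) %*% cache$Q[, cols, drop = FALSE] / sqrt(dk)
  }
  gr$Wq <- t(H) %*% dQ; gr$Wk <- t(H) %*% dK; gr$Wv <- t(H) %*% dV
  gr$dH <- dQ %*% t(blk$Wq) + dK %*% t(blk$Wk) + dV %*% t(blk$Wv)
  gr
}

.block_forward <- function(H, desc, blk, cfg, gD) {
  att <- .mha_forward(H, desc, blk, cfg, gD)
  ln1 <- .ln_forward(H + att$out, blk$ln1_g, blk$ln1_b)
  U <- ln1$y %*% blk$W1
  U <- sweep(U, 2, blk$b1, "+")
  R <- pmax(U, 0)
  FF <- sweep(R %*% blk$W2, 2, blk$b2, "+")
  ln2 <- .ln_forward(ln1$y + FF, blk$ln2_g, blk$ln2_b)
  list(out = ln2$y, att = att, ln1 = ln1, U = U, R = R, ln2 = ln2)
}

.block_backward <- function(dout, cache, H, blk, cfg) {
  l2 <- .ln_backward(dout, cache$ln2, blk$ln2_g)
  dFF <- l2$dx
  gr <- list(ln2_g = l2$dg, ln2_b = l2$db,
             W2 = t(cache$R) %*% dFF, b2 = colSums(dFF))
  dR <- dFF %*% t(blk$W2)
  dU <- dR * (cache$U > 0)
  gr$W1 <- t(cache$ln1$y) %*% dU
  gr$b1 <- colSums(dU)
  dh1 <- l2$dx + dU %*% t(blk$W1)
  l1 <- .ln_backward(dh1, cache$ln1, blk$ln1_g)
  gr$ln1_g <- l1$dg; gr$ln1_b <- l1$db
  att_gr <- .mha_backward(l1$dx, cache$att, H, blk, cfg)
  gr$Wq <- att_gr$Wq; gr$Wk <- att_gr$Wk; gr$Wv <- att_gr$Wv
  gr$Wo <- att_gr$Wo; gr$bo <- att_gr$bo
  gr$dH <- l1$dx + att_gr$dH
  gr
}

# Full forward pass with caches (used by both prediction and backprop).
.forward_cache <- function(desc, weights, cfg) {
  gD <- normalize_distance(desc$distance, cfg$distance_normalizer)
  H <- sweep(desc$node_features %*% weights$embed$W, 2, weights$embed$b, "+")
  caches <- vector("list", cfg$n_blocks)
  Hs <- vector("list", cfg$n_blocks + 1L)
  Hs[[1L]] <- H
  for (b in seq_len(cfg$n_blocks)) {
    caches[[b]] <- .block_forward(Hs[[b]], desc, weights$blocks[[b]], cfg, gD)
    Hs[[b + 1L]] <- caches[[b]]$out
  }
  HN <- Hs[[cfg$n_blocks + 1L]]
  pool <- if (cfg$pooling == "mean") colMeans(HN) else colSums(HN)
  logit <- sum(pool * weights$out$w) + weights$out$b
  prob <- 1 / (1 + exp(-logit))
  list(prob = prob, logit = logit, pool = pool, Hs = Hs, caches = caches)
}

.backward <- function(fw, desc, y, weights, cfg) {
  n <- desc$natoms
  dlogit <- fw$prob - y                       # BCE on the logistic output
  gr <- list(out = list(w = dlogit * fw$pool, b = dlogit))
  dpool <- dlogit * weights$out$w
  dH <- matrix(rep(dpool, each = n), n, cfg$d_model)
  if (cfg$pooling == "mean") dH <- dH / n
  gr$blocks <- vector("list", cfg$n_blocks)
  for (b in rev(seq_len(cfg$n_blocks))) {
    bg <- .block_backward(dH, fw$caches[[b]], fw$Hs[[b]],
                          weights$blocks[[b]], cfg)
    dH <- bg$dH
    bg$dH <- NULL
    gr$blocks[[b]] <- bg
  }
  gr$embed <- list(W = t(desc$node_features) %*% dH, b = colSums(dH))
  gr
}

#' One encoder block
#'
#' Concatenates the heads' molecule self-attention outputs, projects back to
#' `d_model`, applies residual connection and layer normalization, then a
#' position-wise feed-forward sub-layer with its own residual connection and
#' layer normalization.
#'
#' @param hidden Hidden-state matrix, `N x d_model`.
#' @param descriptors A [featurize()] `DescriptorSet` (adjacency, distance
#'   and hydrogen-bond matrices must be `N x N`).
#' @param params One block's weights, an element of
#'   `math_init_weights(config)$blocks`.
#' @param config A [math_config()].
#' @return The transformed hidden state, `N x d_model`.
#' @export
encoder_block <- function(hidden, descriptors, params, config) {
  stopifnot(inherits(config, "math_config"))
  if (!is.matrix(hidden) || ncol(hidden) != config$d_model ||
      nrow(hidden) != descriptors$natoms) {
    .raise("math_shape_error", "hidden must be N x d_model with N = natoms")
  }
  gD <- normalize_distance(descriptors$distance, config$distance_normalizer)
  .block_forward(hidden, descriptors, params, config, gD)$out
}

#' Forward pass: probability that a molecule is active
#'
#' Embeds the node features to `d_model`, applies the encoder blocks, pools
#' over atoms, and applies a logistic classification layer. The result is
#' invariant under any consistent reordering of the atoms.
#'
#' @param molecule A `DescriptorSet` from [featurize()].
#' @param weights A `math_weights` object.
#' @param config The [math_config()] the weights were built for.
#' @return `P(active)`, a single number in `[0, 1]`.
#' @export
math_forward <- function(molecule, weights, config) {
  stopifnot(inherits(molecule, "DescriptorSet"),
            inherits(weights, "math_weights"),
            inherits(config, "math_config"))
  if (ncol(molecule$node_features) != nrow(weights$embed$W)) {
    .raise("math_shape_error", "node-feature width does not match weights")
  }
  .forward_cache(molecule, weights, config)$prob
}
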