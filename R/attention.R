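# Molecule self-attention: scaled-dot-product attention augmented with
# adjacency, inter-atomic distance and intramolecular hydrogen-bond matrices.
#
# For head i with hidden state H (N x d_model):
#   standard:  A(i) = softmax(Q_i K_i^T / sqrt(dk)) V_i
#   molecule:  A(i) = (la * softmax(Q_i K_i^T / sqrt(dk))
#                      + ld * g(D) + lg * A + lh * Hbond) V_i
# where Q_i = H W^Q_i, K_i = H W^K_i, V_i = H W^V_i, A is the adjacency
# matrix, D the distance matrix, Hbond the {0,1} hydrogen-bond matrix, and
# g a distance normalizer. Setting (la, ld, lg, lh) = (1, 0, 0, 0) recovers
# the standard attention exactly.

#' Per-head attention parameters
#'
#' Container for the per-head projection matrices and the mixing weights of
#' the structure-augmented attention.
#'
#' @param wq,wk,wv Lists of per-head projection matrices, each
#'   `d_model x dk`.
#' @param lambda_a,lambda_d,lambda_g Non-negative mixing weights on the
#'   attention softmax, the normalized distance matrix and the adjacency
#'   matrix. Defaults `1/3` each (chosen to sum to 1; the sum is not
#'   enforced).
#' @param lambda_h Weight on the hydrogen-bond matrix (default 1, applied to
#'   the raw `{0,1}` matrix, which is not softmax-normalized).
#' @param distance_normalizer `"row_softmax"` (row-wise softmax of the
#'   negated distances, so nearer atoms get larger weight) or `"exp_neg"`
#'   (elementwise `exp(-D)`).
#' @return An object of class `attention_params`.
#' @export
attention_params <- function(wq, wk, wv, lambda_a = 1 / 3, lambda_d = 1 / 3,
                             lambda_g = 1 / 3, lambda_h = 1,
                             distance_normalizer = c("row_softmax",
                                                     "exp_neg")) {
  stopifnot(is.list(wq), is.list(wk), is.list(wv),
            length(wq) == length(wk), length(wk) == length(wv),
            length(wq) >= 1L)
  if (any(c(lambda_a, lambda_d, lambda_g) < 0)) {
    stop("lambda_a, lambda_d and lambda_g must be non-negative",
         call. = FALSE)
  }
  dk <- ncol(wq[[1]])
  stopifnot(dk > 0)
  structure(list(wq = wq, wk = wk, wv = wv, dk = dk, heads = length(wq),
                 lambda_a = lambda_a, lambda_d = lambda_d,
                 lambda_g = lambda_g, lambda_h = lambda_h,
                 distance_normalizer = match.arg(distance_normalizer)),
            class = "attention_params")
}

#' Randomly initialized attention parameters
#'
#' @param d_model Hidden dimension.
#' @param heads Number of heads.
#' @param dk Per-head dimension (default `d_model / heads`).
#' @param seed RNG seed for the truncated-normal initialization.
#' @param ... Passed to [attention_params()] (mixing weights, normalizer).
#' @export
init_attention_params <- function(d_model, heads, dk = d_model %/% heads,
                                  seed = 1L, ...) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  mk <- function() lapply(seq_len(heads),
                          function(i) .trunc_normal(d_model, dk))
  attention_params(mk(), mk(), mk(), ...)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

# Truncated-normal init: N(0, sd^2) clamped at +/- 2 sd, Glorot-scaled.
.trunc_normal <- function(nr, nc, sd = sqrt(2 / (nr + nc))) {
  x <- stats::rnorm(nr * nc, sd = sd)
  matrix(pmax(pmin(x, 2 * sd), -2 * sd), nr, nc)
}

.softmax_rows <- function(S) {
  S <- S - apply(S, 1, max)
  E <- exp(S)
  E / rowSums(E)
}

#' Normalize a distance matrix for use as an attention weight
#'
#' @param D Distance matrix (Angstrom).
#' @param method `"row_softmax"`: row-wise softmax of `-D` (rows sum to 1,
#'   nearer atoms weighted higher); `"exp_neg"`: elementwise `exp(-D)`.
#' @return Non-negative matrix of the same shape.
#' @export
normalize_distance <- function(D, method = c("row_softmax", "exp_neg")) {
  method <- match.arg(method)
  if (method == "row_softmax") .softmax_rows(-D) else exp(-D)
}

.check_hidden <- function(hidden, params, head) {
  if (!is.matrix(hidden)) stop("hidden must be a matrix", call. = FALSE)
  if (head < 1L || head > params$heads) {
    stop("head index out of range", call. = FALSE)
  }
  if (ncol(hidden) != nrow(params$wq[[head]])) {
    .raise("math_shape_error",
           sprintf("hidden has %d columns but projections expect %d",
                   ncol(hidden), nrow(params$wq[[head]])))
  }
}

#' Standard scaled-dot-product self-attention for one head
#'
#' Computes `softmax(Q K^T / sqrt(dk)) V` with `Q = H W^Q`, `K = H W^K`,
#' `V = H W^V`; every softmax row sums to 1.
#'
#' @param hidden Hidden-state matrix, `N x d_model`.
#' @param params An [attention_params()].
#' @param head Head index (1-based).
#' @return The attended values, `N x dk`.
#' @export
standard_attention <- function(hidden, params, head = 1L) {
  .check_hidden(hidden, params, head)
  Q <- hidden %*% params$wq[[head]]
  K <- hidden %*% params$wk[[head]]
  V <- hidden %*% params$wv[[head]]
  .softmax_rows(Q %*% t(K) / sqrt(params$dk)) %*% V
}

#' Structure-augmented molecule self-attention for one head
#'
#' Mixes the attention softmax with the normalized distance matrix, the
#' adjacency matrix, and the hydrogen-bond matrix:
#' `(la * softmax(Q K^T / sqrt(dk)) + ld * g(D) + lg * A + lh * Hbond) V`.
#' With `lambda_a = 1`, `lambda_d = lambda_g = 0` and a zero hydrogen-bond
#' matrix this reduces exactly to [standard_attention()]; with
#' `lambda_h = 0` (or a zero `hbond`) it is the plain
#' adjacency/distance-augmented attention, which serves as the ablation
#' baseline.
#'
#' @inheritParams standard_attention
#' @param adjacency,distance,hbond Symmetric `N x N` descriptor matrices.
#' @return The attended values, `N x dk`.
#' @export
molecule_self_attention <- function(hidden, adjacency, distance, hbond,
                                    params, head = 1L) {
  .check_hidden(hidden, params, head)
  n <- nrow(hidden)
  for (M in list(adjacency, distance, hbond)) {
    if (!is.matrix(M) || nrow(M) != n || ncol(M) != n) {
      .raise("math_shape_error",
             "descriptor matrices must be N x N with N = nrow(hidden)")
    }
  }
  Q <- hidden %*% params$wq[[head]]
  K <- hidden %*% params$wk[[head]]
  V <- hidden %*% params$wv[[head]]
  mix <- params$lambda_a * .softmax_rows(Q %*% t(K) / sqrt(params$dk)) +
    params$lambda_d * normalize_distance(distance,
                                         params$distance_normalizer) +
    params$lambda_g * adjacency +
    params$lambda_h * hbond
  mix %*% V
}
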