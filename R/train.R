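# Training (Adam, mini-batch BCE), k-fold cross-validation and the
# hydrogen-bond threshold sweep experiment.

# the featurizer_config *argument* of the training functions shadows the
# constructor of the same name inside their bodies
.default_fc <- function() featurizer_config()

#' Featurize a set of SMILES in one batched call
#'
#' Parses and embeds all molecules in a single helper invocation (results
#' are memoised for the session), then assembles the descriptor sets.
#' Molecules that fail to parse or embed are dropped with a warning rather
#' than aborting the batch.
#'
#' @param smiles Character vector of SMILES.
#' @param config A [featurizer_config()].
#' @return A named list of `DescriptorSet`s (names are the input SMILES);
#'   failed molecules are absent, with the failure reasons in the
#'   `"failures"` attribute.
#' @export
featurize_set <- function(smiles, config = featurizer_config()) {
  stopifnot(is.character(smiles))
  uniq <- unique(smiles)
  .mol_query("embed", uniq, seed = config$seed,
             max_attempts = config$max_attempts)   # warm cache in one batch
  out <- list()
  failures <- character(0)
  for (s in smiles) {
    d <- tryCatch(featurize(s, config), error = function(e) e)
    if (inherits(d, "error")) {
      failures[s] <- conditionMessage(d)
    } else {
      out[[s]] <- d
    }
  }
  if (length(failures)) {
    warning(length(failures), " molecule(s) could not be featurized and ",
            "were skipped", call. = FALSE)
  }
  attr(out, "failures") <- failures
  out
}

## ---- nested-list numeric tree helpers (weights, grads, Adam moments) ----

.tree_map2 <- function(a, b, f) {
  if (is.list(a)) {
    if (!is.null(names(a))) b <- b[names(a)]   # align leaves by name
    out <- mapply(.tree_map2, a, b, MoreArgs = list(f = f), SIMPLIFY = FALSE)
    attributes(out) <- attributes(a)
    out
  } else f(a, b)
}

.tree_map <- function(a, f) {
  if (is.list(a)) {
    out <- lapply(a, .tree_map, f = f)
    attributes(out) <- attributes(a)
    out
  } else f(a)
}

.adam_step <- function(w, g, state, lr, beta1, beta2, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- .tree_map2(state$m, g, function(m, g) beta1 * m + (1 - beta1) * g)
  state$v <- .tree_map2(state$v, g,
                        function(v, g) beta2 * v + (1 - beta2) * g^2)
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  upd <- .tree_map2(state$m, state$v,
                    function(m, v) lr * (m / c1) / (sqrt(v / c2) + eps))
  state$w <- .tree_map2(w, upd, `-`)
  state
}

.records_labels <- function(records) {
  stopifnot(is.data.frame(records), "canonical_smiles" %in% names(records),
            "label" %in% names(records))
  .as_binary_labels(records$label)
}

#' Train the hydrogen-bond-augmented attention classifier
#'
#' Mini-batch training with the Adam optimizer and binary cross-entropy on
#' the logistic output, for a fixed number of epochs (no early stopping).
#' Deterministic given `(records, configs, seed)` on a single CPU.
#'
#' @param records Data frame with `canonical_smiles` and `label`
#'   (`"active"`/`"inactive"`) columns.
#' @param featurizer_config A [featurizer_config()].
#' @param model_config A [math_config()].
#' @param seed Seed controlling weight initialization and batch shuffling.
#' @param descriptors Optional pre-computed named list of `DescriptorSet`s
#'   (as from [featurize_set()]) to avoid re-featurizing.
#' @return An object of class `math_model`: weights, both configs, the
#'   per-epoch mean training loss, and the number of molecules trained on.
#' @export
train_model <- function(records, featurizer_config = NULL,
                        model_config = math_config("test"), seed = 1L,
                        descriptors = NULL) {
  if (is.null(featurizer_config)) featurizer_config <- .default_fc()
  y_all <- .records_labels(records)
  if (length(unique(y_all)) < 2L) {
    .raise("math_single_class_error",
           "training set must contain both classes")
  }
  if (is.null(descriptors)) {
    descriptors <- featurize_set(records$canonical_smiles, featurizer_config)
  }
  keep <- records$canonical_smiles %in% names(descriptors)
  if (!all(keep)) records <- records[keep, , drop = FALSE]
  y <- .records_labels(records)
  descs <- descriptors[records$canonical_smiles]
  n <- length(descs)
  if (n < 2L || length(unique(y)) < 2L) {
    .raise("math_single_class_error",
           "not enough featurizable molecules in both classes")
  }

  cfg <- model_config
  weights <- math_init_weights(cfg, d_feat = ncol(descs[[1]]$node_features),
                               seed = seed)
  state <- list(t = 0L,
                m = .tree_map(weights, function(x) x * 0),
                v = .tree_map(weights, function(x) x * 0),
                w = weights)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed + 1L)
  loss_curve <- numeric(cfg$epochs)
  for (epoch in seq_len(cfg$epochs)) {
    ord <- sample.int(n)
    epoch_loss <- 0
    for (start in seq(1L, n, by = cfg$batch_size)) {
      idx <- ord[start:min(start + cfg$batch_size - 1L, n)]
      grads <- NULL
      for (i in idx) {
        fw <- .forward_cache(descs[[i]], state$w, cfg)
        p <- min(max(fw$prob, 1e-12), 1 - 1e-12)
        epoch_loss <- epoch_loss - (y[i] * log(p) + (1 - y[i]) * log(1 - p))
        g <- .backward(fw, descs[[i]], y[i], state$w, cfg)
        grads <- if (is.null(grads)) g else .tree_map2(grads, g, `+`)
      }
      grads <- .tree_map(grads, function(x) x / length(idx))
      state <- .adam_step(state$w, grads, state, cfg$lr, cfg$beta1, cfg$beta2)
    }
    loss_curve[epoch] <- epoch_loss / n
  }
  structure(list(weights = state$w, model_config = cfg,
                 featurizer_config = featurizer_config,
                 loss_curve = loss_curve, n_train = n, seed = seed),
            class = "math_model")
}

#' @export
print.math_model <- function(x, ...) {
  cat("<math_model> ", x$model_config$n_blocks, " blocks, ",
      x$model_config$heads, " heads, d_model ", x$model_config$d_model,
      "; trained on ", x$n_train, " molecules for ",
      x$model_config$epochs, " epochs (final loss ",
      sprintf("%.4f", utils::tail(x$loss_curve, 1)), ")\n", sep = "")
  invisible(x)
}

#' Predict activity probabilities
#'
#' @param object A `math_model`.
#' @param newdata SMILES character vector, a records data frame with a
#'   `canonical_smiles` column, or a list of `DescriptorSet`s.
#' @param ... Unused.
#' @return Numeric vector of `P(active)`, `NA` for molecules that fail to
#'   featurize.
#' @export
predict.math_model <- function(object, newdata, ...) {
  if (is.data.frame(newdata)) newdata <- newdata$canonical_smiles
  if (is.character(newdata)) {
    descs <- featurize_set(newdata, object$featurizer_config)
    out <- rep(NA_real_, length(newdata))
    hit <- newdata %in% names(descs)
    out[hit] <- vapply(descs[newdata[hit]], math_forward, numeric(1),
                       weights = object$weights,
                       config = object$model_config)
    return(out)
  }
  vapply(newdata, math_forward, numeric(1),
         weights = object$weights, config = object$model_config)
}

#' Stratified k-fold cross-validation
#'
#' Splits the records into `k` stratified folds (class proportions
#' preserved within one record per fold), trains on `k - 1` folds and
#' evaluates on the held-out fold, and reports per-fold and mean metrics.
#' The best fold is the one with the highest F1 score.
#'
#' @inheritParams train_model
#' @param k Number of folds (>= 2).
#' @return A list of class `math_cv`: `folds` (per-fold `EvalReport`s),
#'   `fold_assignments`, `mean` (named vector of fold-averaged metrics),
#'   `best_fold` and `models`.
#' @export
cross_validate <- function(records, k = 5L, featurizer_config = NULL,
                           model_config = math_config("test"), seed = 1L,
                           descriptors = NULL) {
  if (is.null(featurizer_config)) featurizer_config <- .default_fc()
  stopifnot(k >= 2L)
  y <- .records_labels(records)
  if (min(table(y)) < k) {
    stop("stratification impossible: a class has fewer than k members",
         call. = FALSE)
  }
  if (is.null(descriptors)) {
    descriptors <- featurize_set(records$canonical_smiles, featurizer_config)
  }
  keep <- records$canonical_smiles %in% names(descriptors)
  records <- records[keep, , drop = FALSE]
  y <- .records_labels(records)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  folds <- caret::createFolds(factor(y), k = k)
  reports <- vector("list", k)
  models <- vector("list", k)
  assignment <- integer(nrow(records))
  for (f in seq_len(k)) {
    test_idx <- folds[[f]]
    assignment[test_idx] <- f
    fit <- train_model(records[-test_idx, , drop = FALSE],
                       featurizer_config, model_config, seed = seed,
                       descriptors = descriptors)
    probs <- predict(fit, records$canonical_smiles[test_idx])
    reports[[f]] <- confusion_and_metrics(y[test_idx], probs,
                                          model_config$threshold)
    models[[f]] <- fit
  }
  metric_names <- c("roc_auc", "precision", "recall", "f1", "specificity")
  mean_metrics <- vapply(metric_names, function(m) {
    mean(vapply(reports, function(r) r[[m]], numeric(1)), na.rm = TRUE)
  }, numeric(1))
  f1s <- vapply(reports, function(r) r$f1 %||% NA_real_, numeric(1))
  structure(list(folds = reports, fold_assignments = assignment,
                 mean = mean_metrics,
                 best_fold = which.max(ifelse(is.na(f1s), -Inf, f1s)),
                 models = models, k = k, seed = seed),
            class = "math_cv")
}

#' @export
print.math_cv <- function(x, ...) {
  cat("<math_cv> ", x$k, "-fold cross-validation\n  mean:  ", sep = "")
  cat(paste(names(x$mean), sprintf("%.4f", x$mean), collapse = "  "), "\n")
  cat("  best fold by F1:", x$best_fold, "\n")
  invisible(x)
}

#' Hydrogen-bond threshold sweep experiment
#'
#' Re-featurizes the data at each distance threshold (the conformer is
#' shared, so only the hydrogen-bond matrix changes), optionally adds the
#' Boolean-mode setting, runs cross-validation per setting with a shared
#' seed, and tabulates the fold-averaged metrics. A setting that fails is
#' reported as an `NA` row rather than aborting the sweep.
#'
#' @inheritParams cross_validate
#' @param thresholds Ascending positive distance thresholds in Angstrom
#'   (default the 2.2-4.0 grid in 0.2 steps).
#' @param include_boolean Include the Boolean-mode setting (default
#'   threshold) as the first row.
#' @return A data frame of class `math_sweep` with one row per setting and
#'   columns `setting`, `dthreshold`, `n_evaluated`, `roc_auc`, `precision`,
#'   `recall`, `f1`, `specificity`, plus a `best` attribute naming the
#'   argmax setting per metric and a `reports` attribute with the full
#'   `math_cv` objects.
#' @export
run_sweep <- function(records, thresholds = seq(2.2, 4.0, by = 0.2),
                      include_boolean = TRUE, k = 5L,
                      featurizer_config = NULL,
                      model_config = math_config("test"), seed = 1L) {
  if (is.null(featurizer_config)) featurizer_config <- .default_fc()
  stopifnot(all(thresholds > 0), !is.unsorted(thresholds))
  settings <- list()
  if (include_boolean) {
    fc <- featurizer_config
    fc$mode <- "boolean"
    fc$dthreshold <- 3.0
    settings[["boolean"]] <- fc
  }
  for (t in thresholds) {
    fc <- featurizer_config
    fc$mode <- "distance"
    fc$dthreshold <- t
    settings[[sprintf("dist<%.1f", t)]] <- fc
  }
  rows <- list()
  reports <- list()
  # settings are derived by editing a copy of the base config: the conformer
  # (and hence the cache) is shared, only the detection threshold changes
  for (nm in names(settings)) {
    fc <- settings[[nm]]
    res <- tryCatch(cross_validate(records, k = k, featurizer_config = fc,
                                   model_config = model_config, seed = seed),
                    error = function(e) e)
    if (inherits(res, "error")) {
      warning("sweep setting ", nm, " failed: ", conditionMessage(res),
              call. = FALSE)
      rows[[nm]] <- data.frame(setting = nm, dthreshold = fc$dthreshold,
                               n_evaluated = 0L, roc_auc = NA_real_,
                               precision = NA_real_, recall = NA_real_,
                               f1 = NA_real_, specificity = NA_real_)
    } else {
      reports[[nm]] <- res
      n_eval <- sum(vapply(res$folds, function(r) r$n, integer(1)))
      rows[[nm]] <- data.frame(setting = nm, dthreshold = fc$dthreshold,
                               n_evaluated = n_eval,
                               roc_auc = res$mean[["roc_auc"]],
                               precision = res$mean[["precision"]],
                               recall = res$mean[["recall"]],
                               f1 = res$mean[["f1"]],
                               specificity = res$mean[["specificity"]])
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  metric_names <- c("roc_auc", "precision", "recall", "f1", "specificity")
  best <- vapply(metric_names, function(m) {
    v <- out[[m]]
    if (all(is.na(v))) NA_character_ else out$setting[which.max(v)]
  }, character(1))
  attr(out, "best") <- best
  attr(out, "reports") <- reports
  class(out) <- c("math_sweep", class(out))
  out
}

#' Save / load a trained model as a single JSON checkpoint
#'
#' The checkpoint carries the weights together with both configurations, so
#' the hydrogen-bond threshold and embedding seed travel with the model.
#'
#' @param model A `math_model`.
#' @param path File path.
#' @return `save_math_model` returns `path` invisibly; `load_math_model`
#'   returns the restored `math_model`.
#' @export
save_math_model <- function(model, path) {
  stopifnot(inherits(model, "math_model"))
  payload <- list(
    weights = unclass(model$weights),
    model_config = unclass(model$model_config),
    featurizer_config = unclass(model$featurizer_config),
    loss_curve = model$loss_curve, n_train = model$n_train,
    seed = model$seed)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_math_model
#' @export
load_math_model <- function(path) {
  # rebuild the weight tree from unsimplified JSON: named lists are
  # sub-trees, unnamed lists of numbers are vectors, unnamed lists of
  # unnamed lists are matrices (rows)
  p <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  restore <- function(x) {
    if (!is.list(x)) return(as.numeric(x))
    if (!is.null(names(x))) return(lapply(x, restore))
    if (all(vapply(x, is.numeric, logical(1)))) return(as.numeric(unlist(x)))
    if (all(vapply(x, function(e) is.list(e) && is.null(names(e)),
                   logical(1)))) {
      return(do.call(rbind, lapply(x, function(r) as.numeric(unlist(r)))))
    }
    lapply(x, restore)
  }
  weights <- restore(p$weights)
  class(weights) <- "math_weights"
  p$loss_curve <- as.numeric(unlist(p$loss_curve))
  mc <- p$model_config
  model_config <- math_config(
    profile = mc$profile, n_blocks = mc$n_blocks, heads = mc$heads,
    d_model = mc$d_model, d_ff = mc$d_ff, batch_size = mc$batch_size,
    epochs = mc$epochs, lr = mc$lr, beta1 = mc$beta1, beta2 = mc$beta2,
    dropout = mc$dropout, pooling = mc$pooling, threshold = mc$threshold,
    lambda_a = mc$lambda_a, lambda_d = mc$lambda_d, lambda_g = mc$lambda_g,
    lambda_h = mc$lambda_h, distance_normalizer = mc$distance_normalizer)
  fc <- p$featurizer_config
  featurizer_config <- featurizer_config(
    dthreshold = fc$dthreshold, mode = fc$mode, seed = fc$seed,
    strict_literal = fc$strict_literal, exclude_13 = fc$exclude_13,
    distance_mode = fc$distance_mode, max_attempts = fc$max_attempts)
  structure(list(weights = weights, model_config = model_config,
                 featurizer_config = featurizer_config,
                 loss_curve = p$loss_curve, n_train = p$n_train,
                 seed = p$seed),
            class = "math_model")
}
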