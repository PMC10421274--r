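# Shared small training fixture: prepared records + cached descriptors.
fixture_records <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      tab <- generate_bioactivity_table(fixture_spec(n_molecules = 60,
                                                     seed = 7))
      cache <<- suppressMessages(prepare_bioactivity(tab, seed = 42))
    }
    cache
  }
})

test_that("training reduces the loss and is deterministic under a fixed seed", {
  recs <- fixture_records()
  cfg <- math_config("test", epochs = 5)
  fit1 <- train_model(recs, model_config = cfg, seed = 1)
  expect_s3_class(fit1, "math_model")
  expect_length(fit1$loss_curve, 5L)
  expect_lt(fit1$loss_curve[5], fit1$loss_curve[1])
  fit2 <- train_model(recs, model_config = cfg, seed = 1)
  expect_identical(fit1$loss_curve, fit2$loss_curve)
  expect_identical(fit1$weights, fit2$weights)
})

test_that("training refuses a single-class set", {
  recs <- fixture_records()
  only_active <- recs[recs$label == "active", ]
  expect_error(train_model(only_active, model_config = math_config("test")),
               class = "math_single_class_error")
})

test_that("the trained model ranks the planted H-bond signal above chance", {
  recs <- fixture_records()
  cfg <- math_config("test", epochs = 8)
  fit <- train_model(recs, model_config = cfg, seed = 2)
  probs <- predict(fit, recs$canonical_smiles)
  expect_true(all(probs >= 0 & probs <= 1))
  r <- confusion_and_metrics(recs$label, probs)
  expect_gt(r$roc_auc, 0.5)
})

test_that("predictions are identical for identical molecules", {
  recs <- fixture_records()
  fit <- train_model(recs, model_config = math_config("test", epochs = 2),
                     seed = 3)
  smi <- recs$canonical_smiles[1]
  p <- predict(fit, c(smi, smi))
  expect_equal(p[1], p[2])
})

test_that("cross-validation builds disjoint stratified folds covering all records", {
  recs <- fixture_records()
  cv <- cross_validate(recs, k = 5,
                       model_config = math_config("test", epochs = 2),
                       seed = 4)
  expect_s3_class(cv, "math_cv")
  expect_length(cv$folds, 5L)
  sizes <- vapply(cv$folds, function(r) r$n, integer(1))
  expect_equal(sum(sizes), nrow(recs))
  expect_true(max(sizes) - min(sizes) <= 2)
  expect_setequal(unique(cv$fold_assignments), 1:5)
  # stratification: per-fold active ratio within one record of global
  y <- as.integer(recs$label == "active")
  global <- mean(y)
  for (f in 1:5) {
    idx <- which(cv$fold_assignments == f)
    expect_lte(abs(sum(y[idx]) - global * length(idx)), 1)
  }
  # summary is the arithmetic mean of the fold metrics
  expect_equal(cv$mean[["f1"]],
               mean(vapply(cv$folds, function(r) r$f1, numeric(1)),
                    na.rm = TRUE))
  expect_equal(cv$best_fold,
               which.max(vapply(cv$folds, function(r) r$f1, numeric(1))))
})

test_that("cross-validation is reproducible given the seed", {
  recs <- fixture_records()
  cfg <- math_config("test", epochs = 2)
  cv1 <- cross_validate(recs, k = 3, model_config = cfg, seed = 6)
  cv2 <- cross_validate(recs, k = 3, model_config = cfg, seed = 6)
  expect_identical(cv1$fold_assignments, cv2$fold_assignments)
  expect_identical(cv1$mean, cv2$mean)
})

test_that("the threshold sweep reports every setting with populated metrics", {
  recs <- fixture_records()
  sw <- run_sweep(recs, thresholds = c(2.2, 3.0), include_boolean = TRUE,
                  k = 2, model_config = math_config("test", epochs = 2),
                  seed = 5)
  expect_equal(nrow(sw), 3L)
  expect_equal(sw$setting, c("boolean", "dist<2.2", "dist<3.0"))
  expect_equal(sw$dthreshold[2:3], c(2.2, 3.0))
  for (m in c("roc_auc", "precision", "recall", "f1", "specificity")) {
    expect_true(all(is.finite(sw[[m]]) | is.na(sw[[m]])))
    expect_false(all(is.na(sw[[m]])))
  }
  expect_equal(sw$n_evaluated, rep(nrow(recs), 3))
  best <- attr(sw, "best")
  expect_true(all(best %in% sw$setting))
  expect_error(run_sweep(recs, thresholds = c(3.0, 2.2)))
})

test_that("model checkpoints round-trip through JSON", {
  recs <- fixture_records()
  fit <- train_model(recs, model_config = math_config("test", epochs = 2),
                     seed = 9)
  path <- withr::local_tempfile(fileext = ".json")
  save_math_model(fit, path)
  back <- load_math_model(path)
  smi <- recs$canonical_smiles[1:5]
  expect_equal(predict(back, smi), predict(fit, smi), tolerance = 1e-12)
  expect_equal(back$model_config$d_model, fit$model_config$d_model)
  expect_equal(back$featurizer_config$dthreshold,
               fit$featurizer_config$dthreshold)
})
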