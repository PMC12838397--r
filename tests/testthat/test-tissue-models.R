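# Stratified splitting, standardization, screening, lasso fitting and
# slide-level evaluation.

test_that("stratified split hits the 70:30 target within one slide per stratum", {
  rec <- data.frame(slide_id = sprintf("s%03d", 1:100),
                    tissue = "liver",
                    rin = seq(1, 10, length.out = 100))
  sp <- stratified_split(rec, test_fraction = 0.3, seed = 4)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_setequal(c(sp$train, sp$test), rec$slide_id)
  expect_lte(abs(length(sp$test) - 30), 4) # 4 strata x (<=1 slide each)
  # per-stratum bookkeeping: 4 tissues of 25 slides -> 7-8 test slides each
  rec4 <- data.frame(slide_id = sprintf("t%03d", 1:100),
                     tissue = rep(c("a", "b", "c", "d"), each = 25),
                     rin = rep(6, 100))
  sp4 <- stratified_split(rec4, test_fraction = 0.3, seed = 4)
  per <- table(rec4$tissue[rec4$slide_id %in% sp4$test])
  expect_true(all(per %in% 7:8))
})

test_that("stratified split is reproducible and rejects empty input", {
  rec <- data.frame(slide_id = sprintf("s%03d", 1:50), tissue = "a",
                    rin = runif(50, 2, 9))
  expect_identical(stratified_split(rec, seed = 11),
                   stratified_split(rec, seed = 11))
  expect_error(stratified_split(rec[0, ]), "no records")
})

test_that("standardization z-scores kept columns and drops constants", {
  X <- cbind(a = c(1, 2, 3), b = c(5, 5, 5), c = c(0, 10, 20))
  sc <- standardize_features(X)
  expect_equal(sc$dropped, 2L)
  expect_equal(unname(sc$X[, 1]), c(-1, 0, 1))
  expect_true(all(abs(colMeans(sc$X)) < 1e-8))
  expect_true(all(abs(apply(sc$X, 2, sd) - 1) < 1e-8))
  expect_identical(apply_scaler(sc, X), sc$X)
  expect_error(standardize_features(cbind(rep(1, 3), rep(2, 3))), "zero variance")
})

test_that("correlation screening returns ceil(fraction * F) features, best first", {
  set.seed(21)
  X <- matrix(rnorm(60 * 100), 60)
  y <- rnorm(60)
  idx <- select_top_correlated(X, y, 0.05)
  expect_length(idx, 5)
  # feature equal to the target always ranks first
  X2 <- cbind(X, y)
  expect_identical(select_top_correlated(X2, y, 0.05)[1], 101L)
  # brute-force |r| sort oracle on a 40-feature instance
  X3 <- matrix(rnorm(50 * 40), 50)
  r_oracle <- vapply(seq_len(40), function(j) {
    xj <- X3[, j]
    sum((xj - mean(xj)) * (y[1:50] - mean(y[1:50]))) /
      sqrt(sum((xj - mean(xj))^2) * sum((y[1:50] - mean(y[1:50]))^2))
  }, numeric(1))
  expect_identical(select_top_correlated(X3, y[1:50], 0.25),
                   order(-abs(r_oracle), seq_len(40))[1:10])
  expect_error(select_top_correlated(X, rep(1, 60)), "zero variance")
})

test_that("lambda at or above lambda_max yields the null model", {
  set.seed(31)
  X <- scale(matrix(rnorm(80 * 10), 80))
  y <- rnorm(80)
  fit <- fit_lasso(X, y, seed = 1)
  path <- fit$glmnet_fit
  expect_true(all(abs(path$beta[, 1]) == 0)) # first grid value = lambda_max
  expect_equal(unname(path$a0[1]), mean(y), tolerance = 1e-10)
  expect_equal(length(fit$lambda_grid), 100L)
})

test_that("orthonormal-design coefficients match the soft-threshold closed form", {
  n <- 64
  H <- stats::contr.helmert(n)[, 1:8]
  U <- sweep(H, 2, sqrt(colSums(H^2)), "/") # orthonormal, mean-zero columns
  set.seed(30)
  rot <- qr.Q(qr(matrix(rnorm(64), 8))) # random rotation keeps t(X)X = n I
  X <- sqrt(n) * U %*% rot # dense design
  y <- 3 * X[, 1]
  fit <- fit_lasso(X, y, seed = 2)
  lam <- fit$lambda
  expect_equal(lam, max(abs(crossprod(X, y)) / n) * 1e-4, tolerance = 1e-8)
  expect_equal(unname(fit$beta[1]), 3 - lam, tolerance = 1e-6)
  expect_true(all(fit$beta[-1] == 0))
  expect_equal(fit$intercept, 0, tolerance = 1e-10)
})

test_that("sparsity is monotone along the regularization path", {
  set.seed(33)
  X <- scale(matrix(rnorm(100 * 30), 100))
  y <- X[, 1] - 2 * X[, 2] + rnorm(100)
  fit <- fit_lasso(X, y, seed = 3)
  df <- fit$glmnet_fit$df # lambda decreases along the path
  expect_true(all(diff(df) >= 0))
})

test_that("cross-validated lambda beats the intercept-only model on planted signal", {
  ds <- shared_dataset()
  rec <- ds$manifest
  sc <- standardize_features(ds$X)
  fit <- fit_lasso(sc$X, rec$rin, seed = 5)
  null_mse <- mean((rec$rin - mean(rec$rin))^2)
  expect_lt(min(fit$cvm), null_mse)
})

test_that("outer CV pools exactly one held-out prediction per slide", {
  ds <- shared_dataset()
  cv <- cross_validate_tissue(ds$manifest, ds$X, "rin", seed = 6)
  expect_identical(sort(cv$predictions$slide_id), sort(ds$manifest$slide_id))
  expect_false(anyNA(cv$predictions$predicted))
  held_out <- unlist(lapply(cv$folds, `[[`, "held_out_slide_ids"))
  expect_identical(sort(held_out), sort(ds$manifest$slide_id)) # partition
  expect_gt(cv$pooled_r, 0.5)
})

test_that("fold models never see their held-out labels", {
  ds <- shared_dataset()
  rec <- ds$manifest
  cv1 <- cross_validate_tissue(rec, ds$X, "rin", seed = 7)
  fold1_ids <- cv1$folds[[1]]$held_out_slide_ids
  # scramble the labels of fold-1 slides; their own held-out predictions
  # must be unchanged because fold 1 is excluded from that model's training
  rec2 <- rec
  scramble <- match(fold1_ids, rec2$slide_id)
  rec2$rin[scramble] <- rev(rec2$rin[scramble])
  cv2 <- cross_validate_tissue(rec2, ds$X, "rin", seed = 7)
  expect_identical(cv1$folds[[1]]$predictions, cv2$folds[[1]]$predictions)
})

test_that("label-shuffled CV correlation concentrates near zero", {
  ds <- shared_dataset()
  rec <- ds$manifest
  rec$rin <- with_seed_sample(rec$rin, 99)
  cv <- cross_validate_tissue(rec, ds$X, "rin", seed = 8)
  expect_lte(abs(cv$pooled_r), 3 / sqrt(nrow(rec)))
})

test_that("final training ignores the test split and round-trips through disk", {
  ds <- shared_dataset_500()
  sp <- stratified_split(ds$manifest, 0.3, seed = 9)
  res <- train_final_and_test(ds$manifest, ds$X, sp$train, sp$test, "rin",
                              seed = 9)
  expect_gt(res$test_r, 0.6)
  expect_error(
    train_final_and_test(ds$manifest, ds$X, sp$train, c(sp$test, sp$train[1]),
                         "rin"),
    "overlap"
  )
  dir <- withr::local_tempdir()
  save_bundle(res$model, dir)
  reloaded <- load_bundle(dir)
  probe <- ds$X[sp$test, , drop = FALSE]
  expect_identical(predict(res$model, probe), predict(reloaded, probe))
})

test_that("shuffled test labels break the prediction-observation correlation", {
  ds <- shared_dataset_500()
  sp <- stratified_split(ds$manifest, 0.4, seed = 10)
  rec <- ds$manifest
  te_rows <- rec$slide_id %in% sp$test
  rec$rin[te_rows] <- with_seed_sample(rec$rin[te_rows], 123)
  res <- train_final_and_test(rec, ds$X, sp$train, sp$test, "rin", seed = 10)
  expect_lte(abs(res$test_r), 0.2)
})

test_that("selected features recover the planted signal coordinates", {
  ds <- shared_dataset_500()
  rec <- ds$manifest
  sc <- standardize_features(ds$X)
  idx <- select_top_correlated(sc$X, rec$rin, 0.05)
  planted <- ds$truth$signal_features # mean-block columns of the embedding
  expect_true(all(planted %in% sc$kept[idx]))
})

test_that("autolysis class accuracy rounds then clips to the ordinal scale", {
  obs <- c(0L, 1L, 2L, 3L, 2L)
  expect_equal(autolysis_class_accuracy(obs, obs), 1)
  expect_equal(autolysis_class_accuracy(obs + 0.4, obs), 1)
  expect_equal(autolysis_class_accuracy(c(0, 1, 2) + 0.6, c(0L, 1L, 2L)), 0)
  expect_equal(autolysis_class_accuracy(c(-5, 9), c(0L, 3L)), 1) # clipping
  expect_error(autolysis_class_accuracy(1:3, 1:2), "length mismatch")
})
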