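# Tissue-specific quality models: stratified splitting, feature
# standardization and screening, L1-penalized regression with cross-validated
# penalty selection, and slide-level evaluation.
#
# The regression objective is the standard lasso,
#   beta* = argmin_beta 1/(2N) ||y - X beta||_2^2 + lambda ||beta||_1,
# fit with glmnet (alpha = 1) over a 100-value log-spaced lambda grid from
# lambda_max (all coefficients zero) down to lambda_max * 1e-4; lambda_min is
# the grid value with smallest mean held-out MSE under 5-fold CV.

#' Train/test split stratified by tissue and RIN quartile
#'
#' RIN quartile breaks are computed on the full labeled cohort before
#' splitting. Within each tissue, quartile strata with fewer than 2 members
#' are merged into the nearest non-empty quartile of the same tissue; slides
#' with missing RIN form their own stratum per tissue. Each stratum is split
#' so the test share is within one slide of `test_fraction`.
#'
#' @param records data frame of slide records (columns `slide_id`, `tissue`,
#'   `rin`, ...).
#' @param test_fraction fraction assigned to the test split (default 0.3).
#' @param seed RNG seed; the split is reproducible for a fixed seed.
#' @return List with character vectors `train` and `test` of slide ids
#'   (disjoint, union = all ids).
#' @export
stratified_split <- function(records, test_fraction = 0.3, seed = 1L) {
  if (nrow(records) == 0L) stop_pathqc("no records to split")
  stopifnot(test_fraction > 0, test_fraction < 1)
  rin <- records$rin
  if (any(!is.na(rin))) {
    breaks <- unique(quantile(rin, probs = seq(0, 1, 0.25), na.rm = TRUE))
    qbin <- if (length(breaks) >= 2L) {
      as.integer(cut(rin, breaks = breaks, include.lowest = TRUE))
    } else {
      rep(1L, length(rin))
    }
  } else {
    qbin <- rep(1L, length(rin))
  }
  qbin[is.na(qbin)] <- 0L # missing-RIN stratum
  stratum <- paste(records$tissue, qbin, sep = "|")

  # merge strata of size < 2 into the nearest quartile within the same tissue
  for (ti in unique(records$tissue)) {
    in_t <- records$tissue == ti
    repeat {
      counts <- table(qbin[in_t])
      small <- names(counts)[counts < 2L]
      if (length(small) == 0L || length(counts) == 1L) break
      b <- as.integer(small[1])
      others <- as.integer(setdiff(names(counts), small[1]))
      nearest <- others[which.min(abs(others - b))]
      qbin[in_t & qbin == b] <- nearest
    }
  }
  stratum <- paste(records$tissue, qbin, sep = "|")

  test_ids <- with_local_seed(seed, {
    unlist(lapply(split(records$slide_id, stratum), function(ids) {
      n_test <- round(length(ids) * test_fraction)
      sample(ids, n_test)
    }), use.names = FALSE)
  })
  list(train = setdiff(records$slide_id, test_ids), test = test_ids)
}

#' Z-score features and drop zero-variance columns
#'
#' @param X N x F numeric matrix (N >= 2), columns optionally named.
#' @return Object of class `feature_scaler`: list with `X` (standardized
#'   matrix over kept columns), `means`, `sds`, `kept` (column indices) and
#'   `dropped`. Apply to new data with [apply_scaler()].
#' @export
standardize_features <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 2L) stop_pathqc("need at least 2 rows to standardize")
  means <- colMeans(X)
  sds <- apply(X, 2, sd)
  kept <- which(sds > 1e-10)
  if (length(kept) == 0L) stop_pathqc("all features have zero variance")
  Xs <- sweep(sweep(X[, kept, drop = FALSE], 2, means[kept], "-"), 2, sds[kept], "/")
  structure(
    list(X = Xs, means = means[kept], sds = sds[kept], kept = kept,
         dropped = setdiff(seq_len(ncol(X)), kept),
         feature_names = colnames(X)),
    class = "feature_scaler"
  )
}

#' @rdname standardize_features
#' @param scaler a `feature_scaler`.
#' @param newdata matrix with the same columns as the fitting matrix.
#' @return Standardized matrix over the kept columns.
#' @export
apply_scaler <- function(scaler, newdata) {
  stopifnot(inherits(scaler, "feature_scaler"))
  newdata <- as.matrix(newdata)
  sweep(sweep(newdata[, scaler$kept, drop = FALSE], 2, scaler$means, "-"),
        2, scaler$sds, "/")
}

#' Select the features most correlated with the target
#'
#' Returns the `ceiling(fraction * F)` column indices with the largest
#' absolute Pearson correlation with `y`; ties are broken by lower index, and
#' constant features rank last.
#'
#' @param X N x F numeric matrix.
#' @param y numeric target vector.
#' @param fraction fraction of features to keep (default 0.05, the top 5%).
#' @return Integer vector of column indices, in decreasing |r| order.
#' @export
select_top_correlated <- function(X, y, fraction = 0.05) {
  X <- as.matrix(X)
  if (ncol(X) < 1L) stop_pathqc("no features to select from")
  if (sd(y) == 0) stop_pathqc("target has zero variance")
  r <- suppressWarnings(as.vector(cor(X, y)))
  absr <- abs(r)
  absr[!is.finite(absr)] <- -Inf
  k <- ceiling(fraction * ncol(X))
  order(-absr, seq_along(absr))[seq_len(k)]
}

#' Fit a lasso with cross-validated penalty selection
#'
#' Fits the L1-penalized least-squares path on a 100-value log-spaced lambda
#' grid (from lambda_max, where every coefficient is zero, down to
#' lambda_max * 1e-4), selects lambda_min by `n_folds`-fold CV on minimum mean
#' squared error, and refits on all rows at lambda_min.
#'
#' @param X standardized N x F design matrix (no further standardization is
#'   applied).
#' @param y numeric response.
#' @param n_folds CV folds for the penalty search (default 5).
#' @param seed seed controlling fold assignment.
#' @param foldid optional explicit fold assignment (overrides `seed`).
#' @return Object of class `lasso_fit`: `beta` (named length-F vector, zeros
#'   included), `intercept`, `lambda` (the selected lambda_min), `lambda_grid`,
#'   `cvm` (mean CV MSE per grid value), `alpha` (always 1), and the
#'   underlying `glmnet_fit` for path inspection.
#' @export
fit_lasso <- function(X, y, n_folds = 5L, seed = 1L, foldid = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < n_folds) stop_pathqc("N = %d is smaller than n_folds = %d", n, n_folds)
  padded <- FALSE
  if (ncol(X) == 1L) { # glmnet requires >= 2 columns
    X <- cbind(X, `.pad` = 0)
    padded <- TRUE
  }
  if (is.null(foldid)) {
    foldid <- with_local_seed(seed, sample(rep(seq_len(n_folds), length.out = n)))
  }
  # explicit grid: glmnet's own path stops early once the deviance plateaus,
  # but the full 100-value sequence down to lambda_max * 1e-4 is part of the
  # fitting contract
  lambda_max <- max(abs(crossprod(X, y - mean(y))) / n)
  if (lambda_max <= 0) stop_pathqc("all features are uncorrelated with the target")
  grid <- exp(seq(log(lambda_max), log(lambda_max * 1e-4), length.out = 100L))
  cvfit <- glmnet::cv.glmnet(
    X, y, alpha = 1, family = "gaussian", foldid = foldid,
    lambda = grid, standardize = FALSE, type.measure = "mse"
  )
  cf <- as.matrix(coef(cvfit, s = "lambda.min"))
  beta <- cf[-1, 1]
  if (padded) beta <- beta[-length(beta)]
  structure(
    list(beta = beta, intercept = cf[1, 1], lambda = cvfit$lambda.min,
         lambda_grid = cvfit$lambda, cvm = cvfit$cvm, alpha = 1,
         glmnet_fit = cvfit$glmnet.fit),
    class = "lasso_fit"
  )
}

#' @export
predict.lasso_fit <- function(object, newdata, ...) {
  as.vector(object$intercept + as.matrix(newdata) %*% object$beta)
}

#' Fit a tissue-specific quality model
#'
#' Full per-tissue fitting recipe: z-score features and drop zero-variance
#' columns, screen to the top `top_fraction` features most correlated with the
#' target, then fit the lasso with cross-validated lambda. All fitting
#' decisions derive from the supplied rows only, so the function can be called
#' inside outer CV folds without leakage.
#'
#' @param X N x F slide-embedding matrix (rownames = slide ids).
#' @param y numeric target (RIN in `[1,10]` or autolysis 0-3).
#' @param tissue,target labels stored on the model.
#' @param top_fraction correlation-screening fraction (default 0.05; use 1 to
#'   keep all features).
#' @param n_folds,seed,foldid passed to [fit_lasso()].
#' @return Object of class `quality_model` holding the standardization
#'   parameters, selected feature indices (into the original columns), sparse
#'   coefficients, intercept and lambda.
#' @export
fit_quality_model <- function(X, y, tissue = "all", target = "rin",
                              top_fraction = 0.05, n_folds = 5L, seed = 1L,
                              foldid = NULL) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y))
  scaler <- standardize_features(X)
  sel_std <- if (top_fraction >= 1) {
    seq_len(ncol(scaler$X))
  } else {
    select_top_correlated(scaler$X, y, fraction = top_fraction)
  }
  fit <- fit_lasso(scaler$X[, sel_std, drop = FALSE], y,
                   n_folds = n_folds, seed = seed, foldid = foldid)
  selected <- scaler$kept[sel_std]
  structure(
    list(tissue = tissue, target = target,
         feature_means = scaler$means[sel_std],
         feature_sds = scaler$sds[sel_std],
         selected_features = selected,
         feature_names = scaler$feature_names,
         coefficients = fit$beta, intercept = fit$intercept,
         lambda = fit$lambda, alpha = 1,
         lambda_grid = fit$lambda_grid, cv_mse = min(fit$cvm),
         n_train = nrow(X)),
    class = "quality_model"
  )
}

#' @export
predict.quality_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  Z <- sweep(sweep(newdata[, object$selected_features, drop = FALSE],
                   2, object$feature_means, "-"),
             2, object$feature_sds, "/")
  as.vector(object$intercept + Z %*% object$coefficients)
}

#' @export
print.quality_model <- function(x, ...) {
  cat(sprintf("quality_model: target=%s tissue=%s | %d/%d nonzero coefficients, lambda=%.4g\n",
              x$target, x$tissue, sum(x$coefficients != 0),
              length(x$coefficients), x$lambda))
  invisible(x)
}

# Bin a target for stratified fold assignment: quartiles for continuous
# targets, the raw categories for ordinal ones.
bin_target <- function(y, target) {
  if (target == "autolysis") return(as.integer(round(y)))
  breaks <- unique(quantile(y, probs = seq(0, 1, 0.25)))
  if (length(breaks) < 2L) return(rep(1L, length(y)))
  as.integer(cut(y, breaks = breaks, include.lowest = TRUE))
}

# Seed-controlled fold assignment, optionally stratified within bins.
make_foldid <- function(n, n_folds, seed, strata = NULL) {
  with_local_seed(seed, {
    foldid <- integer(n)
    if (is.null(strata)) strata <- rep(1L, n)
    for (s in unique(strata)) {
      idx <- which(strata == s)
      foldid[idx] <- sample(rep(seq_len(n_folds), length.out = length(idx)))
    }
    foldid
  })
}

#' Cross-validate a tissue-specific quality model
#'
#' Outer `n_folds`-fold cross-validation at the slide level. Within each fold,
#' standardization, correlation screening and the lambda search are all refit
#' on the fold's training portion only; held-out predictions are pooled across
#' folds (exactly one prediction per slide) and summarized by pooled Pearson R
#' and pooled RMSE.
#'
#' @param records slide records containing `slide_id` and the target column;
#'   slides with a missing target are excluded from this task.
#' @param X slide-embedding matrix with rownames = slide ids.
#' @param target `"rin"` or `"autolysis"`.
#' @param n_folds outer folds (default 5).
#' @param seed controls outer fold assignment and inner lambda-search folds.
#' @param top_fraction correlation-screening fraction (default 0.05).
#' @param stratified if `TRUE`, outer folds are stratified by the binned
#'   target (quartiles for RIN, categories for autolysis).
#' @return Object of class `tissue_cv`: list of per-fold results (`fold_index`,
#'   `held_out_slide_ids`, `predictions`, `fold_r`), `pooled_r`, `pooled_rmse`
#'   and a `predictions` data frame.
#' @export
cross_validate_tissue <- function(records, X, target = c("rin", "autolysis"),
                                  n_folds = 5L, seed = 1L, top_fraction = 0.05,
                                  stratified = FALSE) {
  target <- match.arg(target)
  keep <- !is.na(records[[target]])
  if (!any(keep)) stop_pathqc("target '%s' is missing for all slides", target)
  rec <- records[keep, , drop = FALSE]
  if (nrow(rec) < n_folds) {
    stop_pathqc("only %d slides with %s present; need >= %d folds",
                nrow(rec), target, n_folds)
  }
  X <- as.matrix(X)[rec$slide_id, , drop = FALSE]
  y <- rec[[target]]
  strata <- if (stratified) bin_target(y, target) else NULL
  foldid <- make_foldid(nrow(rec), n_folds, seed, strata)
  folds <- vector("list", n_folds)
  pred <- setNames(rep(NA_real_, nrow(rec)), rec$slide_id)
  for (k in seq_len(n_folds)) {
    tr <- foldid != k
    model <- fit_quality_model(X[tr, , drop = FALSE], y[tr],
                               target = target, top_fraction = top_fraction,
                               n_folds = n_folds, seed = seed + k)
    yhat <- predict(model, X[!tr, , drop = FALSE])
    ids <- rec$slide_id[!tr]
    pred[ids] <- yhat
    folds[[k]] <- list(fold_index = k, held_out_slide_ids = ids,
                       predictions = setNames(yhat, ids),
                       fold_r = pearson_r(yhat, y[!tr]))
  }
  structure(
    list(folds = folds,
         pooled_r = pearson_r(unname(pred), y),
         pooled_rmse = rmse(unname(pred), y),
         fold_r = vapply(folds, `[[`, numeric(1), "fold_r"),
         predictions = data.frame(slide_id = rec$slide_id, observed = y,
                                  predicted = unname(pred), fold = foldid,
                                  stringsAsFactors = FALSE)),
    class = "tissue_cv"
  )
}

#' Train a final model on the training split and evaluate once on the test set
#'
#' All fitting decisions (standardization, screening, lambda) derive from the
#' training rows only; test metrics are computed a single time.
#'
#' @param records slide records (all splits).
#' @param X embedding matrix with rownames = slide ids.
#' @param train_ids,test_ids disjoint slide-id vectors.
#' @param target `"rin"` or `"autolysis"`.
#' @inheritParams cross_validate_tissue
#' @return List with `model` ([fit_quality_model()] result), `test_r`,
#'   `test_rmse` and a `predictions` data frame for the test slides.
#' @export
train_final_and_test <- function(records, X, train_ids, test_ids,
                                 target = c("rin", "autolysis"),
                                 top_fraction = 0.05, n_folds = 5L, seed = 1L) {
  target <- match.arg(target)
  if (length(intersect(train_ids, test_ids)) > 0L) {
    stop_pathqc("train and test ids overlap (%d shared)",
                length(intersect(train_ids, test_ids)))
  }
  X <- as.matrix(X)
  lab <- records[!is.na(records[[target]]), , drop = FALSE]
  tr <- lab[lab$slide_id %in% train_ids, , drop = FALSE]
  te <- lab[lab$slide_id %in% test_ids, , drop = FALSE]
  model <- fit_quality_model(X[tr$slide_id, , drop = FALSE], tr[[target]],
                             target = target, top_fraction = top_fraction,
                             n_folds = n_folds, seed = seed)
  yhat <- predict(model, X[te$slide_id, , drop = FALSE])
  list(model = model,
       test_r = pearson_r(yhat, te[[target]]),
       test_rmse = rmse(yhat, te[[target]]),
       predictions = data.frame(slide_id = te$slide_id, observed = te[[target]],
                                predicted = yhat, stringsAsFactors = FALSE))
}

#' Classification accuracy of continuous autolysis predictions
#'
#' Predictions are rounded to the nearest integer (R's `round()`, ties to
#' even), clipped to the 0-3 ordinal scale, and compared exactly to the
#' observed classes.
#'
#' @param predictions numeric predictions on the autolysis scale.
#' @param observed integer observed scores in `{0, 1, 2, 3}`.
#' @return Fraction of exact matches.
#' @export
autolysis_class_accuracy <- function(predictions, observed) {
  if (length(predictions) != length(observed)) {
    stop_pathqc("length mismatch: %d predictions vs %d observations",
                length(predictions), length(observed))
  }
  cls <- pmin(pmax(round(predictions), 0), 3)
  mean(cls == observed)
}
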