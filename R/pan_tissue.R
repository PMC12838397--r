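# Two-stage pan-tissue framework: a multinomial L1 tissue classifier on
# ANOVA-F-selected features routes each slide, under a confidence threshold,
# to tissue-specific quality models trained on the full feature set.

#' Select the most tissue-discriminative features by one-way ANOVA F-score
#'
#' Computes the one-way ANOVA F statistic of each feature across tissue
#' groups and returns the top `k` features. Features with zero between-group
#' variance (including constants) rank last; ties break by lower index.
#'
#' @param X N x F numeric matrix.
#' @param tissue_labels group labels, at least 2 classes with >= 2 samples
#'   each.
#' @param k number of features to keep (default 500; capped at F with a
#'   warning).
#' @return Integer vector of `k` column indices in decreasing F order, with
#'   the full F-score vector attached as attribute `"f_scores"`.
#' @export
anova_f_select <- function(X, tissue_labels, k = 500L) {
  X <- as.matrix(X)
  g <- factor(tissue_labels)
  if (nlevels(g) < 2L) stop_pathqc("need at least 2 tissue classes for ANOVA F selection")
  if (any(table(g) < 2L)) stop_pathqc("every tissue class needs >= 2 samples")
  if (k > ncol(X)) {
    warning(sprintf("k = %d exceeds feature count %d; returning all features", k, ncol(X)))
    k <- ncol(X)
  }
  n <- nrow(X)
  ng <- as.vector(table(g))
  grp_means <- rowsum(X, g) / ng
  overall <- colMeans(X)
  ssb <- colSums(ng * sweep(grp_means, 2, overall, "-")^2)
  ssw <- colSums(X^2) - colSums(ng * grp_means^2)
  df1 <- nlevels(g) - 1L
  df2 <- n - nlevels(g)
  tol <- 1e-12 * (colSums(X^2) + 1)
  f <- (ssb / df1) / (pmax(ssw, 0) / df2)
  # zero within-group variance: perfectly separating feature -> +Inf;
  # feature constant everywhere (F undefined) -> ranked last
  f[ssw <= tol] <- ifelse(ssb[ssw <= tol] > tol[ssw <= tol], Inf, -Inf)
  f[is.na(f) | is.nan(f)] <- -Inf
  structure(order(-f, seq_along(f))[seq_len(k)], f_scores = f)
}

#' Fit a multinomial lasso tissue classifier
#'
#' Multinomial logistic regression with a pure L1 penalty (alpha = 1); the
#' penalty strength is chosen by stratified `n_folds`-fold cross-validation at
#' minimum mean deviance. Pooled held-out (prevalidated) class predictions at
#' the selected penalty give the cross-validated accuracy.
#'
#' @param X numeric design matrix (already standardized upstream).
#' @param tissue_labels class labels; every class needs >= `n_folds` members.
#' @param n_folds stratified CV folds (default 5).
#' @param seed controls fold assignment.
#' @return Object of class `tissue_classifier` with per-class coefficient
#'   vectors (`beta`, F x C) and `intercepts`, the selected `lambda`,
#'   `cv_accuracy`, and pooled held-out class predictions (`cv_class`).
#' @export
fit_tissue_classifier <- function(X, tissue_labels, n_folds = 5L, seed = 1L) {
  X <- as.matrix(X)
  g <- factor(tissue_labels)
  counts <- table(g)
  if (any(counts < n_folds)) {
    bad <- names(counts)[counts < n_folds]
    stop_pathqc(paste0("class(es) %s have fewer than n_folds = %d members; ",
                       "drop these tissues or reduce n_folds"),
                paste(bad, collapse = ", "), n_folds)
  }
  foldid <- make_foldid(nrow(X), n_folds, seed, strata = as.integer(g))
  cvfit <- glmnet::cv.glmnet(
    X, g, family = "multinomial", alpha = 1, foldid = foldid,
    type.measure = "deviance", standardize = FALSE, keep = TRUE
  )
  idx <- which(cvfit$lambda == cvfit$lambda.min)[1]
  cl <- coef(cvfit, s = "lambda.min")
  beta <- do.call(cbind, lapply(cl, function(m) as.matrix(m)[-1, 1]))
  intercepts <- vapply(cl, function(m) as.matrix(m)[1, 1], numeric(1))
  colnames(beta) <- levels(g)
  # prevalidated link-scale fits -> pooled held-out class predictions
  preval <- cvfit$fit.preval[, , idx]
  cv_class <- levels(g)[max.col(preval, ties.method = "first")]
  structure(
    list(classes = levels(g), beta = beta, intercepts = intercepts,
         lambda = cvfit$lambda.min,
         cv_accuracy = mean(cv_class == as.character(g)),
         cv_class = cv_class),
    class = "tissue_classifier"
  )
}

#' Class probabilities from a fitted tissue classifier
#'
#' Softmax over the per-class linear predictors (glmnet's symmetric
#' multinomial parametrization).
#'
#' @param object a `tissue_classifier`.
#' @param newdata matrix with the same columns the classifier was fit on.
#' @param ... unused.
#' @return N x C matrix of probabilities; rows sum to 1.
#' @export
predict.tissue_classifier <- function(object, newdata, ...) {
  eta <- sweep(as.matrix(newdata) %*% object$beta, 2, object$intercepts, "+")
  eta <- eta - apply(eta, 1, max)
  p <- exp(eta)
  p / rowSums(p)
}

#' Fit the full pan-tissue model
#'
#' On the complete-label subset (slides with both RIN and autolysis present):
#' standardizes the embedding matrix, selects the top `k` tissue-discriminative
#' features by ANOVA F-score, fits the multinomial lasso tissue classifier,
#' and trains per-tissue quality models for RIN and autolysis on all features
#' with fold assignment stratified by RIN quartiles and autolysis categories
#' respectively.
#'
#' @param records slide records for the training split.
#' @param X embedding matrix, rownames = slide ids.
#' @param k ANOVA-F feature count for the classifier (default 500).
#' @param confidence_threshold routing threshold (default 0.6, inclusive).
#' @param n_folds,seed CV controls.
#' @return Object of class `pan_tissue_model`: `scaler`, `selected_features`
#'   (indices into the standardized columns), `classifier`, `tissue_registry`
#'   (tissue -> list(rin, autolysis) of [fit_quality_model()] objects), and
#'   `confidence_threshold`.
#' @export
fit_pan_tissue <- function(records, X, k = 500L, confidence_threshold = 0.6,
                           n_folds = 5L, seed = 1L) {
  complete <- !is.na(records$rin) & !is.na(records$autolysis)
  rec <- records[complete, , drop = FALSE]
  if (nrow(rec) < 2L) stop_pathqc("too few complete-label slides for the pan-tissue model")
  X <- as.matrix(X)[rec$slide_id, , drop = FALSE]
  scaler <- standardize_features(X)
  sel <- anova_f_select(scaler$X, rec$tissue, k = k)
  classifier <- fit_tissue_classifier(scaler$X[, sel, drop = FALSE], rec$tissue,
                                      n_folds = n_folds, seed = seed)
  registry <- list()
  for (ti in classifier$classes) {
    rows <- rec$tissue == ti
    Xt <- X[rows, , drop = FALSE]
    rt <- rec[rows, , drop = FALSE]
    fid_rin <- make_foldid(nrow(rt), n_folds, seed + 1L, bin_target(rt$rin, "rin"))
    fid_aut <- make_foldid(nrow(rt), n_folds, seed + 2L, bin_target(rt$autolysis, "autolysis"))
    registry[[ti]] <- list(
      rin = fit_quality_model(Xt, rt$rin, tissue = ti, target = "rin",
                              top_fraction = 1, n_folds = n_folds,
                              foldid = fid_rin),
      autolysis = fit_quality_model(Xt, rt$autolysis, tissue = ti,
                                    target = "autolysis", top_fraction = 1,
                                    n_folds = n_folds, foldid = fid_aut)
    )
  }
  structure(
    list(scaler = scaler[c("means", "sds", "kept")], selected_features = sel,
         classifier = classifier, tissue_registry = registry,
         confidence_threshold = confidence_threshold,
         feature_names = colnames(X)),
    class = "pan_tissue_model"
  )
}

#' Route slide embeddings to tissue-specific quality models
#'
#' Classifies each slide's tissue from its embedding; a slide is covered iff
#' its top-class probability meets the confidence threshold (inclusive).
#' Covered slides (or all slides when `fallback = TRUE`) receive RIN and
#' autolysis predictions from the matching tissue's quality models.
#'
#' @param embeddings a single embedding vector, a [aggregate_slide()] result,
#'   or an N x 4d matrix with slide-id rownames.
#' @param model a [fit_pan_tissue()] model.
#' @param fallback if `TRUE`, non-covered slides are still routed by the
#'   argmax class and flagged via `covered = FALSE`.
#' @return Data frame with columns `slide_id`, `predicted_tissue`,
#'   `confidence`, `covered`, `rin_pred`, `autolysis_pred` (NA when withheld),
#'   plus the class-probability matrix as attribute `"probabilities"`.
#' @export
route_and_predict <- function(embeddings, model, fallback = FALSE) {
  stopifnot(inherits(model, "pan_tissue_model"))
  if (inherits(embeddings, "slide_embedding")) {
    embeddings <- matrix(embeddings$vector, nrow = 1,
                         dimnames = list(embeddings$slide_id, names(embeddings$vector)))
  }
  if (is.null(dim(embeddings))) embeddings <- matrix(embeddings, nrow = 1)
  X <- as.matrix(embeddings)
  sc <- model$scaler
  Z <- sweep(sweep(X[, sc$kept, drop = FALSE], 2, sc$means, "-"), 2, sc$sds, "/")
  probs <- predict(model$classifier, Z[, model$selected_features, drop = FALSE])
  best <- max.col(probs, ties.method = "first")
  tissue <- model$classifier$classes[best]
  confidence <- probs[cbind(seq_len(nrow(probs)), best)]
  covered <- confidence >= model$confidence_threshold
  rin_pred <- rep(NA_real_, nrow(X))
  aut_pred <- rep(NA_real_, nrow(X))
  for (i in seq_len(nrow(X))) {
    if (covered[i] || fallback) {
      reg <- model$tissue_registry[[tissue[i]]]
      if (is.null(reg)) {
        stop_pathqc("predicted tissue '%s' is absent from the model registry", tissue[i])
      }
      rin_pred[i] <- predict(reg$rin, X[i, , drop = FALSE])
      aut_pred[i] <- predict(reg$autolysis, X[i, , drop = FALSE])
    }
  }
  ids <- rownames(X)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(X)))
  out <- data.frame(slide_id = ids, predicted_tissue = tissue,
                    confidence = confidence, covered = covered,
                    rin_pred = rin_pred, autolysis_pred = aut_pred,
                    stringsAsFactors = FALSE)
  rownames(probs) <- ids
  attr(out, "probabilities") <- probs
  out
}

# Macro F1 over the classes present in the truth labels; per-class F1 is 0
# when a class has no predicted or no true positives.
macro_f1 <- function(truth, predicted) {
  classes <- sort(unique(truth))
  f1 <- vapply(classes, function(cl) {
    tp <- sum(predicted == cl & truth == cl)
    fp <- sum(predicted == cl & truth != cl)
    fn <- sum(predicted != cl & truth == cl)
    if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }, numeric(1))
  mean(f1)
}

binary_auc <- function(is_case, score) {
  if (length(unique(is_case)) < 2L) return(NA_real_)
  as.numeric(pROC::auc(pROC::roc(
    response = is_case, predictor = score,
    levels = c(FALSE, TRUE), direction = "<", quiet = TRUE
  )))
}

#' Evaluate the pan-tissue framework on routed predictions
#'
#' @param routed output of [route_and_predict()] (with its probability
#'   attribute) for the evaluation slides.
#' @param truth slide records matching `routed$slide_id`.
#' @return List report: tissue-classification `accuracy`, `macro_f1`,
#'   `macro_auc` (unweighted mean of one-vs-rest AUCs), `pairwise_auc`
#'   (one-vs-one matrix), `coverage`, and — on covered slides — pooled and
#'   per-tissue RIN Pearson R / RMSE plus autolysis Pearson R and rounded
#'   class accuracy.
#' @export
evaluate_pan <- function(routed, truth) {
  if (!all(routed$slide_id %in% truth$slide_id)) {
    stop_pathqc("routed predictions contain slide ids absent from the truth records")
  }
  truth <- truth[match(routed$slide_id, truth$slide_id), , drop = FALSE]
  probs <- attr(routed, "probabilities")
  classes <- colnames(probs)
  acc <- mean(routed$predicted_tissue == truth$tissue)
  ovr <- vapply(classes, function(cl) {
    binary_auc(truth$tissue == cl, probs[, cl])
  }, numeric(1))
  pair <- matrix(NA_real_, length(classes), length(classes),
                 dimnames = list(classes, classes))
  for (i in seq_along(classes)) {
    for (j in seq_along(classes)) {
      if (i >= j) next
      sub <- truth$tissue %in% classes[c(i, j)]
      if (!any(sub)) next
      pi <- probs[sub, classes[i]]
      pj <- probs[sub, classes[j]]
      score <- pi / pmax(pi + pj, .Machine$double.xmin)
      pair[i, j] <- pair[j, i] <- binary_auc(truth$tissue[sub] == classes[i], score)
    }
  }
  cov_frac <- mean(routed$covered)
  on_cov <- routed$covered
  rin_ok <- on_cov & !is.na(truth$rin) & !is.na(routed$rin_pred)
  aut_ok <- on_cov & !is.na(truth$autolysis) & !is.na(routed$autolysis_pred)
  per_tissue <- lapply(split(which(rin_ok), truth$tissue[rin_ok]), function(idx) {
    list(rin_r = pearson_r(routed$rin_pred[idx], truth$rin[idx]),
         rin_rmse = rmse(routed$rin_pred[idx], truth$rin[idx]),
         n = length(idx))
  })
  list(
    accuracy = acc,
    macro_f1 = macro_f1(truth$tissue, routed$predicted_tissue),
    macro_auc = mean(ovr, na.rm = TRUE),
    ovr_auc = ovr,
    pairwise_auc = pair,
    coverage = cov_frac,
    rin_r = pearson_r(routed$rin_pred[rin_ok], truth$rin[rin_ok]),
    rin_rmse = if (any(rin_ok)) rmse(routed$rin_pred[rin_ok], truth$rin[rin_ok]) else NA_real_,
    rin_per_tissue = per_tissue,
    autolysis_r = pearson_r(routed$autolysis_pred[aut_ok], truth$autolysis[aut_ok]),
    autolysis_accuracy = if (any(aut_ok)) {
      autolysis_class_accuracy(routed$autolysis_pred[aut_ok], truth$autolysis[aut_ok])
    } else NA_real_,
    n = nrow(routed)
  )
}
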