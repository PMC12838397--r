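# Descriptive and diagnostic analyses: confounder variance decomposition,
# RIN-autolysis correlation, feature importance and sharing, fold stability,
# and preservation-percentile robustness.

#' Variance in a quality metric explained by each covariate
#'
#' For each covariate independently, fits a univariate linear model of the
#' target on that covariate (categorical covariates one-hot encoded via
#' factors) and reports its R-squared. Fractions from independent univariate
#' fits need not sum to 1. With `method = "joint"` all covariates enter one
#' model and each fraction is the partial (type-II) sum of squares over the
#' total sum of squares.
#'
#' @param records slide records; covariates among `tissue`, `hardy`, `age`,
#'   `sex` plus the other quality metric (`autolysis` when `target = "rin"`
#'   and vice versa).
#' @param target `"rin"` or `"autolysis"`.
#' @param covariates covariate columns to assess.
#' @param method `"univariate"` (default) or `"joint"`.
#' @return Object of class `variance_report`: data frame with `covariate`,
#'   `fraction` (R-squared in `[0,1]`, `NA` for covariates entirely missing)
#'   and `n`.
#' @export
variance_explained <- function(records, target = c("rin", "autolysis"),
                               covariates = NULL,
                               method = c("univariate", "joint")) {
  target <- match.arg(target)
  method <- match.arg(method)
  other <- if (target == "rin") "autolysis" else "rin"
  if (is.null(covariates)) {
    covariates <- intersect(c("tissue", "hardy", other, "age", "sex"),
                            names(records))
  }
  y <- records[[target]]
  if (length(unique(y[!is.na(y)])) < 2L) {
    stop_pathqc("target '%s' has fewer than 2 distinct values", target)
  }
  as_term <- function(v) {
    if (is.character(v) || is.logical(v)) factor(v) else v
  }
  if (method == "univariate") {
    rows <- lapply(covariates, function(cv) {
      v <- records[[cv]]
      if (all(is.na(v))) {
        return(data.frame(covariate = cv, fraction = NA_real_, n = 0L))
      }
      ok <- !is.na(y) & !is.na(v)
      x <- as_term(v[ok])
      if (length(unique(x)) < 2L) {
        return(data.frame(covariate = cv, fraction = NA_real_, n = sum(ok)))
      }
      fit <- lm(y[ok] ~ x)
      data.frame(covariate = cv, fraction = summary(fit)$r.squared, n = sum(ok))
    })
    out <- do.call(rbind, rows)
  } else {
    dat <- data.frame(.y = y, lapply(records[covariates], as_term))
    names(dat) <- c(".y", covariates)
    dat <- dat[complete.cases(dat), , drop = FALSE]
    fit <- lm(.y ~ ., data = dat)
    d1 <- stats::drop1(fit, test = "F") # partial (type-II) sums of squares
    tot <- sum((dat$.y - mean(dat$.y))^2)
    frac <- d1[["Sum of Sq"]][-1] / tot
    out <- data.frame(covariate = rownames(d1)[-1], fraction = frac,
                      n = nrow(dat))
  }
  rownames(out) <- NULL
  attr(out, "target") <- target
  attr(out, "method") <- method
  class(out) <- c("variance_report", "data.frame")
  out
}

#' Per-tissue Spearman correlation between RIN and autolysis
#'
#' Spearman rank correlation with average ranks for ties and a two-sided
#' asymptotic p-value, computed per tissue on slides where both metrics are
#' present. Significance stars: `***` p < 0.001, `**` p < 0.01, `*` p < 0.05,
#' `ns` otherwise.
#'
#' @param records slide records with `tissue`, `rin`, `autolysis`.
#' @param min_pairs minimum paired observations per tissue (default 4).
#' @return Data frame with `tissue`, `rho`, `p_value`, `stars`, `n`; `rho` is
#'   `NA` when either variable is all-tied within a tissue.
#' @export
rin_autolysis_correlation <- function(records, min_pairs = 4L) {
  ok <- !is.na(records$rin) & !is.na(records$autolysis)
  rec <- records[ok, , drop = FALSE]
  rows <- lapply(sort(unique(rec$tissue)), function(ti) {
    sub <- rec[rec$tissue == ti, , drop = FALSE]
    n <- nrow(sub)
    if (n < min_pairs) {
      return(data.frame(tissue = ti, rho = NA_real_, p_value = NA_real_,
                        stars = NA_character_, n = n))
    }
    if (length(unique(sub$rin)) < 2L || length(unique(sub$autolysis)) < 2L) {
      return(data.frame(tissue = ti, rho = NA_real_, p_value = NA_real_,
                        stars = NA_character_, n = n))
    }
    ct <- suppressWarnings(
      cor.test(sub$rin, sub$autolysis, method = "spearman",
               alternative = "two.sided", exact = FALSE)
    )
    data.frame(tissue = ti, rho = unname(ct$estimate), p_value = ct$p.value,
               stars = significance_stars(ct$p.value), n = n)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @rdname rin_autolysis_correlation
#' @param p p-value(s).
#' @export
significance_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "ns")))
}

# Original-feature names with nonzero coefficients in one quality model.
nonzero_features <- function(model) {
  stopifnot(inherits(model, "quality_model"))
  idx <- model$selected_features[model$coefficients != 0]
  nm <- model$feature_names
  if (is.null(nm)) as.character(idx) else nm[idx]
}

#' Feature selection-frequency matrix and cross-target sharing
#'
#' For one target, a feature's frequency is the number of tissues whose model
#' assigns it a nonzero coefficient. The global top-`top_n` features are taken
#' by frequency (ties by lower feature index). When models for the second
#' target are supplied, the overlap of the two top-`top_n` sets is reported.
#'
#' @param models named list (by tissue) of [fit_quality_model()] objects for
#'   the first target.
#' @param models2 optional named list for the second target.
#' @param top_n number of global top features (default 20).
#' @return List with `frequency` (tissue x feature 0/1 matrix), `counts`
#'   (per-feature selection counts), `top_features`; plus `frequency2`,
#'   `counts2`, `top_features2` and `overlap` when `models2` is given.
#' @export
feature_importance_matrix <- function(models, models2 = NULL, top_n = 20L) {
  build <- function(ms) {
    stopifnot(length(ms) >= 1L, !is.null(names(ms)))
    feats <- sort(unique(unlist(lapply(ms, nonzero_features))))
    mat <- matrix(0L, length(ms), length(feats),
                  dimnames = list(names(ms), feats))
    for (ti in names(ms)) {
      mat[ti, nonzero_features(ms[[ti]])] <- 1L
    }
    counts <- colSums(mat)
    top <- colnames(mat)[order(-counts, seq_along(counts))][seq_len(min(top_n, length(counts)))]
    list(frequency = mat, counts = counts, top_features = top)
  }
  a <- build(models)
  if (is.null(models2)) {
    return(a)
  }
  b <- build(models2)
  c(a,
    list(frequency2 = b$frequency, counts2 = b$counts,
         top_features2 = b$top_features,
         overlap = intersect(a$top_features, b$top_features)))
}

#' Hierarchically cluster a feature-importance matrix
#'
#' Agglomerative complete-linkage clustering on Euclidean distances, applied
#' independently to rows and to columns.
#'
#' @param mat numeric matrix with >= 2 rows and >= 2 columns, no missing
#'   values.
#' @return List with `row_order`, `col_order` (leaf orders) and the `hclust`
#'   trees `row_tree`, `col_tree`.
#' @export
hierarchical_cluster <- function(mat) {
  mat <- as.matrix(mat)
  if (anyNA(mat)) stop_pathqc("matrix contains missing values")
  if (nrow(mat) < 2L || ncol(mat) < 2L) stop_pathqc("need >= 2 rows and columns")
  rt <- hclust(dist(mat, method = "euclidean"), method = "complete")
  ct <- hclust(dist(t(mat), method = "euclidean"), method = "complete")
  list(row_order = rt$order, col_order = ct$order,
       row_tree = rt, col_tree = ct)
}

#' Fold-stability coefficient of variation
#'
#' CV = sigma / mu of the per-fold correlation coefficients (sample SD,
#' divisor n-1). Models with CV below 0.2 are labelled stable, above 0.5
#' unstable, otherwise intermediate. A non-positive mean leaves CV undefined
#' and the model is flagged unstable with a warning.
#'
#' @param fold_correlations numeric vector of per-fold correlations (>= 2).
#' @param tissue optional label carried on the report.
#' @return Object of class `stability_report`: list with `tissue`,
#'   `fold_correlations`, `mean`, `sd`, `cv`, `label`.
#' @export
stability_cv <- function(fold_correlations, tissue = NA_character_) {
  if (length(fold_correlations) < 2L) stop_pathqc("need >= 2 fold correlations")
  mu <- mean(fold_correlations)
  sigma <- sd(fold_correlations)
  if (mu <= 0) {
    warning("mean fold correlation is non-positive; CV undefined, labelling unstable")
    cv <- NA_real_
    label <- "unstable"
  } else {
    cv <- sigma / mu
    label <- if (cv < 0.2) "stable" else if (cv > 0.5) "unstable" else "intermediate"
  }
  structure(
    list(tissue = tissue, fold_correlations = fold_correlations,
         mean = mu, sd = sigma, cv = cv, label = label),
    class = "stability_report"
  )
}

#' Preservation-percentile robustness curve
#'
#' Sorts slides by observed quality and progressively removes the
#' highest-quality ones: at each preservation percentile `q`, slides with
#' observed value at or below the q-th percentile are retained and the
#' Pearson correlation between predictions and observations is recomputed on
#' the retained subset. `q = 100` reproduces the full-sample correlation
#' exactly.
#'
#' @param predicted,observed paired numeric vectors (>= 10 pairs).
#' @param percentile_steps preservation percentiles (default 100, 90, ..., 30).
#' @param min_subset subsets smaller than this report `NA` (default 5).
#' @return Data frame with `percentile`, `n_retained`, `r` (`NA` when the
#'   subset is too small or the observed values are constant within it).
#' @export
preservation_percentile <- function(predicted, observed,
                                    percentile_steps = seq(100, 30, by = -10),
                                    min_subset = 5L) {
  if (length(predicted) != length(observed)) {
    stop_pathqc("length mismatch: %d vs %d", length(predicted), length(observed))
  }
  if (length(observed) < 10L) stop_pathqc("need >= 10 paired observations")
  rows <- lapply(percentile_steps, function(q) {
    cutoff <- quantile(observed, q / 100, names = FALSE)
    keep <- observed <= cutoff
    n <- sum(keep)
    r <- if (n < min_subset || length(unique(observed[keep])) < 2L) {
      NA_real_
    } else {
      pearson_r(predicted[keep], observed[keep])
    }
    data.frame(percentile = q, n_retained = n, r = r)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
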