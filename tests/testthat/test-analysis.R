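# Variance decomposition, quality-metric correlation, feature sharing,
# stability and preservation-percentile analyses.

test_that("variance explained is 1 for a covariate that determines the target", {
  set.seed(61)
  rec <- data.frame(
    slide_id = sprintf("s%d", 1:60),
    tissue = rep(c("liver", "lung", "colon"), each = 20),
    autolysis = NA_real_, hardy = NA_real_, age = rnorm(60, 50), sex = "female"
  )
  means <- c(liver = 4, lung = 7, colon = 9)
  rec$rin <- unname(means[rec$tissue])
  vr <- suppressWarnings( # exact fit trips lm's perfect-fit warning
    variance_explained(rec, "rin", covariates = c("tissue", "age"))
  )
  expect_equal(vr$fraction[vr$covariate == "tissue"], 1, tolerance = 1e-12)
  expect_true(all(vr$fraction >= 0 & vr$fraction <= 1, na.rm = TRUE))
})

test_that("a two-group toy decomposes as the hand ANOVA fraction 0.8", {
  rec <- data.frame(slide_id = sprintf("s%d", 1:4),
                    tissue = c("g0", "g0", "g1", "g1"),
                    rin = c(1, 3, 5, 7))
  vr <- variance_explained(rec, "rin", covariates = "tissue")
  # between-group SS = 2*(2-4)^2 + 2*(6-4)^2 = 16; total SS = 20
  expect_equal(vr$fraction, 16 / 20, tolerance = 1e-12)
})

test_that("independent covariates explain almost nothing at n = 1000", {
  set.seed(62)
  n <- 1000
  rec <- data.frame(slide_id = sprintf("s%d", 1:n),
                    tissue = sample(letters[1:5], n, replace = TRUE),
                    rin = rnorm(n, 7))
  vr <- variance_explained(rec, "rin", covariates = "tissue")
  expect_lte(vr$fraction, 0.02)
})

test_that("variance fractions are invariant to affine covariate transforms", {
  set.seed(63)
  rec <- data.frame(slide_id = sprintf("s%d", 1:80),
                    age = runif(80, 20, 70))
  rec$rin <- 5 + 0.03 * rec$age + rnorm(80, sd = 0.5)
  v1 <- variance_explained(rec, "rin", covariates = "age")$fraction
  rec$age <- 3 * rec$age - 40
  v2 <- variance_explained(rec, "rin", covariates = "age")$fraction
  expect_equal(v1, v2, tolerance = 1e-12)
})

test_that("entirely missing covariates are reported as absent, not zero", {
  rec <- data.frame(slide_id = sprintf("s%d", 1:10),
                    tissue = rep(c("a", "b"), 5),
                    hardy = NA_real_, rin = rnorm(10, 7))
  vr <- variance_explained(rec, "rin", covariates = c("tissue", "hardy"))
  expect_true(is.na(vr$fraction[vr$covariate == "hardy"]))
})

test_that("Spearman correlation handles the textbook rank example", {
  # one tissue with ranks (1,2,3,4) vs (2,1,4,3): rho = 1 - 6*4/(4*15) = 0.6
  rec <- data.frame(slide_id = sprintf("s%d", 1:4), tissue = "colon",
                    rin = c(1, 2, 3, 4), autolysis = c(1, 0, 3, 2))
  out <- rin_autolysis_correlation(rec)
  expect_equal(out$rho, 0.6, tolerance = 1e-12)
  expect_identical(out$stars, "ns") # n = 4, p >> 0.05
})

test_that("monotone decreasing pairs give rho -1 with significance stars", {
  rec <- data.frame(slide_id = sprintf("s%d", 1:20), tissue = "adrenal",
                    rin = seq(2, 9, length.out = 20),
                    autolysis = rep(3:0, each = 5))
  out <- rin_autolysis_correlation(rec)
  expect_lt(out$rho, -0.9)
  expect_true(out$stars %in% c("*", "**", "***"))
  expect_identical(significance_stars(c(0.0005, 0.005, 0.03, 0.2)),
                   c("***", "**", "*", "ns"))
})

test_that("tissues with all-tied values report a missing correlation", {
  rec <- data.frame(slide_id = sprintf("s%d", 1:6), tissue = "brain",
                    rin = rep(7, 6), autolysis = c(0, 1, 2, 0, 1, 2))
  out <- rin_autolysis_correlation(rec)
  expect_true(is.na(out$rho))
})

fake_quality_model <- function(tissue, nonzero_idx, n_features = 12) {
  structure(
    list(tissue = tissue, target = "rin",
         feature_means = rep(0, length(nonzero_idx)),
         feature_sds = rep(1, length(nonzero_idx)),
         selected_features = nonzero_idx,
         feature_names = sprintf("f%02d", seq_len(n_features)),
         coefficients = rep(0.5, length(nonzero_idx)),
         intercept = 0, lambda = 0.1, alpha = 1),
    class = "quality_model"
  )
}

test_that("feature selection frequencies match a counting-loop oracle", {
  set.seed(64)
  tissues <- c("liver", "lung", "colon", "heart")
  picks <- lapply(tissues, function(t) sort(sample(12, 4)))
  models <- setNames(mapply(fake_quality_model, tissues, picks,
                            SIMPLIFY = FALSE), tissues)
  fim <- feature_importance_matrix(models, top_n = 3)
  for (feat in colnames(fim$frequency)) {
    j <- as.integer(sub("f", "", feat))
    count <- 0
    for (p in picks) if (j %in% p) count <- count + 1
    expect_equal(unname(fim$counts[feat]), count)
  }
  # a feature selected by every tissue ranks first
  models2 <- lapply(models, function(m) {
    m$selected_features <- union(1L, m$selected_features)
    m$coefficients <- rep(0.5, length(m$selected_features))
    m$feature_means <- rep(0, length(m$selected_features))
    m$feature_sds <- rep(1, length(m$selected_features))
    m
  })
  fim2 <- feature_importance_matrix(models2, top_n = 3)
  expect_identical(fim2$top_features[1], "f01")
  expect_equal(unname(fim2$counts["f01"]), length(tissues))
})

test_that("identical models for both targets overlap completely", {
  models <- setNames(lapply(c("a", "b"), fake_quality_model,
                            nonzero_idx = c(2L, 5L, 9L)), c("a", "b"))
  fim <- feature_importance_matrix(models, models, top_n = 3)
  expect_length(fim$overlap, 3)
  expect_setequal(fim$overlap, fim$top_features)
})

test_that("complete-linkage clustering reproduces hand-computed merges", {
  # 1-d points 0, 1, 10: first merge {0,1} at height 1, final at height 10
  m <- cbind(c(0, 1, 10), 0)
  rownames(m) <- c("p0", "p1", "p10")
  hc <- hierarchical_cluster(cbind(m, m))
  expect_equal(hc$row_tree$height, c(sqrt(2), sqrt(2) * 10), tolerance = 1e-12)
  # identical rows merge first at height 0
  m2 <- rbind(a = c(1, 2, 3), b = c(1, 2, 3), c = c(9, 9, 9))
  hc2 <- hierarchical_cluster(m2)
  expect_equal(hc2$row_tree$height[1], 0)
  expect_identical(sort(hc2$row_tree$merge[1, ]), c(-2L, -1L))
  expect_error(hierarchical_cluster(matrix(c(1, NA, 2, 3), 2)), "missing")
})

test_that("row permutation leaves the clustering topology unchanged", {
  set.seed(65)
  m <- matrix(rnorm(6 * 4), 6, dimnames = list(letters[1:6], NULL))
  perm <- sample(6)
  h1 <- hierarchical_cluster(m)$row_tree
  h2 <- hierarchical_cluster(m[perm, ])$row_tree
  expect_equal(sort(h1$height), sort(h2$height), tolerance = 1e-12)
  co1 <- as.matrix(stats::cophenetic(h1))
  co2 <- as.matrix(stats::cophenetic(h2))
  expect_equal(co1[rownames(co2), colnames(co2)], co2, tolerance = 1e-12)
})

test_that("stability CV reproduces hand arithmetic and label thresholds", {
  s <- stability_cv(rep(0.5, 5))
  expect_equal(s$cv, 0)
  expect_identical(s$label, "stable")
  s2 <- stability_cv(c(0.1, 0.6, 0.2))
  expect_equal(s2$mean, 0.3, tolerance = 1e-12)
  expect_equal(s2$sd, sqrt((0.04 + 0.09 + 0.01) / 2), tolerance = 1e-12)
  expect_equal(s2$cv, s2$sd / 0.3, tolerance = 1e-12)
  expect_equal(s2$cv, 0.882, tolerance = 1e-3)
  expect_identical(s2$label, "unstable")
  expect_identical(stability_cv(c(0.5, 0.55, 0.45, 0.52, 0.48))$label, "stable")
  expect_warning(s3 <- stability_cv(c(-0.2, 0.1, -0.1)), "non-positive")
  expect_identical(s3$label, "unstable")
  expect_true(is.na(s3$cv))
})

test_that("stability CV is invariant to positive rescaling of fold correlations", {
  folds <- c(0.3, 0.4, 0.35, 0.5)
  expect_equal(stability_cv(folds)$cv, stability_cv(2 * folds)$cv,
               tolerance = 1e-12)
})

test_that("preservation percentiles reproduce the full-sample R at q = 100", {
  set.seed(66)
  obs <- rnorm(200, 7)
  pred <- obs + rnorm(200, sd = 0.5)
  curve <- preservation_percentile(pred, obs)
  expect_identical(curve$r[curve$percentile == 100], pearson_r(pred, obs))
  expect_identical(curve$n_retained[curve$percentile == 100], 200L)
  # perfect predictions stay at R = 1 wherever defined
  curve2 <- preservation_percentile(obs, obs)
  ok <- !is.na(curve2$r)
  expect_equal(curve2$r[ok], rep(1, sum(ok)), tolerance = 1e-12)
})

test_that("restricting to degraded samples attenuates R as the model predicts", {
  set.seed(67)
  n <- 2000
  obs <- rnorm(n)
  tau <- 0.5
  pred <- obs + rnorm(n, sd = tau)
  curve <- preservation_percentile(pred, obs, percentile_steps = c(100, 50))
  # truncation below the median leaves var = 1 - (2*dnorm(0))^2 of a standard
  # normal; attenuated R = sqrt(v / (v + tau^2))
  v <- 1 - (2 * dnorm(0))^2
  expect_equal(curve$r[curve$percentile == 100], 1 / sqrt(1 + tau^2),
               tolerance = 0.05)
  expect_equal(curve$r[curve$percentile == 50], sqrt(v / (v + tau^2)),
               tolerance = 0.05)
})

test_that("degenerate preservation subsets are reported missing", {
  obs <- c(rep(1, 8), 5, 6, 7, 8, 9, 10)
  pred <- rnorm(14)
  curve <- preservation_percentile(pred, obs, percentile_steps = c(100, 30))
  expect_true(is.na(curve$r[curve$percentile == 30])) # constant observed
  expect_error(preservation_percentile(1:5, 1:5), ">= 10")
})
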