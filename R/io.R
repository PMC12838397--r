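# Shared I/O: slide manifests, embedding matrices, model bundles and run
# logs. All tabular formats are tab-delimited UTF-8 text with missing values
# as empty strings; model bundles are directories of JSON metadata plus
# delimited numeric arrays written at full double precision.

BUNDLE_VERSION <- 1L

manifest_columns <- c("slide_id", "donor_id", "tissue", "rin", "autolysis",
                      "hardy", "age", "sex")

# as.numeric with a line-numbered error instead of silent NA coercion.
parse_numeric_column <- function(x, col) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(!is.na(x) & is.na(out))
  if (length(bad) > 0L) {
    stop_pathqc("malformed %s value '%s' at manifest line %d",
                col, x[bad[1]], bad[1] + 1L) # +1 for the header line
  }
  out
}

#' Read a slide manifest
#'
#' Tab-delimited text with header columns `slide_id, donor_id, tissue, rin,
#' autolysis, hardy, age, sex`; empty fields are missing. Slides with missing
#' RIN or autolysis are retained (they are excluded per prediction task
#' downstream, not here).
#'
#' @param path manifest file.
#' @param known_tissues optional character vector; tissues outside it are
#'   accepted with a warning.
#' @return Data frame of typed slide records.
#' @export
read_manifest <- function(path, known_tissues = NULL) {
  if (!file.exists(path)) stop_pathqc("manifest not found: %s", path)
  raw <- read.delim(path, sep = "\t", colClasses = "character",
                    na.strings = "", check.names = FALSE)
  missing_cols <- setdiff(c("slide_id", "tissue"), names(raw))
  if (length(missing_cols) > 0L) {
    stop_pathqc("manifest lacks required column(s): %s",
                paste(missing_cols, collapse = ", "))
  }
  for (col in setdiff(manifest_columns, names(raw))) raw[[col]] <- NA_character_
  raw <- raw[, manifest_columns]
  if (anyNA(raw$slide_id)) stop_pathqc("manifest has empty slide_id fields")
  dup <- raw$slide_id[duplicated(raw$slide_id)]
  if (length(dup) > 0L) {
    stop_pathqc("duplicate slide_id in manifest: %s",
                paste(unique(dup), collapse = ", "))
  }
  out <- data.frame(
    slide_id = raw$slide_id,
    donor_id = raw$donor_id,
    tissue = raw$tissue,
    rin = parse_numeric_column(raw$rin, "rin"),
    autolysis = parse_numeric_column(raw$autolysis, "autolysis"),
    hardy = parse_numeric_column(raw$hardy, "hardy"),
    age = parse_numeric_column(raw$age, "age"),
    sex = raw$sex,
    stringsAsFactors = FALSE
  )
  bad_rin <- which(!is.na(out$rin) & (out$rin < 1 | out$rin > 10))
  if (length(bad_rin) > 0L) {
    stop_pathqc("RIN outside [1, 10] at manifest line %d", bad_rin[1] + 1L)
  }
  bad_aut <- which(!is.na(out$autolysis) & !(out$autolysis %in% 0:3))
  if (length(bad_aut) > 0L) {
    stop_pathqc("autolysis score outside {0,1,2,3} at manifest line %d",
                bad_aut[1] + 1L)
  }
  if (!is.null(known_tissues)) {
    unknown <- setdiff(unique(out$tissue), known_tissues)
    if (length(unknown) > 0L) {
      warning(sprintf("manifest contains unrecognized tissue(s): %s",
                      paste(unknown, collapse = ", ")))
    }
  }
  out
}

#' @rdname read_manifest
#' @param records slide-record data frame.
#' @export
write_manifest <- function(records, path) {
  out <- records[, intersect(manifest_columns, names(records)), drop = FALSE]
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}

#' Read / write a slide-embedding matrix
#'
#' Tab-delimited text; first column `slide_id`, remaining columns the 4d
#' embedding features (`mean_0001 ... max_<d>`).
#'
#' @param path file path.
#' @return Numeric matrix with slide ids as rownames.
#' @export
read_embeddings <- function(path) {
  if (!file.exists(path)) stop_pathqc("embeddings file not found: %s", path)
  tab <- read.delim(path, sep = "\t", check.names = FALSE)
  X <- as.matrix(tab[, -1, drop = FALSE])
  rownames(X) <- tab[[1]]
  storage.mode(X) <- "double"
  X
}

#' @rdname read_embeddings
#' @param X embedding matrix (rownames = slide ids).
#' @export
write_embeddings <- function(X, path) {
  df <- data.frame(slide_id = rownames(X),
                   as.data.frame(format_full(X), check.names = FALSE),
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Full-precision decimal text for doubles (round-trips exactly).
format_full <- function(x) {
  out <- sprintf("%.17g", x)
  dim(out) <- dim(x)
  dimnames(out) <- dimnames(x)
  out
}

write_tsv_full <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  for (j in which(num)) df[[j]] <- sprintf("%.17g", df[[j]])
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
}

save_quality_model <- function(model, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  meta <- list(
    bundle_version = BUNDLE_VERSION,
    type = "quality_model",
    tissue = model$tissue, target = model$target,
    lambda = model$lambda, alpha = model$alpha,
    intercept = model$intercept,
    cv_mse = model$cv_mse, n_train = model$n_train,
    n_features = length(model$feature_names),
    feature_names = model$feature_names,
    package_version = as.character(utils::packageVersion("pathqc"))
  )
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = I(17), null = "null")
  arr <- data.frame(
    feature_index = model$selected_features,
    mean = model$feature_means,
    sd = model$feature_sds,
    coefficient = model$coefficients
  )
  write_tsv_full(arr, file.path(path, "coefficients.tsv"))
  invisible(path)
}

load_quality_model <- function(path) {
  meta_path <- file.path(path, "meta.json")
  arr_path <- file.path(path, "coefficients.tsv")
  if (!file.exists(meta_path) || !file.exists(arr_path)) {
    stop_pathqc("incomplete model bundle at '%s'", path)
  }
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  if (is.null(meta$bundle_version) || meta$bundle_version != BUNDLE_VERSION) {
    stop_pathqc("bundle version %s does not match supported version %d",
                as.character(meta$bundle_version), BUNDLE_VERSION)
  }
  arr <- read.delim(arr_path, sep = "\t")
  fn <- meta$feature_names
  if (length(fn) == 0L) fn <- NULL
  structure(
    list(tissue = meta$tissue, target = meta$target,
         feature_means = arr$mean, feature_sds = arr$sd,
         selected_features = as.integer(arr$feature_index),
         feature_names = fn,
         coefficients = arr$coefficient, intercept = meta$intercept,
         lambda = meta$lambda, alpha = meta$alpha,
         cv_mse = meta$cv_mse, n_train = meta$n_train),
    class = "quality_model"
  )
}

save_pan_tissue_model <- function(model, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  clf <- model$classifier
  meta <- list(
    bundle_version = BUNDLE_VERSION,
    type = "pan_tissue_model",
    confidence_threshold = model$confidence_threshold,
    classes = clf$classes,
    lambda = clf$lambda,
    cv_accuracy = clf$cv_accuracy,
    selected_features = model$selected_features,
    scaler_kept = model$scaler$kept,
    feature_names = model$feature_names,
    package_version = as.character(utils::packageVersion("pathqc"))
  )
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = I(17), null = "null")
  write_tsv_full(data.frame(mean = model$scaler$means, sd = model$scaler$sds),
                 file.path(path, "scaler.tsv"))
  beta <- rbind(intercept = clf$intercepts, clf$beta)
  write_tsv_full(as.data.frame(beta), file.path(path, "classifier.tsv"))
  for (ti in names(model$tissue_registry)) {
    save_quality_model(model$tissue_registry[[ti]]$rin,
                       file.path(path, "registry", ti, "rin"))
    save_quality_model(model$tissue_registry[[ti]]$autolysis,
                       file.path(path, "registry", ti, "autolysis"))
  }
  invisible(path)
}

load_pan_tissue_model <- function(path) {
  meta_path <- file.path(path, "meta.json")
  if (!file.exists(meta_path)) stop_pathqc("incomplete model bundle at '%s'", path)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  if (is.null(meta$bundle_version) || meta$bundle_version != BUNDLE_VERSION) {
    stop_pathqc("bundle version %s does not match supported version %d",
                as.character(meta$bundle_version), BUNDLE_VERSION)
  }
  sc <- read.delim(file.path(path, "scaler.tsv"), sep = "\t")
  cl <- as.matrix(read.delim(file.path(path, "classifier.tsv"), sep = "\t",
                             check.names = FALSE))
  classifier <- structure(
    list(classes = meta$classes, beta = cl[-1, , drop = FALSE],
         intercepts = cl[1, ], lambda = meta$lambda,
         cv_accuracy = meta$cv_accuracy, cv_class = NULL),
    class = "tissue_classifier"
  )
  registry <- list()
  for (ti in meta$classes) {
    registry[[ti]] <- list(
      rin = load_quality_model(file.path(path, "registry", ti, "rin")),
      autolysis = load_quality_model(file.path(path, "registry", ti, "autolysis"))
    )
  }
  structure(
    list(scaler = list(means = sc$mean, sds = sc$sd,
                       kept = as.integer(meta$scaler_kept)),
         selected_features = as.integer(meta$selected_features),
         classifier = classifier, tissue_registry = registry,
         confidence_threshold = meta$confidence_threshold,
         feature_names = meta$feature_names),
    class = "pan_tissue_model"
  )
}

#' Save / load a fitted model bundle
#'
#' Bundles are directories containing `meta.json` (model type, bundle
#' version, configuration scalars, package version) plus full-precision
#' delimited numeric arrays, so loading reproduces bit-identical predictions.
#' A missing file or a version mismatch raises an explicit error.
#'
#' @param model a `quality_model` or `pan_tissue_model`.
#' @param path bundle directory.
#' @return `save_bundle` returns `path` invisibly; `load_bundle` returns the
#'   reconstructed model.
#' @export
save_bundle <- function(model, path) {
  if (inherits(model, "quality_model")) {
    save_quality_model(model, path)
  } else if (inherits(model, "pan_tissue_model")) {
    save_pan_tissue_model(model, path)
  } else {
    stop_pathqc("cannot serialize object of class '%s'", class(model)[1])
  }
}

#' @rdname save_bundle
#' @export
load_bundle <- function(path) {
  meta_path <- file.path(path, "meta.json")
  if (!file.exists(meta_path)) stop_pathqc("no model bundle at '%s'", path)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  switch(
    meta$type %||% "",
    quality_model = load_quality_model(path),
    pan_tissue_model = load_pan_tissue_model(path),
    stop_pathqc("unknown bundle type '%s'", as.character(meta$type))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a machine-readable run log
#'
#' Records the effective configuration, seed and library versions of a
#' pipeline run as JSON, sufficient to replay it.
#'
#' @param path output file.
#' @param config named list of configuration values.
#' @param seed the RNG seed used.
#' @return `path`, invisibly.
#' @export
write_run_log <- function(path, config = list(), seed = NULL) {
  log <- list(
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    config = config,
    r_version = R.version.string,
    package_versions = list(
      pathqc = as.character(utils::packageVersion("pathqc")),
      glmnet = as.character(utils::packageVersion("glmnet"))
    )
  )
  jsonlite::write_json(log, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Default run configuration
#'
#' All defaults are the pipeline's canonical operating values: 512-pixel
#' patches, 50% maximum background, minimum 2 valid patches per slide, 5 CV
#' folds, 70:30 train-test split, top-5% correlation screening, 500
#' ANOVA-F classifier features, 0.6 routing confidence threshold.
#'
#' @param ... overrides for any field.
#' @return Named list of configuration values.
#' @export
run_config <- function(...) {
  cfg <- list(
    patch_size = 512L,
    max_background_fraction = 0.5,
    min_valid_patches = 2L,
    encoder = "synthetic",
    encoder_dim = 64L,
    n_folds = 5L,
    test_fraction = 0.3,
    top_feature_fraction = 0.05,
    pan_k = 500L,
    confidence_threshold = 0.6,
    seed = 1L
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(cfg))
  if (length(unknown) > 0L) {
    stop_pathqc("unknown config field(s): %s", paste(unknown, collapse = ", "))
  }
  cfg[names(overrides)] <- overrides
  cfg
}

#' Read an RGB image file into an 8-bit H x W x 3 array
#'
#' Supports PNG (always) and TIFF when the `tiff` package is installed.
#' Grayscale images are replicated to three channels; alpha is dropped.
#'
#' @param path image file.
#' @return H x W x 3 array with values in `[0, 255]`.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop_pathqc("image not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  img <- if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE)) {
      stop_pathqc("reading TIFF requires the 'tiff' package")
    }
    tiff::readTIFF(path)
  } else {
    png::readPNG(path)
  }
  if (length(dim(img)) == 2L) img <- array(rep(img, 3), dim = c(dim(img), 3))
  if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE]
  round(img * 255)
}
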