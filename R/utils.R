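# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so library code never clobbers user RNG.
with_local_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

stop_pathqc <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

#' Pearson correlation between predictions and observations
#'
#' Thin wrapper around [stats::cor()] that returns `NA` when either input is
#' constant instead of raising a warning.
#'
#' @param x,y numeric vectors of equal length.
#' @return Pearson correlation coefficient, or `NA` if undefined.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop_pathqc("length mismatch: %d vs %d", length(x), length(y))
  if (length(x) < 2L || sd(x) == 0 || sd(y) == 0) return(NA_real_)
  cor(x, y, method = "pearson")
}

#' Root-mean-square error
#'
#' @param predicted,observed numeric vectors of equal length.
#' @return `sqrt(mean((predicted - observed)^2))`.
#' @export
rmse <- function(predicted, observed) {
  if (length(predicted) != length(observed)) {
    stop_pathqc("length mismatch: %d vs %d", length(predicted), length(observed))
  }
  sqrt(mean((predicted - observed)^2))
}

# Validate an 8-bit RGB raster stored H x W x 3 with values in [0, 255].
check_rgb <- function(image, what = "image") {
  if (!is.array(image) || length(dim(image)) != 3L || dim(image)[3] != 3L) {
    stop_pathqc("%s must be an H x W x 3 RGB array", what)
  }
  d <- dim(image)
  if (d[1] < 1L || d[2] < 1L) stop_pathqc("%s is empty", what)
  if (anyNA(image) || min(image) < 0 || max(image) > 255) {
    stop_pathqc("%s must have channel values in [0, 255]", what)
  }
  invisible(image)
}

# Luminance (ITU-R BT.601 weights) of an RGB raster, on the same 0-255 scale.
rgb_to_gray <- function(image) {
  0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
}

# Zero-padded feature names for the aggregated slide embedding:
# mean_0001 ... max_<d>, in block order mean | std | min | max.
embedding_feature_names <- function(d) {
  width <- max(4L, nchar(as.character(d)))
  idx <- formatC(seq_len(d), width = width, flag = "0")
  as.vector(vapply(
    c("mean", "std", "min", "max"),
    function(b) paste0(b, "_", idx),
    character(d)
  ))
}
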