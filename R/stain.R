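# Macenko stain estimation and normalization.
#
# Stain mixing is modelled in optical-density (OD) space, where the
# Beer-Lambert law makes absorption approximately linear in stain
# concentration: OD = -log10((I + 1) / 256) per channel (pseudo-count of 1
# keeps OD finite on saturated pixels). High-OD pixels are projected onto the
# top-2 singular plane of OD space and the extreme percentile angles give the
# hematoxylin and eosin vectors.

#' Convert between 8-bit RGB intensity and optical density
#'
#' @param image numeric array or matrix of 8-bit intensities in `[0, 255]`.
#' @return Array of the same shape: `OD = -log10((I + 1) / 256)`.
#' @export
od_from_rgb <- function(image) {
  -log10((image + 1) / 256)
}

#' @rdname od_from_rgb
#' @param od optical-density values.
#' @return Intensities clipped to `[0, 255]` (not rounded).
#' @export
rgb_from_od <- function(od) {
  pmin(pmax(256 * 10^(-od) - 1, 0), 255)
}

#' Construct a stain profile
#'
#' @param stain_matrix 3 x 2 OD stain basis; column 1 hematoxylin, column 2
#'   eosin. Columns must be non-negative with unit Euclidean norm (to 1e-6).
#' @param max_concentrations length-2 reference 99th-percentile concentrations
#'   used to match stain intensity between images.
#' @return Object of class `stain_profile`.
#' @export
stain_profile <- function(stain_matrix, max_concentrations) {
  stain_matrix <- as.matrix(stain_matrix)
  stopifnot(all(dim(stain_matrix) == c(3L, 2L)), length(max_concentrations) == 2L)
  norms <- sqrt(colSums(stain_matrix^2))
  if (any(abs(norms - 1) > 1e-6)) {
    stop_pathqc("stain matrix columns must be unit-normalized (norms: %s)",
                paste(signif(norms, 6), collapse = ", "))
  }
  if (any(stain_matrix < 0)) stop_pathqc("stain matrix entries must be non-negative")
  dimnames(stain_matrix) <- list(c("R", "G", "B"), c("hematoxylin", "eosin"))
  structure(
    list(stain_matrix = stain_matrix, max_concentrations = as.numeric(max_concentrations)),
    class = "stain_profile"
  )
}

#' Default H&E reference stain profile
#'
#' The widely used reference OD vectors for hematoxylin and eosin
#' (H = (0.5626, 0.7201, 0.4062), E = (0.2159, 0.8012, 0.5581)) with reference
#' maximum concentrations (1.9705, 1.0308), so that normalization is
#' reproducible without supplying a reference image.
#'
#' @return A [stain_profile()].
#' @export
default_stain_profile <- function() {
  m <- matrix(c(0.5626, 0.7201, 0.4062,
                0.2159, 0.8012, 0.5581), ncol = 2)
  m <- sweep(m, 2, sqrt(colSums(m^2)), "/")
  stain_profile(m, c(1.9705, 1.0308))
}

# Non-negative stain concentrations per pixel, via clipped pseudo-inverse of
# the 3x2 stain basis. `od` is N x 3; result is N x 2.
stain_concentrations_od <- function(od, stain_matrix) {
  pinv <- solve(crossprod(stain_matrix), t(stain_matrix)) # 2 x 3
  conc <- od %*% t(pinv)
  conc[conc < 0] <- 0
  conc
}

#' Estimate the stain profile of an image (Macenko's method)
#'
#' High-OD pixels (Euclidean OD norm above `od_threshold`) are projected onto
#' the plane of the top two right singular vectors of their OD tuples; the
#' directions at the `angle_percentile` and `100 - angle_percentile`
#' percentiles of the projection angle are taken as the two stain vectors.
#' The hematoxylin column is ordered first, identified as the vector with the
#' larger red-channel OD (hematoxylin transmits blue light and absorbs red).
#'
#' @param image H x W x 3 RGB array, 8-bit.
#' @param od_threshold pixels whose OD vector norm exceeds this are considered
#'   stained tissue (default 0.15); the norm-based rule keeps the retained
#'   pixel set stable across stain bases.
#' @param angle_percentile robust extreme-angle percentile (default 1).
#' @param min_pixels minimum number of qualifying pixels (default 100).
#' @return A [stain_profile()] with `max_concentrations` set to the image's
#'   99th-percentile concentration per stain.
#' @export
estimate_stain_profile <- function(image, od_threshold = 0.15,
                                   angle_percentile = 1, min_pixels = 100L) {
  check_rgb(image)
  od <- cbind(as.vector(od_from_rgb(image[, , 1])),
              as.vector(od_from_rgb(image[, , 2])),
              as.vector(od_from_rgb(image[, , 3])))
  keep <- sqrt(rowSums(od^2)) > od_threshold
  odh <- od[keep, , drop = FALSE]
  if (nrow(odh) < min_pixels) {
    stop_pathqc("insufficient tissue for stain estimation (%d high-OD pixels, need >= %d)",
                nrow(odh), min_pixels)
  }
  # 8-bit quantization leaves a noise floor of ~2e-3 on the second singular
  # value even for a pure single-stain image, so the rank-1 test needs a
  # relative tolerance well above machine precision
  sv <- svd(odh, nu = 0, nv = 3)
  if (sv$d[2] <= 5e-3 * sv$d[1]) {
    stop_pathqc("degenerate stain plane: OD cloud is effectively rank-1 (single stain?)")
  }
  basis <- sv$v[, 1:2, drop = FALSE]
  proj <- odh %*% basis
  # orient the first axis toward the data so angles are well-behaved
  if (mean(proj[, 1]) < 0) {
    basis[, 1] <- -basis[, 1]
    proj[, 1] <- -proj[, 1]
  }
  phi <- atan2(proj[, 2], proj[, 1])
  lo <- quantile(phi, angle_percentile / 100, names = FALSE)
  hi <- quantile(phi, 1 - angle_percentile / 100, names = FALSE)
  v1 <- basis %*% c(cos(lo), sin(lo))
  v2 <- basis %*% c(cos(hi), sin(hi))
  fix <- function(v) {
    if (sum(v) < 0) v <- -v
    v[v < 0] <- 0
    v / sqrt(sum(v^2))
  }
  v1 <- fix(v1); v2 <- fix(v2)
  m <- if (v1[1] >= v2[1]) cbind(v1, v2) else cbind(v2, v1)
  conc <- stain_concentrations_od(od, m)
  maxc <- apply(conc, 2, quantile, probs = 0.99, names = FALSE)
  stain_profile(m, maxc)
}

#' Normalize an image's stain appearance to a target profile
#'
#' Per-pixel concentrations are solved against `source$stain_matrix` with a
#' clipped pseudo-inverse, scaled so the image's 99th-percentile concentration
#' of each stain matches `target$max_concentrations`, and re-rendered through
#' `target$stain_matrix`. Unstained (white) pixels have zero OD and are fixed
#' points of the transform.
#'
#' @param image H x W x 3 RGB array, 8-bit.
#' @param source [stain_profile()] describing the image's own stains,
#'   typically from [estimate_stain_profile()].
#' @param target [stain_profile()] to map to (default: the shipped reference).
#' @return Normalized RGB array of the same shape, 8-bit integers.
#' @export
macenko_normalize <- function(image, source, target = default_stain_profile()) {
  check_rgb(image)
  stopifnot(inherits(source, "stain_profile"), inherits(target, "stain_profile"))
  d <- dim(image)
  od <- cbind(as.vector(od_from_rgb(image[, , 1])),
              as.vector(od_from_rgb(image[, , 2])),
              as.vector(od_from_rgb(image[, , 3])))
  conc <- stain_concentrations_od(od, source$stain_matrix)
  maxc <- apply(conc, 2, quantile, probs = 0.99, names = FALSE)
  scale_fac <- ifelse(maxc > 0, target$max_concentrations / maxc, 1)
  conc <- sweep(conc, 2, scale_fac, "*")
  od_new <- conc %*% t(target$stain_matrix)
  out <- round(rgb_from_od(od_new))
  array(c(out[, 1], out[, 2], out[, 3]), dim = d)
}
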