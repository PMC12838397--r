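# Slide preprocessing: tissue masking, tiling and slide-level filtering.
# Images are plain R arrays, H x W x 3, 8-bit values in [0, 255], row-major
# with 0-based grid indices on patches.

#' Construct a raw slide object
#'
#' @param slide_id character scalar identifying the slide.
#' @param pixels H x W x 3 RGB array with 8-bit values in `[0, 255]`.
#' @param microns_per_pixel optional scan resolution (~0.5 at 20x).
#' @return An object of class `raw_slide`.
#' @export
raw_slide <- function(slide_id, pixels, microns_per_pixel = NULL) {
  stopifnot(is.character(slide_id), length(slide_id) == 1L)
  check_rgb(pixels, "pixels")
  structure(
    list(slide_id = slide_id, pixels = pixels, microns_per_pixel = microns_per_pixel),
    class = "raw_slide"
  )
}

#' Sobel gradient magnitude of an image
#'
#' Computes the gradient magnitude `sqrt(gx^2 + gy^2)` of the luminance channel
#' using the standard 3x3 Sobel kernels with replicated image borders.
#'
#' @param image H x W x 3 RGB array (8-bit) or an H x W grayscale matrix.
#' @return Numeric H x W matrix of gradient magnitudes.
#' @export
sobel_gradient <- function(image) {
  gray <- if (is.matrix(image)) image else {
    check_rgb(image)
    rgb_to_gray(image)
  }
  kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), nrow = 3, byrow = TRUE)
  ky <- t(kx)
  if (nrow(gray) < 3L || ncol(gray) < 3L) {
    return(matrix(0, nrow(gray), ncol(gray)))
  }
  gx <- EBImage::filter2(gray, kx, boundary = "replicate")
  gy <- EBImage::filter2(gray, ky, boundary = "replicate")
  sqrt(gx^2 + gy^2)
}

#' Compute a tissue mask by Sobel edge detection
#'
#' Background removal for histology rasters: the Sobel gradient magnitude of
#' the luminance image is thresholded (Otsu's method by default), then cleaned
#' by a 3x3 binary closing and removal of connected components smaller than
#' `min_object_px` pixels. Tissue regions are edge-rich; blank background is
#' flat and falls below the threshold.
#'
#' @param image H x W x 3 RGB array, 8-bit.
#' @param gradient_threshold numeric; pixels with gradient magnitude strictly
#'   above this value are tissue. `NULL` (default) selects the threshold by
#'   Otsu's method on the gradient image.
#' @param closing_size side of the square closing brush (pixels).
#' @param fill_holes if `TRUE` (default), enclosed background regions inside
#'   detected edge contours are filled, so solid tissue regions are masked as
#'   tissue rather than only their boundaries.
#' @param min_object_px connected components smaller than this are removed.
#' @return An object of class `tissue_mask`: list with `mask` (logical H x W)
#'   and `tissue_fraction` (exactly `mean(mask)`).
#' @export
compute_tissue_mask <- function(image, gradient_threshold = NULL,
                                closing_size = 3L, fill_holes = TRUE,
                                min_object_px = 64L) {
  check_rgb(image)
  grad <- sobel_gradient(image)
  grad[grad < 1e-6] <- 0 # FFT convolution noise floor (0-255 intensity scale)
  gmax <- max(grad)
  if (gmax == 0) {
    mask <- matrix(FALSE, nrow(grad), ncol(grad))
    return(tissue_mask(mask))
  }
  if (is.null(gradient_threshold)) {
    gradient_threshold <- gmax * EBImage::otsu(EBImage::Image(grad / gmax), range = c(0, 1))
  }
  mask <- grad > gradient_threshold
  if (any(mask) && closing_size > 1L) {
    mask <- EBImage::closing(mask, EBImage::makeBrush(closing_size, shape = "box")) > 0
  }
  if (any(mask) && fill_holes) {
    mask <- EBImage::fillHull(EBImage::bwlabel(mask)) > 0
  }
  if (any(mask) && min_object_px > 1L) {
    lab <- EBImage::bwlabel(mask)
    sizes <- tabulate(lab[lab > 0])
    keep <- which(sizes >= min_object_px)
    mask <- matrix(lab %in% keep, nrow(mask), ncol(mask))
  }
  tissue_mask(mask)
}

#' @rdname compute_tissue_mask
#' @param mask logical H x W matrix.
#' @export
tissue_mask <- function(mask) {
  stopifnot(is.matrix(mask), is.logical(mask))
  structure(
    list(mask = mask, tissue_fraction = mean(mask)),
    class = "tissue_mask"
  )
}

#' Tile a slide into fixed-size patches with background filtering
#'
#' Cuts a non-overlapping `patch_size` grid anchored at pixel (0,0); partial
#' edge tiles are discarded. A patch is retained iff its tissue fraction under
#' `mask` is at least `1 - max_background_fraction` (background exceeding 50%
#' excludes the patch under the defaults).
#'
#' @param slide a [raw_slide()] object.
#' @param mask a [tissue_mask()] covering the same raster, or `NULL` to compute
#'   one with [compute_tissue_mask()] defaults.
#' @param patch_size patch side in pixels (default 512).
#' @param max_background_fraction maximum tolerated background fraction
#'   (default 0.5).
#' @param keep_filtered if `TRUE`, also return the excluded patches (for
#'   diagnostics); default `FALSE`.
#' @return List of `patch` objects, each with `slide_id`, 0-based `row`/`col`
#'   grid indices, `pixels` and `tissue_fraction`. May be empty.
#' @export
tile_slide <- function(slide, mask = NULL, patch_size = 512L,
                       max_background_fraction = 0.5, keep_filtered = FALSE) {
  stopifnot(inherits(slide, "raw_slide"), patch_size >= 1L)
  if (is.null(mask)) mask <- compute_tissue_mask(slide$pixels)
  stopifnot(inherits(mask, "tissue_mask"))
  d <- dim(slide$pixels)
  if (!all(dim(mask$mask) == d[1:2])) {
    stop_pathqc("mask dimensions (%d x %d) do not match slide (%d x %d)",
                nrow(mask$mask), ncol(mask$mask), d[1], d[2])
  }
  n_rows <- d[1] %/% patch_size
  n_cols <- d[2] %/% patch_size
  min_tissue <- 1 - max_background_fraction
  out <- list()
  for (r in seq_len(n_rows) - 1L) {
    for (cc in seq_len(n_cols) - 1L) {
      ri <- (r * patch_size + 1L):((r + 1L) * patch_size)
      ci <- (cc * patch_size + 1L):((cc + 1L) * patch_size)
      tf <- mean(mask$mask[ri, ci])
      retained <- tf >= min_tissue
      if (retained || keep_filtered) {
        p <- structure(
          list(slide_id = slide$slide_id, row = r, col = cc,
               pixels = slide$pixels[ri, ci, , drop = FALSE],
               tissue_fraction = tf, retained = retained),
          class = "patch"
        )
        out[[length(out) + 1L]] <- p
      }
    }
  }
  out
}

#' Slide-level quality gate on patch count
#'
#' Slides yielding fewer than `min_valid_patches` tissue patches after
#' background filtering carry too little usable tissue and are excluded from
#' all downstream stages.
#'
#' @param patches list of retained `patch` objects for one slide.
#' @param min_valid_patches minimum patch count to pass (default 2).
#' @return `TRUE` (pass) or `FALSE` (fail, slide excluded).
#' @export
filter_slide <- function(patches, min_valid_patches = 2L) {
  length(patches) >= min_valid_patches
}
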