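# Patch encoding and slide-level embedding aggregation.

#' Construct a patch encoder
#'
#' An encoder maps a `patch` to a fixed-length numeric feature vector. The
#' pipeline is agnostic to which encoder is plugged in; a deterministic
#' image-statistics encoder is provided for fully reproducible runs
#' ([synthetic_encoder()]), and external foundation-model features can be
#' supplied as precomputed matrices instead.
#'
#' @param name encoder name.
#' @param dim output dimensionality `d`.
#' @param encode function taking a `patch` (or bare RGB array) and returning a
#'   length-`dim` numeric vector; must be deterministic for fixed input.
#' @return Object of class `patch_encoder`.
#' @export
patch_encoder <- function(name, dim, encode) {
  stopifnot(is.character(name), dim >= 1L, is.function(encode))
  structure(list(name = name, dim = as.integer(dim), encode = encode),
            class = "patch_encoder")
}

#' Deterministic image-statistics patch encoder
#'
#' Computes simple per-channel summary statistics of the patch (means,
#' standard deviations, deciles, Sobel gradient energy) and expands them to
#' dimension `d` through a fixed random projection followed by a tanh
#' nonlinearity. The projection is drawn once from a seeded RNG at encoder
#' construction, so the encoder is deterministic for a fixed `(d, seed)` and
#' across sessions.
#'
#' @param d output dimensionality (default 64).
#' @param seed seed for the projection matrix (default 1).
#' @return A [patch_encoder()] named `"synthetic"`.
#' @export
synthetic_encoder <- function(d = 64L, seed = 1L) {
  n_stats <- 16L
  proj <- with_local_seed(seed, {
    list(w = matrix(rnorm(d * n_stats, sd = 1 / sqrt(n_stats)), nrow = d),
         b = rnorm(d, sd = 0.1))
  })
  encode <- function(patch) {
    px <- if (inherits(patch, "patch")) patch$pixels else patch
    check_rgb(px, "patch pixels")
    x <- px / 255
    s <- numeric(n_stats)
    for (k in 1:3) {
      ch <- x[, , k]
      s[k] <- mean(ch)
      s[3 + k] <- sd(ch)
      s[6 + k] <- quantile(ch, 0.1, names = FALSE)
      s[9 + k] <- quantile(ch, 0.9, names = FALSE)
    }
    gray <- rgb_to_gray(px) / 255
    s[13] <- mean(gray)
    s[14] <- sd(as.vector(gray))
    g <- sobel_gradient(gray * 255) / 255
    s[15] <- mean(g)
    s[16] <- max(g)
    as.vector(tanh(proj$w %*% s + proj$b))
  }
  patch_encoder("synthetic", d, encode)
}

#' Encode a list of patches into a patch-feature matrix
#'
#' @param patches non-empty list of `patch` objects (or RGB arrays).
#' @param encoder a [patch_encoder()].
#' @return P x d numeric matrix; row i is `encoder$encode(patches[[i]])`.
#' @export
encode_patches <- function(patches, encoder) {
  stopifnot(inherits(encoder, "patch_encoder"))
  if (length(patches) < 1L) stop_pathqc("no patches to encode")
  rows <- lapply(seq_along(patches), function(i) {
    v <- tryCatch(encoder$encode(patches[[i]]), error = function(e) {
      id <- if (inherits(patches[[i]], "patch")) {
        sprintf("%s_%d_%d", patches[[i]]$slide_id, patches[[i]]$row, patches[[i]]$col)
      } else {
        as.character(i)
      }
      stop_pathqc("encoder '%s' failed on patch %s: %s", encoder$name, id,
                  conditionMessage(e))
    })
    if (length(v) != encoder$dim) {
      stop_pathqc("encoder '%s' returned length %d, expected %d",
                  encoder$name, length(v), encoder$dim)
    }
    as.numeric(v)
  })
  do.call(rbind, rows)
}

#' Aggregate a patch-feature matrix into a slide-level embedding
#'
#' Concatenates the element-wise mean, standard deviation (sample convention,
#' divisor P-1), minimum and maximum over patches, in that order, yielding a
#' 4d-length slide vector (4096 features for d = 1024). The combined
#' aggregation captures both central tendency and within-slide heterogeneity
#' of patch morphology.
#'
#' @param patch_matrix P x d numeric matrix of patch features, P >= 2.
#' @param slide_id optional slide identifier carried on the result.
#' @return Object of class `slide_embedding`: list with `slide_id`, `vector`
#'   (named length-4d numeric, blocks `mean | std | min | max`) and
#'   `n_patches`.
#' @export
aggregate_slide <- function(patch_matrix, slide_id = NA_character_) {
  patch_matrix <- as.matrix(patch_matrix)
  if (nrow(patch_matrix) < 2L) {
    stop_pathqc("slide excluded: insufficient patches (P = %d, need >= 2)",
                nrow(patch_matrix))
  }
  d <- ncol(patch_matrix)
  v <- c(colMeans(patch_matrix),
         apply(patch_matrix, 2, sd),
         apply(patch_matrix, 2, min),
         apply(patch_matrix, 2, max))
  names(v) <- embedding_feature_names(d)
  structure(
    list(slide_id = slide_id, vector = v, n_patches = nrow(patch_matrix)),
    class = "slide_embedding"
  )
}

#' Embed a set of slides' patch matrices into a feature matrix
#'
#' Convenience wrapper stacking [aggregate_slide()] vectors into the N x 4d
#' design matrix consumed by the quality models (one row per slide, rownames =
#' slide ids).
#'
#' @param patch_matrices named list of P x d patch-feature matrices.
#' @return N x 4d numeric matrix with slide ids as rownames.
#' @export
embed_slides <- function(patch_matrices) {
  stopifnot(length(patch_matrices) >= 1L, !is.null(names(patch_matrices)))
  rows <- lapply(names(patch_matrices), function(id) {
    aggregate_slide(patch_matrices[[id]], slide_id = id)$vector
  })
  X <- do.call(rbind, rows)
  rownames(X) <- names(patch_matrices)
  X
}
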