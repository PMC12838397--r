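# Synthetic data with the statistical structure the pipeline assumes:
# (a) H&E-like RGB tiles built from a two-stain Beer-Lambert mixing model with
#     known stain vectors and concentration fields, plus ground-truth masks;
# (b) slide-embedding datasets where patch features follow tissue-specific
#     Gaussian signatures and a designated feature subset carries a planted
#     linear link to RIN, with autolysis derived from a negatively coupled
#     latent so the two metrics are anti-correlated as in real cohorts.

#' Specification for synthetic embedding datasets
#'
#' @param n_tissues number of tissue classes.
#' @param slides_per_tissue slides generated per tissue.
#' @param d patch-feature dimensionality (slide embeddings have length 4d).
#' @param patches_per_slide integer range (min, max) of patches per slide.
#' @param n_signal_features number of patch-feature coordinates carrying the
#'   planted RIN signal (the first `n_signal_features` coordinates).
#' @param signal_weights linear weights of the planted signal; default
#'   decreases from 1 to 0.5.
#' @param noise_sd RIN observation noise, as a multiple of the planted-signal
#'   SD (default 0.5).
#' @param autolysis_noise_sd noise on the autolysis latent, same units
#'   (default 0.5).
#' @param tissue_signature_separation SD of tissue signature coordinates;
#'   larger values separate tissues more (default 3).
#' @param patch_sd isotropic SD of patch features around the slide mean.
#' @param confounder_strength effect size of the Hardy-scale proxy on RIN
#'   (default 0.5).
#' @param rin_range clipping range of generated RIN (default `c(1, 10)`).
#' @param rin_center,rin_scale affine map from the standardized latent to the
#'   RIN scale (defaults 6.5 and 1.5, placing most slides between 5 and 8).
#' @param rin_missing_fraction,autolysis_missing_fraction fractions of slides
#'   whose label is blanked to missing (default 0).
#' @param seed RNG seed; generation is bit-reproducible for a fixed seed.
#' @return Object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_tissues = 5L, slides_per_tissue = 100L, d = 64L,
                           patches_per_slide = c(8L, 16L),
                           n_signal_features = 5L, signal_weights = NULL,
                           noise_sd = 0.5, autolysis_noise_sd = 0.5,
                           tissue_signature_separation = 3,
                           patch_sd = 1, confounder_strength = 0.5,
                           rin_range = c(1, 10), rin_center = 6.5,
                           rin_scale = 1.5,
                           rin_missing_fraction = 0,
                           autolysis_missing_fraction = 0,
                           seed = 1L) {
  if (n_signal_features > d) {
    stop_pathqc("n_signal_features (%d) exceeds d (%d)", n_signal_features, d)
  }
  stopifnot(n_tissues >= 1L, slides_per_tissue >= 1L, noise_sd >= 0,
            length(patches_per_slide) == 2L, patches_per_slide[1] >= 2L)
  if (is.null(signal_weights)) {
    signal_weights <- seq(1, 0.5, length.out = n_signal_features)
  }
  stopifnot(length(signal_weights) == n_signal_features)
  structure(
    list(n_tissues = as.integer(n_tissues),
         slides_per_tissue = as.integer(slides_per_tissue),
         d = as.integer(d), patches_per_slide = as.integer(patches_per_slide),
         n_signal_features = as.integer(n_signal_features),
         signal_weights = signal_weights, noise_sd = noise_sd,
         autolysis_noise_sd = autolysis_noise_sd,
         tissue_signature_separation = tissue_signature_separation,
         patch_sd = patch_sd, confounder_strength = confounder_strength,
         rin_range = rin_range, rin_center = rin_center, rin_scale = rin_scale,
         rin_missing_fraction = rin_missing_fraction,
         autolysis_missing_fraction = autolysis_missing_fraction,
         seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

#' Generate a slide-embedding dataset with planted quality signal
#'
#' Per slide: patch vectors are drawn from a tissue-specific Gaussian
#' signature, with the slide's own latent offset added on the signal
#' coordinates; patches are aggregated by [aggregate_slide()] (the same
#' mean/std/min/max rule the pipeline uses). RIN is an affine map of the
#' weighted signal latent plus a Hardy-scale proxy effect and Gaussian noise,
#' clipped to the RIN range. Autolysis is a discretized, negatively coupled
#' transform of the same latent (thresholds at the 50/80/95th percentiles of
#' its distribution), so Spearman(RIN, autolysis) is negative by
#' construction.
#'
#' @param spec a [synthetic_spec()].
#' @return List with `X` (N x 4d embedding matrix, slide-id rownames),
#'   `manifest` (data frame: slide_id, donor_id, tissue, rin, autolysis,
#'   hardy, age, sex) and `truth` (signatures, per-slide latents, planted
#'   feature indices and weights, uncensored labels).
#' @export
generate_embedding_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_local_seed(spec$seed, {
    n <- spec$n_tissues * spec$slides_per_tissue
    d <- spec$d
    tissues <- paste0("tissue_", LETTERS[seq_len(spec$n_tissues)])
    tissue <- rep(tissues, each = spec$slides_per_tissue)
    signatures <- matrix(
      rnorm(spec$n_tissues * d, sd = spec$tissue_signature_separation),
      nrow = spec$n_tissues, dimnames = list(tissues, NULL)
    )
    sig_idx <- seq_len(spec$n_signal_features)
    w <- spec$signal_weights
    sd_signal <- sqrt(sum(w^2))

    u <- matrix(rnorm(n * spec$n_signal_features), nrow = n)
    signal <- as.vector(u %*% w)
    hardy <- sample(0:4, n, replace = TRUE)
    conf <- spec$confounder_strength * (2 - hardy) / 2
    noise <- rnorm(n, sd = spec$noise_sd * sd_signal)
    latent <- signal + conf + noise
    latent_sd <- sqrt(sum(w^2) * 1 +
                        (spec$confounder_strength / 2)^2 * 2 +
                        (spec$noise_sd * sd_signal)^2)
    rin <- pmin(pmax(spec$rin_center + spec$rin_scale * latent / latent_sd,
                     spec$rin_range[1]), spec$rin_range[2])

    aut_latent <- -signal + rnorm(n, sd = spec$autolysis_noise_sd * sd_signal)
    cuts <- quantile(aut_latent, c(0.5, 0.8, 0.95), names = FALSE)
    autolysis <- findInterval(aut_latent, cuts)

    X <- matrix(NA_real_, n, 4L * d)
    n_patches <- integer(n)
    for (i in seq_len(n)) {
      mu <- signatures[tissue[i], ]
      mu[sig_idx] <- mu[sig_idx] + u[i, ]
      P <- sample(seq(spec$patches_per_slide[1], spec$patches_per_slide[2]), 1L)
      Z <- matrix(rnorm(P * d, sd = spec$patch_sd), P, d)
      Z <- sweep(Z, 2, mu, "+")
      agg <- aggregate_slide(Z)
      X[i, ] <- agg$vector
      n_patches[i] <- P
    }
    colnames(X) <- embedding_feature_names(d)
    slide_id <- sprintf("S%04d", seq_len(n))
    rownames(X) <- slide_id

    rin_obs <- rin
    aut_obs <- autolysis
    if (spec$rin_missing_fraction > 0) {
      rin_obs[sample(n, round(n * spec$rin_missing_fraction))] <- NA
    }
    if (spec$autolysis_missing_fraction > 0) {
      aut_obs[sample(n, round(n * spec$autolysis_missing_fraction))] <- NA
    }
    manifest <- data.frame(
      slide_id = slide_id,
      donor_id = sprintf("D%04d", seq_len(n)),
      tissue = tissue,
      rin = rin_obs,
      autolysis = aut_obs,
      hardy = hardy,
      age = round(runif(n, 21, 70), 1),
      sex = sample(c("male", "female"), n, replace = TRUE),
      stringsAsFactors = FALSE
    )
    list(
      X = X, manifest = manifest,
      truth = list(signatures = signatures, u = u, signal = signal,
                   signal_features = sig_idx, signal_weights = w,
                   hardy_effect = conf, rin = rin, autolysis = autolysis,
                   aut_latent = aut_latent, n_patches = n_patches)
    )
  })
}

#' Render a synthetic H&E-like tile through a two-stain mixing model
#'
#' Composes a white background with elliptical tissue blobs. Inside the
#' blobs, hematoxylin and eosin concentration fields (smooth radial profiles
#' with multiplicative noise) are rendered through the Beer-Lambert model
#' `I = 256 * 10^(-M c) - 1` using the supplied stain matrix, so the stain
#' vectors and the concentration field of every pixel are known exactly.
#'
#' @param height,width tile size in pixels.
#' @param tissue_fraction target fraction of tissue pixels; blobs are added
#'   until coverage reaches it (0 gives a pure-white tile).
#' @param stain_matrix 3 x 2 unit-column OD basis (default: shipped
#'   reference).
#' @param max_conc peak hematoxylin/eosin concentrations (length 2).
#' @param seed RNG seed.
#' @return List with `image` (H x W x 3, 8-bit), `mask` (logical ground-truth
#'   tissue mask) and `concentrations` (H x W x 2 field).
#' @export
simulate_stain_tile <- function(height = 128L, width = 128L,
                                tissue_fraction = 0.5,
                                stain_matrix = default_stain_profile()$stain_matrix,
                                max_conc = c(1.2, 0.9), seed = 1L) {
  with_local_seed(seed, {
    mask <- matrix(FALSE, height, width)
    conc <- array(0, dim = c(height, width, 2))
    if (tissue_fraction > 0) {
      rr <- matrix(seq_len(height), height, width)
      cc <- matrix(seq_len(width), height, width, byrow = TRUE)
      max_tries <- 200L
      tries <- 0L
      while (mean(mask) < tissue_fraction && tries < max_tries) {
        tries <- tries + 1L
        cy <- runif(1, 1, height)
        cx <- runif(1, 1, width)
        ay <- runif(1, height / 12, height / 5)
        ax <- runif(1, width / 12, width / 5)
        r2 <- ((rr - cy) / ay)^2 + ((cc - cx) / ax)^2
        inside <- r2 <= 1
        # smooth radial concentration profile, denser toward the blob centre
        prof <- pmax(1 - r2, 0)
        h_amp <- runif(1, 0.6, 1) * max_conc[1]
        e_amp <- runif(1, 0.6, 1) * max_conc[2]
        conc[, , 1][inside] <- pmax(conc[, , 1][inside],
                                    h_amp * prof[inside] * runif(sum(inside), 0.8, 1))
        conc[, , 2][inside] <- pmax(conc[, , 2][inside],
                                    e_amp * prof[inside] * runif(sum(inside), 0.8, 1))
        mask <- mask | inside
      }
    }
    od <- cbind(as.vector(conc[, , 1]), as.vector(conc[, , 2])) %*% t(stain_matrix)
    img <- round(rgb_from_od(od))
    image <- array(c(img[, 1], img[, 2], img[, 3]), dim = c(height, width, 3))
    list(image = image, mask = mask, concentrations = conc)
  })
}

#' Write a directory of synthetic slide tiles with ground truth
#'
#' Renders `n_slides` tiles with [simulate_stain_tile()], writing each slide
#' image as `{slide_id}.png`, its ground-truth tissue mask as
#' `{slide_id}_mask.png`, and a tab-delimited `tiles_manifest.tsv` recording
#' the requested and achieved tissue fraction per slide. Output is
#' byte-identical for a fixed seed.
#'
#' @param out_dir output directory (created if needed).
#' @param n_slides number of tiles.
#' @param height,width tile size in pixels.
#' @param tissue_fractions per-slide target tissue fractions (recycled).
#' @param stain_matrix 3 x 2 OD stain basis used to render all tiles.
#' @param seed RNG seed.
#' @return The manifest data frame, invisibly.
#' @export
generate_tiles <- function(out_dir, n_slides = 4L, height = 256L, width = 256L,
                           tissue_fractions = 0.6,
                           stain_matrix = default_stain_profile()$stain_matrix,
                           seed = 1L) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop_pathqc("cannot create output directory '%s'", out_dir)
  }
  tissue_fractions <- rep_len(tissue_fractions, n_slides)
  rows <- vector("list", n_slides)
  for (i in seq_len(n_slides)) {
    id <- sprintf("slide_%03d", i)
    tile <- simulate_stain_tile(height, width, tissue_fractions[i],
                                stain_matrix = stain_matrix, seed = seed + i)
    png::writePNG(tile$image / 255, file.path(out_dir, paste0(id, ".png")))
    png::writePNG(tile$mask * 1, file.path(out_dir, paste0(id, "_mask.png")))
    rows[[i]] <- data.frame(slide_id = id,
                            requested_fraction = tissue_fractions[i],
                            achieved_fraction = mean(tile$mask),
                            stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  write.table(manifest, file.path(out_dir, "tiles_manifest.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(manifest)
}
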