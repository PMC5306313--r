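## synthetic_data (part 1): blob phantoms emulating soft-tissue lesions with
## bright/dark features of controllable size, number and contrast, plus an
## optional sub--50 HU gas pocket.

#' Specify a lesion phantom
#'
#' The phantom is a soft-tissue disc (the ROI) on a square HU grid containing
#' Gaussian-profile blobs at non-overlapping random centres plus white noise.
#' Blob "radius" follows the same convention as the spatial scale filter: a
#' blob of radius r mm has Gaussian profile sigma `r/sqrt(2)` mm, so the LoG
#' filter at `ssf_mm = r` matches it best.
#'
#' @param grid Side length of the square pixel grid.
#' @param spacing_mm Pixel size in mm (default 0.98, a typical low-dose CT
#'   in-plane resolution at 512x512 / 400 mm FOV).
#' @param background_hu Background (soft-tissue) attenuation, default 40 HU.
#' @param blob_count Number of blobs to place.
#' @param blob_radius_mm Nominal blob radius in mm.
#' @param blob_amplitude_hu Signed peak contrast of each blob against the
#'   background; a scalar is recycled, a vector gives per-blob amplitudes
#'   (mix signs to emulate bright and dark features).
#' @param noise_sd_hu Standard deviation of additive white noise (HU).
#' @param mask_radius_frac ROI disc radius as a fraction of the grid side.
#' @param gas_pocket Optional `list(center_px = c(row, col), radius_px, hu)`
#'   rendering a gas pocket (default hu -800) inside the lesion.
#' @param seed Optional RNG seed; a fixed seed gives bit-identical phantoms.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(grid = 64L, spacing_mm = 0.98, background_hu = 40,
                         blob_count = 10L, blob_radius_mm = 3,
                         blob_amplitude_hu = 100, noise_sd_hu = 8,
                         mask_radius_frac = 0.42, gas_pocket = NULL,
                         seed = NULL) {
  if (blob_radius_mm <= 0) ctta_stop("blob radius must be positive", "bad_spec")
  if (blob_count < 0) ctta_stop("blob count must be non-negative", "bad_spec")
  if (noise_sd_hu < 0) ctta_stop("noise sd must be non-negative", "bad_spec")
  structure(list(grid = as.integer(grid), spacing_mm = spacing_mm,
                 background_hu = background_hu, blob_count = as.integer(blob_count),
                 blob_radius_mm = blob_radius_mm,
                 blob_amplitude_hu = blob_amplitude_hu,
                 noise_sd_hu = noise_sd_hu, mask_radius_frac = mask_radius_frac,
                 gas_pocket = gas_pocket, seed = seed),
            class = "phantom_spec")
}

#' Generate a lesion phantom
#'
#' Renders the phantom described by a [phantom_spec()]: background + blobs +
#' optional gas pocket, then additive Gaussian noise; the mask is the lesion
#' disc. Blob centres are drawn uniformly inside the disc (keeping the blob
#' footprint inside it) by rejection sampling with a minimum centre-to-centre
#' distance of twice the blob radius; if the requested count cannot be placed
#' after bounded retries an overcrowded-spec error is signalled.
#'
#' @param spec A [phantom_spec()].
#' @return List with `image` ([lesion_image()]), `mask` ([roi_mask()]), and
#'   `blob_centers` (matrix of row/col pixel coordinates).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(spec$seed, {
    n <- spec$grid
    ctr <- (n + 1) / 2
    rr <- matrix(seq_len(n), n, n)
    cc <- matrix(seq_len(n), n, n, byrow = TRUE)
    mask_r <- spec$mask_radius_frac * n
    d2ctr <- (rr - ctr)^2 + (cc - ctr)^2
    mask <- d2ctr <= mask_r^2

    img <- matrix(spec$background_hu, n, n)
    blob_r_px <- spec$blob_radius_mm / spec$spacing_mm
    sigma_px <- blob_r_px / sqrt(2)
    centers <- matrix(numeric(0), 0, 2)
    if (spec$blob_count > 0) {
      amps <- rep_len(spec$blob_amplitude_hu, spec$blob_count)
      placed <- 0L
      tries <- 0L
      max_tries <- 400L * spec$blob_count
      avail_r <- mask_r - blob_r_px
      if (avail_r <= 0)
        ctta_stop("blobs larger than the lesion disc", "overcrowded_spec")
      while (placed < spec$blob_count) {
        tries <- tries + 1L
        if (tries > max_tries)
          ctta_stop(sprintf(
            "could not place %d non-overlapping blobs of radius %.2g mm",
            spec$blob_count, spec$blob_radius_mm), "overcrowded_spec")
        u <- runif(1); th <- runif(1, 0, 2 * pi)
        r <- avail_r * sqrt(u)
        cand <- c(ctr + r * cos(th), ctr + r * sin(th))
        if (placed > 0L) {
          dd <- sqrt((centers[, 1] - cand[1])^2 + (centers[, 2] - cand[2])^2)
          if (any(dd < 2 * blob_r_px)) next
        }
        centers <- rbind(centers, cand)
        placed <- placed + 1L
        img <- img + amps[placed] *
          exp(-((rr - cand[1])^2 + (cc - cand[2])^2) / (2 * sigma_px^2))
      }
    }
    gp <- spec$gas_pocket
    if (!is.null(gp)) {
      hu <- if (is.null(gp$hu)) -800 else gp$hu
      ing <- (rr - gp$center_px[1])^2 + (cc - gp$center_px[2])^2 <= gp$radius_px^2
      img[ing] <- hu
    }
    if (spec$noise_sd_hu > 0)
      img <- img + matrix(rnorm(n * n, 0, spec$noise_sd_hu), n, n)
    list(image = lesion_image(img, spec$spacing_mm), mask = roi_mask(mask),
         blob_centers = centers)
  })
}
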