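## texture_core: LoG filtration + excess-kurtosis histogram analysis of a
## masked CT lesion.

#' Construct a lesion image
#'
#' A 2-D grid of CT attenuation values (Hounsfield units) on the single axial
#' slice with the largest lesion cross-section, together with the isotropic
#' in-plane pixel spacing in millimetres.
#'
#' @param pixels Numeric matrix of HU values.
#' @param spacing_mm Positive scalar, in-plane pixel size in mm (isotropic).
#' @return An object of class `lesion_image` with elements `pixels` and
#'   `spacing_mm`.
#' @export
lesion_image <- function(pixels, spacing_mm) {
  if (!is.matrix(pixels) || !is.numeric(pixels) || length(pixels) == 0L)
    ctta_stop("`pixels` must be a non-empty numeric matrix", "bad_image")
  if (!all(is.finite(pixels)))
    ctta_stop("image contains non-finite attenuation values", "bad_image")
  if (!is.numeric(spacing_mm) || length(spacing_mm) != 1L ||
      !is.finite(spacing_mm) || spacing_mm <= 0)
    ctta_stop("`spacing_mm` must be a single positive number", "bad_image")
  structure(list(pixels = pixels, spacing_mm = as.numeric(spacing_mm)),
            class = "lesion_image")
}

#' Construct a region-of-interest mask
#'
#' A binary grid congruent with its lesion image; the TRUE pixels form the
#' region R over which the attenuation histogram is analysed.
#'
#' @param mask Logical (or 0/1 numeric) matrix.
#' @return An object of class `roi_mask` with elements `mask` (logical matrix)
#'   and `n_pixels` (count of TRUE pixels).
#' @export
roi_mask <- function(mask) {
  if (is.numeric(mask)) mask <- mask > 0.5
  if (!is.matrix(mask) || !is.logical(mask) || length(mask) == 0L)
    ctta_stop("`mask` must be a non-empty logical matrix", "bad_mask")
  mask[is.na(mask)] <- FALSE
  n <- sum(mask)
  if (n < 1L)
    ctta_stop("mask contains no pixels", "empty_roi")
  structure(list(mask = mask, n_pixels = n), class = "roi_mask")
}

check_congruent <- function(image, mask) {
  if (!identical(dim(image$pixels), dim(mask$mask)))
    ctta_stop(sprintf("image (%s) and mask (%s) grids are not congruent",
                      paste(dim(image$pixels), collapse = "x"),
                      paste(dim(mask$mask), collapse = "x")),
              "shape_mismatch")
  invisible(TRUE)
}

#' Refine an ROI by excluding gas
#'
#' Removes from the mask every pixel whose attenuation is strictly below the
#' threshold (default -50 HU), the automatic contouring step that excludes
#' gas from a freehand tumour ROI. Idempotent; the pixel count never grows.
#'
#' @param mask An [roi_mask()] congruent with `image`.
#' @param image The [lesion_image()] the mask lives on.
#' @param hu_threshold Exclusion threshold in HU; pixels with value
#'   `< hu_threshold` are dropped. Default -50.
#' @return The refined `roi_mask`.
#' @export
auto_contour <- function(mask, image, hu_threshold = -50) {
  check_congruent(image, mask)
  keep <- mask$mask & (image$pixels >= hu_threshold)
  if (!any(keep))
    ctta_stop("auto-contour removed every ROI pixel (lesion unanalyzable)",
              "empty_roi")
  roi_mask(keep)
}

#' Erode a binary mask by a disc
#'
#' Optional boundary clean-up: a pixel survives only if every pixel within
#' `radius_px` of it (Euclidean, pixel units) is inside the mask. Radius 0 is
#' the identity.
#'
#' @param mask An [roi_mask()].
#' @param radius_px Non-negative erosion radius in pixels.
#' @return The eroded `roi_mask`.
#' @export
erode_mask <- function(mask, radius_px = 0) {
  if (radius_px <= 0) return(mask)
  m <- mask$mask
  r <- ceiling(radius_px)
  offs <- expand.grid(dr = -r:r, dc = -r:r)
  offs <- offs[offs$dr^2 + offs$dc^2 <= radius_px^2, , drop = FALSE]
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(TRUE, nr, nc)
  padded <- matrix(FALSE, nr + 2L * r, nc + 2L * r)
  padded[(r + 1L):(r + nr), (r + 1L):(r + nc)] <- m
  for (i in seq_len(nrow(offs))) {
    dr <- offs$dr[i]; dc <- offs$dc[i]
    out <- out & padded[(r + 1L + dr):(r + nr + dr), (r + 1L + dc):(r + nc + dc)]
  }
  if (!any(out))
    ctta_stop("erosion removed every ROI pixel", "empty_roi")
  roi_mask(out)
}

#' Laplacian-of-Gaussian kernel for a spatial scale filter
#'
#' Builds the 2-D LoG kernel whose pass band highlights image features of
#' approximately `ssf_mm` radius. The Gaussian scale is
#' `sigma_mm = ssf_mm / sqrt(2)`, which puts the kernel's zero-crossing circle
#' at radius `ssf_mm` and maximizes the response to a Gaussian blob of that
#' nominal radius; `sigma_px = sigma_mm / spacing_mm`. Support is truncated at
#' `trunc_sigmas` (odd-sized kernel) and the entries are recentred so they sum
#' to exactly zero, making the filter exactly DC-invariant.
#'
#' @param ssf_mm Feature radius in mm (canonically 2-6).
#' @param spacing_mm Pixel size in mm.
#' @param trunc_sigmas Truncation half-width in units of sigma (default 4).
#' @return Numeric matrix with attributes `sigma_px` and `half_width`.
#' @export
log_kernel <- function(ssf_mm, spacing_mm, trunc_sigmas = 4) {
  if (ssf_mm <= 0 || !is.finite(ssf_mm))
    ctta_stop("`ssf_mm` must be a positive length", "scale_too_fine")
  if (ssf_mm < spacing_mm)
    ctta_stop(sprintf("scale %.3g mm is finer than one pixel (%.3g mm)",
                      ssf_mm, spacing_mm), "scale_too_fine")
  sigma_px <- (ssf_mm / sqrt(2)) / spacing_mm
  m <- as.integer(ceiling(trunc_sigmas * sigma_px))
  x <- -m:m
  r2 <- outer(x^2, x^2, `+`)
  k <- (r2 - 2 * sigma_px^2) / sigma_px^4 * exp(-r2 / (2 * sigma_px^2))
  k <- k - mean(k)           # exact zero sum
  attr(k, "sigma_px") <- sigma_px
  attr(k, "half_width") <- m
  k
}

## Symmetric (edge-including) reflective padding by m pixels on each side.
pad_reflect <- function(x, m) {
  nr <- nrow(x); nc <- ncol(x)
  if (m >= nr || m >= nc)
    ctta_stop("image too small for the requested filter scale", "image_too_small")
  ri <- c(m:1, 1:nr, nr:(nr - m + 1L))
  ci <- c(m:1, 1:nc, nc:(nc - m + 1L))
  x[ri, ci, drop = FALSE]
}

## Linear convolution with mirror boundary, computed as a circular FFT
## convolution on the reflect-padded grid (pad margin = kernel half-width, so
## no wrap-around reaches the original region).
convolve_reflect <- function(pixels, kernel) {
  m <- attr(kernel, "half_width")
  p <- pad_reflect(pixels, m)
  nr <- nrow(p); nc <- ncol(p)
  kb <- matrix(0, nr, nc)
  idx_r <- ((-m:m) %% nr) + 1L
  idx_c <- ((-m:m) %% nc) + 1L
  kb[idx_r, idx_c] <- kernel[, , drop = FALSE]
  out <- Re(fft(fft(p) * fft(kb), inverse = TRUE)) / (nr * nc)
  out[(m + 1L):(m + nrow(pixels)), (m + 1L):(m + ncol(pixels)), drop = FALSE]
}

#' Apply LoG band-pass filtration at a spatial scale
#'
#' Convolves the whole image with the [log_kernel()] for `ssf_mm`, using
#' mirror (reflective) boundary padding. Scale 0 ("without filtration") is a
#' caller-side identity and is rejected here.
#'
#' @inheritParams log_kernel
#' @param image A [lesion_image()].
#' @return A `lesion_image` of the filtered response (same grid and spacing).
#' @export
log_filter <- function(image, ssf_mm, trunc_sigmas = 4) {
  k <- log_kernel(ssf_mm, image$spacing_mm, trunc_sigmas)
  out <- convolve_reflect(image$pixels, k)
  structure(list(pixels = out, spacing_mm = image$spacing_mm),
            class = "lesion_image")
}

#' Bias-corrected sample excess kurtosis
#'
#' The histogram "sharpness" statistic: for a sample of n values with mean
#' a-bar and sample standard deviation sd,
#' \deqn{k = \frac{n(n+1)\sum (a_i-\bar a)^4}{(n-1)(n-2)(n-3)\,sd^4}
#'       - \frac{3(n-1)^2}{(n-2)(n-3)},}
#' which is zero in expectation for Gaussian data, positive for histograms
#' more peaked/heavy-tailed than Gaussian, negative for flatter ones. The
#' denominators require n >= 4 and sd > 0.
#'
#' @param values Numeric vector (n >= 4, non-degenerate).
#' @return The excess kurtosis (dimensionless scalar).
#' @export
excess_kurtosis <- function(values) {
  values <- as.numeric(values)
  if (anyNA(values) || !all(is.finite(values)))
    ctta_stop("values must be finite", "bad_values")
  n <- length(values)
  if (n < 4L)
    ctta_stop("excess kurtosis needs at least 4 pixels", "insufficient_pixels")
  d <- values - mean(values)
  s2 <- sum(d^2) / (n - 1)
  if (s2 == 0)
    ctta_stop("zero-variance histogram (all pixel values equal)",
              "degenerate_histogram")
  n * (n + 1) * sum(d^4) / ((n - 1) * (n - 2) * (n - 3) * s2^2) -
    3 * (n - 1)^2 / ((n - 2) * (n - 3))
}

#' Filtration-histogram texture profile of a masked lesion
#'
#' For each requested spatial scale, filters the full image (so out-of-mask
#' context contributes to the convolution), samples the response at in-mask
#' pixel positions, and reports the excess kurtosis of that histogram. Scale 0
#' is the unfiltered control: kurtosis of the raw in-mask HU values. The mask
#' is first refined by [auto_contour()] (gas exclusion below `hu_threshold`)
#' unless `refine = FALSE`; an optional erosion of the refined mask is
#' available (default none). A scale whose histogram is degenerate or too
#' small is recorded as missing (NA) rather than aborting the profile.
#'
#' @param image A [lesion_image()].
#' @param mask An [roi_mask()] congruent with `image`.
#' @param scales Subset of `c(0, 2, 3, 4, 5, 6)` (mm; 0 = no filtration).
#' @param hu_threshold Gas-exclusion threshold passed to [auto_contour()].
#' @param refine Apply [auto_contour()] first? Default TRUE.
#' @param erosion_px Optional mask erosion radius in pixels (default 0).
#' @return An object of class `texture_profile`: list with `values` (named
#'   numeric, names "k0","k2",...; NA = missing), `n_pixels` (refined ROI
#'   size), and `missing` (character vector of scales that failed, with
#'   reasons as names).
#' @export
compute_texture_profile <- function(image, mask, scales = SSF_SCALES,
                                    hu_threshold = -50, refine = TRUE,
                                    erosion_px = 0) {
  check_congruent(image, mask)
  if (!all(scales %in% SSF_SCALES))
    ctta_stop(sprintf("scales must be drawn from {%s}",
                      paste(SSF_SCALES, collapse = ", ")), "bad_scale")
  scales <- sort(unique(scales))
  if (refine) mask <- auto_contour(mask, image, hu_threshold)
  if (erosion_px > 0) mask <- erode_mask(mask, erosion_px)
  idx <- which(mask$mask)
  vals <- setNames(rep(NA_real_, length(scales)), scale_col(scales))
  missing <- character(0)
  ## Filtered responses whose spread is numerically zero relative to the raw
  ## ROI contrast (or below ~1e-9 HU, far under CT quantization) are treated
  ## as degenerate rather than analysing floating-point residue.
  raw_sd <- sd(image$pixels[idx])
  sd_floor <- 1e-9 * max(raw_sd, 1)
  for (s in scales) {
    samp <- if (s == 0) image$pixels[idx] else log_filter(image, s)$pixels[idx]
    if (length(samp) >= 2L && sd(samp) <= sd_floor)
      samp <- rep(samp[1], length(samp))   # forces the degenerate signal
    k <- tryCatch(excess_kurtosis(samp), cttasurv_error = function(e) {
      missing <<- c(missing, setNames(as.character(s), conditionMessage(e)))
      NA_real_
    })
    vals[scale_col(s)] <- k
  }
  structure(list(values = vals, n_pixels = mask$n_pixels, missing = missing,
                 scales = scales),
            class = "texture_profile")
}

#' @export
print.texture_profile <- function(x, ...) {
  cat("Filtration-histogram texture profile (", x$n_pixels, " ROI pixels)\n",
      sep = "")
  tab <- data.frame(ssf_mm = x$scales, kurtosis = unname(x$values))
  print(tab, row.names = FALSE, digits = 4)
  if (length(x$missing))
    cat("missing scales:", paste(x$missing, collapse = ", "), "\n")
  invisible(x)
}
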