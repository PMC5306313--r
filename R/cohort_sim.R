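## synthetic_data (part 2): simulated lymphoma cohorts whose progression
## hazard depends jointly on a latent texture class and interim-PET status,
## with administrative censoring over a 10-62 month follow-up window.

## Class-conditional calibration used by the "marker" imaging mode: per-lesion
## kurtosis at each scale is drawn from a normal with these means/sds. The
## separation is strongest at SSF = 5 mm (low-class mean -0.16 vs high-class
## 2.18, the subgroup means seen in iPET-negative patients), weaker elsewhere.
MARKER_CLASS_PARAMS <- list(
  scales    = SSF_SCALES,
  mean_low  = c(0.55, 0.45, 0.50, 0.35, -0.16, 0.00),
  mean_high = c(1.30, 0.70, 1.30, 0.95,  2.18, 1.35),
  sd        = c(2.00, 1.00, 1.30, 1.20,  0.90, 1.30)
)

## Blob parameters behind the "phantom" imaging mode. Kurtosis is inversely
## related to the number of highlighted objects, so the high-kurtosis class
## has few large high-contrast blobs and the low-kurtosis class many small
## low-contrast ones.
PHANTOM_CLASS_PARAMS <- list(
  low  = list(blob_count = 28L, blob_radius_mm = 2, blob_amplitude_hu = 45,
              noise_sd_hu = 8),
  high = list(blob_count = 4L, blob_radius_mm = 5, blob_amplitude_hu = 130,
              noise_sd_hu = 8)
)

#' Specify a simulated lymphoma cohort
#'
#' Each simulated patient carries a lymphoma subtype, a latent texture class
#' (low/high kurtosis), an underlying interim-PET status (possibly missing at
#' measurement), 1-5 lesions with SUVmax and per-scale kurtosis, and a
#' progression-free-survival outcome drawn from an exponential hazard set by
#' the (iPET, texture-class) risk tier, administratively censored at a uniform
#' follow-up time.
#'
#' @param n_patients Cohort size (default 45).
#' @param fraction_hl Fraction of Hodgkin's lymphoma (default 18/45).
#' @param fraction_ipet_positive P(iPET positive) among measured (default 7/37).
#' @param fraction_ipet_missing P(iPET not performed) (default 8/45).
#' @param p_high_texture_neg P(high-kurtosis class | iPET negative), default
#'   16/30; `p_high_texture_pos` defaults to 1 (iPET-positive patients carry
#'   the highest kurtosis values).
#' @param p_high_texture_pos See above.
#' @param prog_40mo Named progression probabilities by 40 months for the
#'   `lower` / `intermediate` / `higher` risk tiers (defaults 0.02, 0.30,
#'   0.70); converted to monthly exponential hazards
#'   `-log(1 - p)/40`. Supply `hazard_monthly` to set hazards directly.
#' @param hazard_monthly Optional named monthly hazards overriding `prog_40mo`.
#' @param follow_up_months Administrative censoring window, uniform over
#'   `c(min, max)` months (default `c(10, 62)`).
#' @param lesions_range Integer range of lesions per patient (default 1:5).
#' @param imaging `"phantom"` renders blob phantoms and measures kurtosis
#'   through the texture pipeline (the full end-to-end route); `"marker"`
#'   draws per-lesion kurtosis directly from the class-conditional
#'   calibration (fast path for large simulation studies).
#' @param grid,spacing_mm Phantom geometry for `imaging = "phantom"`.
#' @param suv_meanlog Named meanlog of the lognormal SUVmax distribution per
#'   subtype (defaults `log(13.2)` for HL, `log(20.5)` for NHL).
#' @param suv_sdlog Lognormal sdlog for SUVmax (default 0.5).
#' @param seed Optional RNG seed (full determinism under a fixed seed).
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_patients = 45L, fraction_hl = 18 / 45,
                        fraction_ipet_positive = 7 / 37,
                        fraction_ipet_missing = 8 / 45,
                        p_high_texture_neg = 16 / 30,
                        p_high_texture_pos = 1.0,
                        prog_40mo = c(lower = 0.02, intermediate = 0.30,
                                      higher = 0.70),
                        hazard_monthly = NULL,
                        follow_up_months = c(10, 62),
                        lesions_range = 1:5,
                        imaging = c("phantom", "marker"),
                        grid = 64L, spacing_mm = 0.98,
                        suv_meanlog = c(HL = log(13.2), NHL = log(20.5)),
                        suv_sdlog = 0.5,
                        seed = NULL) {
  imaging <- match.arg(imaging)
  fr <- c(fraction_hl, fraction_ipet_positive, fraction_ipet_missing,
          p_high_texture_neg, p_high_texture_pos)
  if (any(fr < 0 | fr > 1)) ctta_stop("fractions must lie in [0, 1]", "bad_spec")
  if (is.null(hazard_monthly)) {
    if (any(prog_40mo < 0 | prog_40mo >= 1))
      ctta_stop("40-month progression probabilities must lie in [0, 1)", "bad_spec")
    hazard_monthly <- -log(1 - prog_40mo) / 40
  }
  need <- c("lower", "intermediate", "higher")
  if (!all(need %in% names(hazard_monthly)) || any(hazard_monthly < 0))
    ctta_stop("hazard_monthly needs non-negative lower/intermediate/higher entries",
              "bad_spec")
  if (length(follow_up_months) != 2L || diff(follow_up_months) < 0)
    ctta_stop("follow_up_months must be an increasing (min, max) pair", "bad_spec")
  structure(list(n_patients = as.integer(n_patients), fraction_hl = fraction_hl,
                 fraction_ipet_positive = fraction_ipet_positive,
                 fraction_ipet_missing = fraction_ipet_missing,
                 p_high_texture_neg = p_high_texture_neg,
                 p_high_texture_pos = p_high_texture_pos,
                 hazard_monthly = hazard_monthly[need],
                 follow_up_months = follow_up_months,
                 lesions_range = lesions_range, imaging = imaging,
                 grid = as.integer(grid), spacing_mm = spacing_mm,
                 suv_meanlog = suv_meanlog, suv_sdlog = suv_sdlog,
                 seed = seed),
            class = "cohort_spec")
}

lesion_kurtosis_marker <- function(class, params = MARKER_CLASS_PARAMS) {
  mu <- if (class == "high") params$mean_high else params$mean_low
  setNames(rnorm(length(params$scales), mu, params$sd),
           scale_col(params$scales))
}

lesion_kurtosis_phantom <- function(class, spec) {
  bp <- PHANTOM_CLASS_PARAMS[[class]]
  amps <- bp$blob_amplitude_hu * sample(c(-1, 1), bp$blob_count, replace = TRUE)
  ph <- generate_phantom(phantom_spec(
    grid = spec$grid, spacing_mm = spec$spacing_mm,
    blob_count = bp$blob_count, blob_radius_mm = bp$blob_radius_mm,
    blob_amplitude_hu = amps, noise_sd_hu = bp$noise_sd_hu))
  prof <- compute_texture_profile(ph$image, ph$mask)
  list(values = prof$values, n_pixels = prof$n_pixels, phantom = ph)
}

#' Generate a simulated cohort
#'
#' Draws the cohort described by a [cohort_spec()]. With `dir` set, phantom
#' images and masks are written as NIfTI and the lesion/clinical tables as
#' CSV in the schemas consumed by the analysis pipeline; otherwise everything
#' stays in memory (lesion kurtosis columns `k0`, `k2`, ..., `k6`).
#'
#' @param spec A [cohort_spec()].
#' @param dir Optional output directory for NIfTI phantoms + CSV tables.
#' @return An object of class `ctta_cohort`: list with `clinical`
#'   (patient-level data frame: patient_id, subtype, stage, treatment, ipet,
#'   bulk_px, pfs_months, event, plus the latent `texture_class` and `tier`
#'   used in simulation), `lesions` (lesion-level data frame with suv_max,
#'   area_px and kurtosis columns), `follow_up_window`, and `spec`.
#' @export
generate_cohort <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, {
    n <- spec$n_patients
    if (n < 1L) ctta_stop("need at least one patient", "bad_spec")
    ids <- sprintf("P%03d", seq_len(n))
    subtype <- ifelse(runif(n) < spec$fraction_hl, "HL", "NHL")
    ipet_true <- ifelse(runif(n) < spec$fraction_ipet_positive,
                        "positive", "negative")
    ipet_missing <- runif(n) < spec$fraction_ipet_missing
    p_high <- ifelse(ipet_true == "positive", spec$p_high_texture_pos,
                     spec$p_high_texture_neg)
    texture_class <- ifelse(runif(n) < p_high, "high", "low")
    tier <- as.character(stratify_three_groups(texture_class == "high", ipet_true))
    haz <- spec$hazard_monthly[tier]
    t_event <- ifelse(haz > 0, rexp(n) / pmax(haz, .Machine$double.xmin), Inf)
    cens <- runif(n, spec$follow_up_months[1], spec$follow_up_months[2])
    pfs <- pmin(t_event, cens)
    event <- as.integer(t_event <= cens)
    stage <- sample(c("I", "II", "III", "IV"), n, replace = TRUE,
                    prob = c(5, 17, 9, 14) / 45)
    treatment <- sample(c("standard", "non_standard"), n, replace = TRUE,
                        prob = c(35, 10) / 45)
    ipet_obs <- ifelse(ipet_missing, NA_character_, ipet_true)

    les <- list()
    phantoms <- list()
    for (i in seq_len(n)) {
      nl <- sample(spec$lesions_range, 1L)
      for (j in seq_len(nl)) {
        suv <- rlnorm(1, spec$suv_meanlog[[subtype[i]]], spec$suv_sdlog)
        lid <- sprintf("%s_L%02d", ids[i], j)
        if (spec$imaging == "phantom") {
          lk <- lesion_kurtosis_phantom(texture_class[i], spec)
          area <- lk$n_pixels
          if (!is.null(dir)) phantoms[[lid]] <- lk$phantom
          kv <- lk$values
        } else {
          kv <- lesion_kurtosis_marker(texture_class[i])
          area <- round(rlnorm(1, log(1200), 0.8))
        }
        les[[length(les) + 1L]] <- data.frame(
          patient_id = ids[i], lesion_id = lid, suv_max = suv,
          area_px = area, as.list(kv), check.names = FALSE,
          stringsAsFactors = FALSE)
      }
    }
    lesions <- do.call(rbind, les)
    bulk <- tapply(lesions$area_px, lesions$patient_id, sum)[ids]
    clinical <- data.frame(
      patient_id = ids, subtype = subtype, stage = stage,
      treatment = treatment, ipet = ipet_obs, bulk_px = as.numeric(bulk),
      pfs_months = pfs, event = event,
      texture_class = texture_class, tier = tier,
      stringsAsFactors = FALSE)

    cohort <- structure(list(clinical = clinical, lesions = lesions,
                             follow_up_window = spec$follow_up_months,
                             spec = spec),
                        class = "ctta_cohort")
    if (!is.null(dir)) write_cohort(cohort, dir, phantoms)
    cohort
  })
}

#' @export
print.ctta_cohort <- function(x, ...) {
  cl <- x$clinical
  cat("Simulated cohort:", nrow(cl), "patients,", nrow(x$lesions), "lesions\n")
  cat("  progressed:", sum(cl$event), " censored:", sum(cl$event == 0), "\n")
  cat("  tiers:", paste(sprintf("%s=%d", names(table(cl$tier)),
                                as.integer(table(cl$tier))), collapse = ", "), "\n")
  invisible(x)
}
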