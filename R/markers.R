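## cohort_pipeline: lesion selection, per-patient aggregation, and
## Mann-Whitney marker screening.

#' Select the most FDG-avid lesions
#'
#' Keeps the `max_n` lesions with the highest SUVmax (all lesions when fewer
#' are available). Ties at the boundary are broken toward the
#' lexicographically smaller `lesion_id`, so the selection is deterministic.
#'
#' @param lesions Data frame with at least `lesion_id` and `suv_max` columns.
#' @param max_n Cap on the number of lesions used per patient (default 5).
#' @return The selected rows, ordered by decreasing SUVmax.
#' @export
select_lesions <- function(lesions, max_n = 5L) {
  if (is.null(lesions) || nrow(lesions) == 0L)
    ctta_stop("patient has no lesions", "no_lesion")
  ord <- order(-lesions$suv_max, as.character(lesions$lesion_id))
  lesions[head(ord, max_n), , drop = FALSE]
}

#' Aggregate selected lesions into patient-level markers
#'
#' The representative measurement per patient is the arithmetic mean over the
#' used lesions: per-scale kurtosis means use available cases (lesions with a
#' defined value at that scale); a scale missing in every lesion is missing
#' at the patient level. SUVmax is averaged over all used lesions and tumour
#' bulk is the summed lesion area in pixels.
#'
#' @param lesions Data frame of selected lesions with `suv_max`, `area_px`
#'   and kurtosis columns `k0`, `k2`, ... `k6`.
#' @return List with `ctta` (named per-scale means), `suv_max_patient`,
#'   `bulk_px` and `n_lesions`.
#' @export
aggregate_patient <- function(lesions) {
  if (is.null(lesions) || nrow(lesions) == 0L)
    ctta_stop("patient has no lesions", "no_lesion")
  kcols <- intersect(scale_col(SSF_SCALES), names(lesions))
  ctta <- vapply(kcols, function(cn) {
    v <- lesions[[cn]]
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }, numeric(1))
  list(ctta = ctta,
       suv_max_patient = mean(lesions$suv_max),
       bulk_px = sum(lesions$area_px),
       n_lesions = nrow(lesions))
}

#' Build the patient-level marker table
#'
#' Applies [select_lesions()] and [aggregate_patient()] to every patient and
#' joins the clinical covariates, yielding one row per patient with columns
#' `k0`...`k6`, `suv_max`, `bulk_px`, `n_lesions` plus the clinical table.
#'
#' @param lesions Lesion-level data frame (`patient_id`, `lesion_id`,
#'   `suv_max`, `area_px`, kurtosis columns).
#' @param clinical Patient-level data frame keyed by `patient_id`.
#' @param max_n Lesion cap per patient (default 5).
#' @return Patient marker data frame.
#' @export
build_patient_markers <- function(lesions, clinical, max_n = 5L) {
  if (anyDuplicated(clinical$patient_id))
    ctta_stop("duplicate patient_id in clinical table", "bad_table")
  rows <- lapply(clinical$patient_id, function(pid) {
    sel <- select_lesions(lesions[lesions$patient_id == pid, , drop = FALSE],
                          max_n)
    ag <- aggregate_patient(sel)
    data.frame(patient_id = pid, as.list(ag$ctta),
               suv_max = ag$suv_max_patient, bulk_px = ag$bulk_px,
               n_lesions = ag$n_lesions, check.names = FALSE,
               stringsAsFactors = FALSE)
  })
  mk <- do.call(rbind, rows)
  merge(mk, clinical[, setdiff(names(clinical), "bulk_px"), drop = FALSE],
        by = "patient_id", sort = TRUE)
}

#' Mann-Whitney U test
#'
#' Rank-sum comparison of two independent samples with midrank handling of
#' ties. For groups of at most 8 observations each the two-sided p-value is
#' computed by exact enumeration of all group assignments of the observed
#' (tied) ranks, `p = min(1, 2 min(P(U <= u), P(U >= u)))`; for larger groups
#' a normal approximation with tie-corrected variance is used (no continuity
#' correction).
#'
#' @param a,b Numeric samples (each of length >= 2).
#' @param exact Force the exact (`TRUE`) or asymptotic (`FALSE`) path;
#'   default `NULL` switches on group size 8.
#' @return List with `U` (statistic for sample `a`), `p` (two-sided), and
#'   `method` ("exact" or "asymptotic").
#' @export
mann_whitney <- function(a, b, exact = NULL) {
  a <- as.numeric(a); b <- as.numeric(b)
  na <- length(a); nb <- length(b)
  if (na < 2L || nb < 2L)
    ctta_stop("each group needs at least 2 observations", "underpowered_comparison")
  if (anyNA(c(a, b))) ctta_stop("samples must not contain NA", "bad_values")
  N <- na + nb
  r <- rank(c(a, b))
  U <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  if (is.null(exact)) exact <- max(na, nb) <= 8L
  if (exact) {
    cs <- combn(N, na)
    Ra <- colSums(matrix(r[cs], nrow = na))
    Ud <- Ra - na * (na + 1) / 2
    eps <- 1e-8
    p <- 2 * min(mean(Ud <= U + eps), mean(Ud >= U - eps))
    list(U = U, p = min(1, p), method = "exact")
  } else {
    mu <- na * nb / 2
    tie <- table(r)
    sig2 <- na * nb / 12 * ((N + 1) - sum(tie^3 - tie) / (N * (N - 1)))
    if (sig2 <= 0) return(list(U = U, p = 1, method = "asymptotic"))
    z <- (U - mu) / sqrt(sig2)
    list(U = U, p = 2 * pnorm(-abs(z)), method = "asymptotic")
  }
}

#' Select the best texture scale by relapse separation
#'
#' For every candidate spatial scale, compares patient-level kurtosis between
#' progressed and non-progressed patients with a Mann-Whitney test and
#' returns the scale with the lowest two-sided p (ties broken toward the
#' smaller scale). Scales missing in every patient, or with fewer than two
#' defined values in either group, are excluded from the candidates.
#'
#' @param markers Patient marker data frame (kurtosis columns + `event`).
#' @param scales Candidate scales, default `c(0, 2, 3, 4, 5, 6)`.
#' @return List with `ssf` (best scale, mm), `p` (its p-value), `table`
#'   (per-scale data frame of p-values), and `excluded` (scales dropped).
#' @export
select_best_texture_scale <- function(markers, scales = SSF_SCALES) {
  ev <- markers$event == 1
  tab <- data.frame(ssf_mm = numeric(0), U = numeric(0), p = numeric(0))
  excluded <- numeric(0)
  for (s in scales) {
    cn <- scale_col(s)
    if (!cn %in% names(markers)) { excluded <- c(excluded, s); next }
    x <- markers[[cn]][ev]; y <- markers[[cn]][!ev]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    if (length(x) < 2L || length(y) < 2L) { excluded <- c(excluded, s); next }
    mw <- mann_whitney(x, y)
    tab <- rbind(tab, data.frame(ssf_mm = s, U = mw$U, p = mw$p))
  }
  if (nrow(tab) == 0L)
    ctta_stop("no texture scale has enough data in both outcome groups",
              "underpowered_comparison")
  best <- which(tab$p == min(tab$p))[1]   # table ordered by ssf: tie -> smaller
  list(ssf = tab$ssf_mm[best], p = tab$p[best], table = tab,
       excluded = excluded)
}
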