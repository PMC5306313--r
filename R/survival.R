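## survival_stratification: optimized Kaplan-Meier dichotomization,
## Benjamini-Hochberg control, Cox modelling with a CTTA-by-iPET interaction,
## and three-tier risk grouping.

#' Kaplan-Meier curve with restricted mean survival
#'
#' Product-limit estimate of progression-free survival, plus the restricted
#' mean survival time: the area under the KM step curve up to the largest
#' observed time in the sample (the usual "mean survival in months" of
#' survival tables).
#'
#' @param time Follow-up times in months (>= 0).
#' @param event Progression indicator (1 = progressed, 0 = censored).
#' @return Object of class `km_curve`: data frame `steps` (time, n_risk,
#'   n_event, surv), `rmean` (months), `rmean_tmax` (restriction time), `n`.
#' @export
km_curve <- function(time, event) {
  if (length(time) < 1L) ctta_stop("empty survival sample", "bad_values")
  if (length(time) != length(event)) ctta_stop("length mismatch", "bad_values")
  if (any(time < 0)) ctta_stop("negative follow-up time", "bad_values")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  steps <- data.frame(time = fit$time, n_risk = fit$n.risk,
                      n_event = fit$n.event, surv = fit$surv)
  tmax <- max(time)
  tt <- steps$time[steps$time <= tmax]
  ss <- steps$surv[steps$time <= tmax]
  # area under the right-continuous step function S(t), S(0) = 1
  rmean <- sum(diff(c(0, tt, tmax)) * c(1, ss))
  structure(list(steps = steps, rmean = rmean, rmean_tmax = tmax,
                 n = length(time)), class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat("Kaplan-Meier curve: n =", x$n, "\n")
  cat(sprintf("restricted mean survival %.1f months (to t = %.1f)\n",
              x$rmean, x$rmean_tmax))
  invisible(x)
}

#' @export
plot.km_curve <- function(x, xlab = "Months", ylab = "Progression-free survival",
                          ...) {
  st <- x$steps
  plot(c(0, st$time), c(1, st$surv), type = "s", ylim = c(0, 1),
       xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

#' Two-group log-rank test
#'
#' Standard 1-df log-rank chi-square: at each event time the observed minus
#' expected events in one group, with hypergeometric variance; p from the
#' chi-square upper tail. Symmetric in the group labels.
#'
#' @param time,event Survival sample (months, 1 = progressed).
#' @param group Two-level grouping vector.
#' @return List with `chi2`, `p`, `n` and `n_events`.
#' @export
logrank_test <- function(time, event, group) {
  group <- as.factor(group)
  if (nlevels(droplevels(group)) != 2L)
    ctta_stop("log-rank test needs exactly two non-empty groups",
              "untestable_contrast")
  if (sum(event) < 1L)
    ctta_stop("no events: log-rank contrast untestable", "untestable_contrast")
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  list(chi2 = unname(sd$chisq),
       p = pchisq(unname(sd$chisq), df = 1, lower.tail = FALSE),
       n = length(time), n_events = sum(event))
}

#' Optimized Kaplan-Meier cutpoint for a prognostic marker
#'
#' Searches the midpoints between consecutive distinct marker values for the
#' threshold that best separates good and poor prognosis, i.e. minimizes the
#' two-group log-rank p-value of "above threshold" versus "at or below
#' threshold". Candidate splits leaving fewer than `min_group` patients on
#' either side are not considered; p ties are broken toward the smaller
#' threshold. Because the threshold is chosen to minimize p, the reported
#' p-value is anti-conservative and is corrected downstream across the
#' marker family (see [bh_adjust()]).
#'
#' @param marker Numeric marker values, one per patient.
#' @param time,event Survival sample.
#' @param min_group Minimum group size on each side of a split (default 3).
#' @param marker_name Label carried into the result.
#' @return Object of class `cutpoint_result`: threshold, p_logrank, counts
#'   and restricted mean survivals above/below, and the searched candidate
#'   table.
#' @export
optimal_cutpoint <- function(marker, time, event, min_group = 3L,
                             marker_name = deparse(substitute(marker))) {
  keep <- !is.na(marker)
  marker <- marker[keep]; time <- time[keep]; event <- event[keep]
  v <- sort(unique(marker))
  if (length(v) < 2L)
    ctta_stop("marker is constant: no candidate thresholds", "no_candidate")
  cand <- (v[-1] + v[-length(v)]) / 2
  ok <- vapply(cand, function(cp) {
    sum(marker > cp) >= min_group && sum(marker <= cp) >= min_group
  }, logical(1))
  cand <- cand[ok]
  if (length(cand) == 0L)
    ctta_stop("no admissible split leaves enough patients on both sides",
              "groups_too_small")
  ps <- vapply(cand, function(cp) {
    tryCatch(logrank_test(time, event, marker > cp)$p,
             cttasurv_untestable_contrast = function(e) NA_real_)
  }, numeric(1))
  if (all(is.na(ps)))
    ctta_stop("no events: cutpoint search untestable", "untestable_contrast")
  best <- which(ps == min(ps, na.rm = TRUE))[1]  # candidates ascending: tie -> smaller
  thr <- cand[best]
  above <- marker > thr
  km_a <- km_curve(time[above], event[above])
  km_b <- km_curve(time[!above], event[!above])
  structure(list(marker_name = marker_name, threshold = thr,
                 p_logrank = ps[best],
                 n_above = sum(above), n_below = sum(!above),
                 mean_survival_above = km_a$rmean,
                 mean_survival_below = km_b$rmean,
                 candidates = data.frame(threshold = cand, p = ps)),
            class = "cutpoint_result")
}

#' @export
print.cutpoint_result <- function(x, ...) {
  cat(sprintf("Optimized KM cutpoint for %s: > %.4g (log-rank p = %.4g)\n",
              x$marker_name, x$threshold, x$p_logrank))
  cat(sprintf("  above: n = %d, mean PFS %.1f months; below: n = %d, mean PFS %.1f months\n",
              x$n_above, x$mean_survival_above, x$n_below,
              x$mean_survival_below))
  invisible(x)
}

#' Benjamini-Hochberg step-up procedure
#'
#' Controls the false discovery rate at level `q` across `m` tests: the
#' critical value at rank i is `i * q / m` and all hypotheses ranked at or
#' below the largest i with `p_(i) <= i q / m` are rejected. Significance
#' flags are obtained from `stats::p.adjust(., "BH") <= q`, which implements
#' the same step-up rule.
#'
#' @param raw_ps Raw p-values in (0, 1].
#' @param q FDR level (default 0.05).
#' @return Object of class `bh_result`: data frame in the input order with
#'   raw_p, rank, critical_value, adjusted_p, significant; attributes `m`
#'   and `q`.
#' @export
bh_adjust <- function(raw_ps, q = 0.05) {
  raw_ps <- as.numeric(raw_ps)
  if (length(raw_ps) < 1L) ctta_stop("no p-values supplied", "bad_values")
  if (any(is.na(raw_ps) | raw_ps <= 0 | raw_ps > 1))
    ctta_stop("raw p-values must lie in (0, 1]", "bad_values")
  if (q <= 0 || q >= 1) ctta_stop("q must lie in (0, 1)", "bad_values")
  m <- length(raw_ps)
  rk <- rank(raw_ps, ties.method = "first")
  adj <- p.adjust(raw_ps, method = "BH")
  out <- data.frame(raw_p = raw_ps, rank = rk,
                    critical_value = rk * q / m,
                    adjusted_p = adj,
                    significant = adj <= q)
  structure(out, m = m, q = q, class = c("bh_result", "data.frame"))
}

#' @export
print.bh_result <- function(x, ...) {
  cat(sprintf("Benjamini-Hochberg step-up: m = %d tests, FDR q = %g, %d significant\n",
              attr(x, "m"), attr(x, "q"), sum(x$significant)))
  NextMethod()
}

## Resolve exactly aliased (duplicate) covariate columns. When an interaction
## column duplicates a main-effect column (the empty-cell situation: every
## iPET-positive patient is high-texture), the two parametrizations have the
## same likelihood; we keep the interaction term, matching how the surviving
## predictor is reported clinically.
drop_aliased <- function(X) {
  dropped <- character(0)
  j <- 1L
  while (j <= ncol(X)) {
    dup <- which(vapply(seq_len(ncol(X)), function(k) {
      k != j && isTRUE(all.equal(X[[j]], X[[k]], tolerance = 0))
    }, logical(1)))
    if (length(dup)) {
      grp <- c(j, dup)
      inter <- grepl("_x_", names(X)[grp])
      keep <- if (any(inter)) grp[inter][1] else grp[1]
      kill <- setdiff(grp, keep)
      dropped <- c(dropped, names(X)[kill])
      X <- X[, -kill, drop = FALSE]
      j <- 1L
    } else j <- j + 1L
  }
  list(X = X, dropped = dropped)
}

cox_term_table <- function(fit) {
  s <- summary(fit)
  co <- s$coefficients
  ci <- s$conf.int
  data.frame(term = rownames(co),
             log_hr = co[, "coef"],
             hazard_ratio = ci[, "exp(coef)"],
             ci95_low = ci[, "lower .95"],
             ci95_high = ci[, "upper .95"],
             p_wald = co[, "Pr(>|z|)"],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Cox proportional-hazards fit with backward elimination
#'
#' Multivariate Cox partial-likelihood fit (Efron tie handling by default,
#' Breslow available) of progression-free survival on a set of 0/1 or
#' numeric covariates, which may include product (interaction) terms. After
#' the full-model fit, terms are removed one at a time by backward
#' elimination of the largest Wald p >= `alpha`, refitting after each
#' removal; both the full and the reduced (final) model are reported.
#' Constant columns are dropped with a flag; exactly aliased columns are
#' resolved in favour of interaction terms; non-convergence or monotone
#' likelihood is flagged as an unstable fit.
#'
#' @param time,event Survival sample (months, 1 = progressed).
#' @param covariates Data frame of numeric covariates; name interaction
#'   columns with `"_x_"` (e.g. `ctta_high_x_ipet_pos`) so aliasing resolves
#'   toward them.
#' @param ties `"efron"` (default) or `"breslow"`.
#' @param eliminate Run backward elimination (default TRUE).
#' @param alpha Wald p threshold for staying in the model (default 0.05).
#' @return Object of class `cox_result`: `full` and `final` term tables
#'   (hazard_ratio, ci95_low/high, p_wald), `loglik`, `dropped`,
#'   `eliminated`, `unstable`, `n`, `n_events`, and the final `fit`.
#' @export
cox_fit <- function(time, event, covariates, ties = c("efron", "breslow"),
                    eliminate = TRUE, alpha = 0.05) {
  ties <- match.arg(ties)
  X <- as.data.frame(covariates)
  if (nrow(X) != length(time)) ctta_stop("covariate length mismatch", "bad_values")
  const <- vapply(X, function(v) length(unique(v)) < 2L, logical(1))
  dropped <- names(X)[const]
  X <- X[, !const, drop = FALSE]
  if (ncol(X) == 0L)
    ctta_stop("no non-constant covariates to fit", "no_candidate")
  al <- drop_aliased(X)
  X <- al$X
  dropped <- c(dropped, al$dropped)
  n_events <- sum(event)
  if (n_events < 5 * ncol(X))
    ctta_warn(sprintf("only %d events for %d terms (< 5 per term)",
                      n_events, ncol(X)), "events_per_term")

  unstable <- FALSE
  fit_once <- function(dat) {
    withCallingHandlers(
      survival::coxph(survival::Surv(time, event) ~ ., data = dat, ties = ties),
      warning = function(w) {
        if (grepl("converge|infinite|beta may be infinite|Loglik", conditionMessage(w)))
          unstable <<- TRUE
        invokeRestart("muffleWarning")
      })
  }
  dat <- cbind(data.frame(time = time, event = event), X)
  full_fit <- fit_once(dat)
  full <- cox_term_table(full_fit)
  eliminated <- character(0)
  terms <- names(X)
  fit <- full_fit
  if (eliminate) {
    repeat {
      tab <- cox_term_table(fit)
      pw <- ifelse(is.na(tab$p_wald), 1, tab$p_wald)
      if (all(pw < alpha) || length(terms) == 0L) break
      worst <- tab$term[which.max(pw)]
      if (max(pw) < alpha) break
      terms <- setdiff(terms, worst)
      eliminated <- c(eliminated, worst)
      if (length(terms) == 0L) { fit <- NULL; break }
      fit <- fit_once(dat[, c("time", "event", terms), drop = FALSE])
    }
  }
  final <- if (is.null(fit)) full[0, , drop = FALSE] else cox_term_table(fit)
  if (unstable)
    ctta_warn("unstable Cox fit (non-convergence or monotone likelihood)",
              "unstable_fit")
  structure(list(full = full, final = final,
                 loglik = unname(full_fit$loglik[2]),
                 dropped = dropped, eliminated = eliminated,
                 unstable = unstable, n = nrow(dat), n_events = n_events,
                 fit = fit),
            class = "cox_result")
}

#' @export
print.cox_result <- function(x, digits = 3, ...) {
  cat(sprintf("Cox proportional-hazards fit: n = %d, events = %d, loglik = %.2f\n",
              x$n, x$n_events, x$loglik))
  cat("Full model:\n")
  print(x$full, digits = digits, row.names = FALSE)
  if (length(x$eliminated)) {
    cat("Backward elimination removed:", paste(x$eliminated, collapse = ", "), "\n")
    cat("Final model:\n")
    print(x$final, digits = digits, row.names = FALSE)
  } else cat("Backward elimination removed no terms.\n")
  if (length(x$dropped))
    cat("Dropped (constant/aliased):", paste(x$dropped, collapse = ", "), "\n")
  invisible(x)
}

#' Three-tier risk stratification from CTTA and interim PET
#'
#' Combines dichotomized pre-treatment texture (low/high kurtosis at the
#' optimal cutpoint) with interim-PET status: iPET-negative patients are
#' split by texture into lower risk (low kurtosis) and intermediate risk
#' (high kurtosis), while iPET-positive patients form the higher-risk tier
#' regardless of texture. Patients with missing iPET get `NA` and should be
#' excluded (and logged) by the caller.
#'
#' @param ctta_high Logical (or 0/1): kurtosis above the optimal cutpoint.
#' @param ipet Character/factor with levels "negative"/"positive"; NA allowed.
#' @return Ordered factor with levels `lower < intermediate < higher`.
#' @export
stratify_three_groups <- function(ctta_high, ipet) {
  ctta_high <- as.logical(ctta_high)
  ipet <- as.character(ipet)
  bad <- !is.na(ipet) & !ipet %in% c("negative", "positive")
  if (any(bad))
    ctta_stop("ipet must be 'negative', 'positive' or NA", "bad_values")
  tier <- ifelse(is.na(ipet), NA_character_,
                 ifelse(ipet == "positive", "higher",
                        ifelse(ctta_high, "intermediate", "lower")))
  factor(tier, levels = c("lower", "intermediate", "higher"), ordered = TRUE)
}
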