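## io_cli (pipeline): chain texture -> aggregation -> marker selection ->
## optimized KM + BH -> Cox interaction -> three-tier stratification, with
## CSV outputs, a manifest and a run log.

MARKER_LABELS <- c(ipet = "iPET status", ctta = "CTTA kurtosis",
                   suv_max = "SUVmax", subtype = "Lymphoma type",
                   stage = "Stage", treatment = "Treatment",
                   bulk_px = "Bulk (pixels)")

## Numeric coding of the univariate marker family (Table-style conventions:
## binary markers are 0/1 and the split is "> 0"; stage is ordinal I-IV).
marker_values <- function(markers, best_col) {
  list(
    ipet = ifelse(is.na(markers$ipet), NA,
                  as.numeric(markers$ipet == "positive")),
    ctta = markers[[best_col]],
    suv_max = markers$suv_max,
    subtype = as.numeric(markers$subtype == "NHL"),
    stage = as.numeric(factor(markers$stage,
                              levels = c("I", "II", "III", "IV"))),
    treatment = as.numeric(markers$treatment == "standard"),
    bulk_px = markers$bulk_px)
}

#' Run the full prognostic analysis pipeline
#'
#' Executes, in order: per-lesion texture computation (when the lesion table
#' carries image paths instead of kurtosis columns), per-patient aggregation
#' of the up-to-five most avid lesions, best-scale selection by Mann-Whitney
#' relapse separation, optimized Kaplan-Meier dichotomization of the
#' seven-marker family with Benjamini-Hochberg FDR control, Cox modelling of
#' the significant markers with their pairwise interactions (backward
#' elimination), and three-tier risk stratification with per-tier KM curves.
#' All stage outputs are written to `out_dir` as CSV together with a
#' `MANIFEST.txt` (stage status) and `run_log.txt` (config echo); a stage
#' failure keeps earlier outputs and records the failed stage.
#'
#' @param cohort A `ctta_cohort` (from [generate_cohort()]), or NULL when
#'   `lesion_table`/`clinical_table` are given.
#' @param lesion_table,clinical_table Data frames (or CSV paths) in the
#'   schemas of [read_cohort_tables()].
#' @param out_dir Output directory (created if needed).
#' @param scales Candidate spatial scales.
#' @param hu_threshold Gas-exclusion threshold for texture computation.
#' @param min_group Minimum group size per side in the cutpoint search.
#' @param q FDR level for the Benjamini-Hochberg step.
#' @param ties Cox tie handling, `"efron"` or `"breslow"`.
#' @param max_lesions Lesion cap per patient (default 5).
#' @param verbose Print stage progress.
#' @return Object of class `ctta_run` with components `markers`,
#'   `scale_selection`, `marker_table` (Table-style survival summary),
#'   `bh`, `cox`, `tiers`, `km`, `manifest`, `out_dir`.
#' @export
run_pipeline <- function(cohort = NULL, lesion_table = NULL,
                         clinical_table = NULL, out_dir = tempfile("ctta_run_"),
                         scales = SSF_SCALES, hu_threshold = -50,
                         min_group = 3L, q = 0.05,
                         ties = c("efron", "breslow"), max_lesions = 5L,
                         verbose = FALSE) {
  ties <- match.arg(ties)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- character(0)
  logf <- file.path(out_dir, "run_log.txt")
  log_line <- function(...) {
    msg <- paste0(...)
    cat(msg, "\n", file = logf, append = TRUE, sep = "")
    if (verbose) message(msg)
  }
  note_stage <- function(stage, status) {
    manifest <<- c(manifest, sprintf("%-10s %s", stage, status))
    writeLines(manifest, file.path(out_dir, "MANIFEST.txt"))
  }
  log_line("cttasurv run: scales={", paste(scales, collapse = ","),
           "} hu_threshold=", hu_threshold, " min_group=", min_group,
           " q=", q, " ties=", ties, " max_lesions=", max_lesions)

  res <- list(out_dir = out_dir)
  run_stage <- function(stage, expr) {
    out <- tryCatch(expr, error = function(e) {
      note_stage(stage, paste("FAILED:", conditionMessage(e)))
      stop(e)
    })
    note_stage(stage, "ok")
    out
  }

  ## -- inputs ---------------------------------------------------------------
  if (!is.null(cohort)) {
    lesions <- cohort$lesions
    clinical <- cohort$clinical
  } else {
    if (is.character(lesion_table) || is.character(clinical_table)) {
      tb <- read_cohort_tables(lesion_table, clinical_table)
      lesions <- tb$lesions; clinical <- tb$clinical
    } else {
      lesions <- lesion_table; clinical <- clinical_table
    }
  }
  check_table(lesions, LESION_TABLE_COLS, "lesion")
  check_table(clinical, CLINICAL_TABLE_COLS, "clinical")

  ## -- texture --------------------------------------------------------------
  kcols <- scale_col(scales)
  if (!all(kcols %in% names(lesions))) {
    lesions <- run_stage("texture", {
      log_line("computing texture profiles for ", nrow(lesions), " lesions")
      lesion_texture_table(lesions, scales = scales,
                           hu_threshold = hu_threshold)
    })
    write.csv(lesions[, c(LESION_TABLE_COLS, kcols)],
              file.path(out_dir, "lesion_texture.csv"), row.names = FALSE)
  } else note_stage("texture", "skipped (kurtosis columns supplied)")

  ## -- aggregation + scale selection ---------------------------------------
  sel <- run_stage("cohort", {
    markers <- build_patient_markers(lesions, clinical, max_n = max_lesions)
    ss <- select_best_texture_scale(markers, scales)
    log_line("best texture scale: SSF=", ss$ssf, " mm (Mann-Whitney p=",
             signif(ss$p, 3), ")")
    list(markers = markers, scale = ss)
  })
  markers <- sel$markers
  res$markers <- markers
  res$scale_selection <- sel$scale
  write.csv(markers, file.path(out_dir, "patient_markers.csv"),
            row.names = FALSE)
  write.csv(sel$scale$table, file.path(out_dir, "scale_selection.csv"),
            row.names = FALSE)

  ## -- survival -------------------------------------------------------------
  surv <- run_stage("survival", {
    best_col <- scale_col(sel$scale$ssf)
    mv <- marker_values(markers, best_col)
    if (all(is.na(mv$ipet))) {
      log_line("iPET missing for every patient: iPET marker and Cox ",
               "interaction skipped")
      mv$ipet <- NULL
    }
    cps <- list()
    for (mk in names(mv)) {
      cp <- tryCatch(
        optimal_cutpoint(mv[[mk]], markers$pfs_months, markers$event,
                         min_group = min_group, marker_name = mk),
        cttasurv_error = function(e) {
          log_line("marker ", mk, " not testable: ", conditionMessage(e))
          NULL
        })
      if (!is.null(cp)) cps[[mk]] <- cp
    }
    if (length(cps) == 0L)
      ctta_stop("no marker admitted a survival split", "no_candidate")
    raw_p <- vapply(cps, function(x) x$p_logrank, numeric(1))
    bh <- bh_adjust(raw_p, q = q)
    tab <- data.frame(
      marker = names(cps),
      label = unname(MARKER_LABELS[names(cps)]),
      threshold = vapply(cps, function(x) x$threshold, numeric(1)),
      n_above = vapply(cps, function(x) x$n_above, numeric(1)),
      n_below = vapply(cps, function(x) x$n_below, numeric(1)),
      mean_surv_above = vapply(cps, function(x) x$mean_survival_above, numeric(1)),
      mean_surv_below = vapply(cps, function(x) x$mean_survival_below, numeric(1)),
      p_logrank = raw_p,
      bh_rank = bh$rank, bh_critical = bh$critical_value,
      significant = bh$significant,
      row.names = NULL, stringsAsFactors = FALSE)
    tab <- tab[order(tab$p_logrank), ]
    log_line(sum(tab$significant), " of ", nrow(tab),
             " markers significant after BH at q=", q)

    ## Cox on the BH-significant markers (dichotomized at their optimal
    ## cutpoints) + pairwise interactions; iPET-missing patients excluded.
    cox <- NULL; tiers <- NULL; km <- NULL
    sig <- tab$marker[tab$significant]
    have_ipet <- "ipet" %in% names(mv)
    if (length(sig) >= 1L && have_ipet) {
      use <- !is.na(mv$ipet)
      n_excl <- sum(!use)
      if (n_excl) log_line(n_excl, " patients without iPET excluded from Cox")
      X <- list()
      for (mk in sig)
        X[[paste0(mk, "_high")]] <- as.numeric(mv[[mk]][use] > cps[[mk]]$threshold)
      X <- as.data.frame(X)
      nm <- names(X)
      if (length(nm) >= 2L) {
        for (i in seq_len(length(nm) - 1L)) for (j in (i + 1L):length(nm))
          X[[paste(nm[i], nm[j], sep = "_x_")]] <- X[[nm[i]]] * X[[nm[j]]]
      }
      cox <- withCallingHandlers(
        cox_fit(markers$pfs_months[use], markers$event[use], X, ties = ties),
        cttasurv_warning = function(w) {
          log_line("cox warning: ", conditionMessage(w))
          invokeRestart("muffleWarning")
        })
    } else {
      log_line("Cox stage skipped (need >= 1 significant marker and iPET data)")
    }
    tier_contrast <- NULL
    if (have_ipet && "ctta" %in% names(cps)) {
      ctta_high <- markers[[best_col]] > cps[["ctta"]]$threshold
      ## The three-tier headline contrast: hazard of the (CTTA-high, iPET+)
      ## cell versus everyone else, i.e. the CTTA-by-iPET product term fitted
      ## alone (the reduced model in which the interaction is the sole
      ## surviving predictor).
      use_tc <- !is.na(mv$ipet)
      prod_term <- as.numeric(ctta_high[use_tc] & mv$ipet[use_tc] == 1)
      if (length(unique(prod_term)) == 2L && sum(markers$event[use_tc]) >= 1L)
        tier_contrast <- withCallingHandlers(
          cox_fit(markers$pfs_months[use_tc], markers$event[use_tc],
                  data.frame(ctta_high_x_ipet_pos = prod_term),
                  ties = ties, eliminate = FALSE),
          cttasurv_warning = function(w) {
            log_line("tier-contrast warning: ", conditionMessage(w))
            invokeRestart("muffleWarning")
          })
      tiers <- data.frame(
        patient_id = markers$patient_id,
        tier = as.character(stratify_three_groups(ctta_high, markers$ipet)),
        stringsAsFactors = FALSE)
      km <- list()
      for (tr in c("lower", "intermediate", "higher")) {
        sel_t <- !is.na(tiers$tier) & tiers$tier == tr
        if (sum(sel_t) >= 1L)
          km[[tr]] <- km_curve(markers$pfs_months[sel_t],
                               markers$event[sel_t])
      }
    }
    list(cutpoints = cps, table = tab, bh = bh, cox = cox,
         tier_contrast = tier_contrast, tiers = tiers, km = km)
  })

  res$marker_table <- surv$table
  res$cutpoints <- surv$cutpoints
  res$bh <- surv$bh
  res$cox <- surv$cox
  res$tier_contrast <- surv$tier_contrast
  res$tiers <- surv$tiers
  res$km <- surv$km
  write.csv(surv$table, file.path(out_dir, "markers_survival.csv"),
            row.names = FALSE)
  if (!is.null(surv$cox)) {
    write.csv(surv$cox$full, file.path(out_dir, "cox_full.csv"),
              row.names = FALSE)
    write.csv(surv$cox$final, file.path(out_dir, "cox_final.csv"),
              row.names = FALSE)
  }
  if (!is.null(surv$tier_contrast))
    write.csv(surv$tier_contrast$full, file.path(out_dir, "cox_tier_contrast.csv"),
              row.names = FALSE)
  if (!is.null(surv$tiers))
    write.csv(surv$tiers, file.path(out_dir, "tiers.csv"), row.names = FALSE)
  if (!is.null(surv$km)) {
    kmtab <- do.call(rbind, lapply(names(surv$km), function(tr) {
      st <- surv$km[[tr]]$steps
      data.frame(tier = tr, st)
    }))
    write.csv(kmtab, file.path(out_dir, "km_curves.csv"), row.names = FALSE)
  }
  note_stage("outputs", "ok")
  res$manifest <- manifest
  class(res) <- "ctta_run"
  res
}

#' @export
print.ctta_run <- function(x, ...) {
  cat("cttasurv pipeline run (", nrow(x$markers), " patients)\n", sep = "")
  cat(sprintf("best texture scale: SSF=%g mm (Mann-Whitney p=%.3g)\n",
              x$scale_selection$ssf, x$scale_selection$p))
  cat("\nUnivariate optimized KM + Benjamini-Hochberg:\n")
  print(x$marker_table[, c("label", "threshold", "n_above", "n_below",
                           "mean_surv_above", "mean_surv_below",
                           "p_logrank", "bh_critical", "significant")],
        digits = 3, row.names = FALSE)
  if (!is.null(x$cox)) {
    cat("\n"); print(x$cox)
  }
  if (!is.null(x$tier_contrast)) {
    tc <- x$tier_contrast$full
    cat(sprintf("\nCTTA x iPET tier contrast: HR = %.1f (95%% CI %.1f-%.1f, p = %.3g)\n",
                tc$hazard_ratio, tc$ci95_low, tc$ci95_high, tc$p_wald))
  }
  if (!is.null(x$km)) {
    cat("\nRisk tiers (restricted mean PFS):\n")
    for (tr in names(x$km))
      cat(sprintf("  %-12s n = %2d, mean PFS %.1f months\n", tr,
                  x$km[[tr]]$n, x$km[[tr]]$rmean))
  }
  cat("\noutputs:", x$out_dir, "\n")
  invisible(x)
}

#' @export
plot.ctta_run <- function(x, ...) {
  if (is.null(x$km) || length(x$km) == 0L)
    ctta_stop("run has no per-tier KM curves to plot", "bad_values")
  cols <- c(lower = "#1b7837", intermediate = "#e08214", higher = "#b2182b")
  tmax <- max(vapply(x$km, function(k) max(k$steps$time), numeric(1)))
  plot(NA, xlim = c(0, tmax), ylim = c(0, 1), xlab = "Months",
       ylab = "Progression-free survival", ...)
  for (tr in names(x$km)) {
    st <- x$km[[tr]]$steps
    lines(c(0, st$time), c(1, st$surv), type = "s", col = cols[[tr]], lwd = 2)
  }
  legend("bottomleft", legend = names(x$km), col = cols[names(x$km)],
         lwd = 2, bty = "n")
  invisible(x)
}
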