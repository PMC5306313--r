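test_that("Kaplan-Meier estimates match hand product-limit calculations", {
  km <- km_curve(c(2, 4, 6, 8), c(1, 1, 1, 1))
  expect_equal(km$steps$time, c(2, 4, 6, 8))
  expect_equal(km$steps$surv, c(0.75, 0.5, 0.25, 0))

  # all censored: flat survival over the whole follow-up
  km2 <- km_curve(c(5, 10, 15), c(0, 0, 0))
  expect_true(all(km2$steps$surv == 1))
  expect_equal(km2$rmean, 15)   # area of S = 1 up to the last observation

  # two uncensored times: area of the two-step curve
  expect_equal(km_curve(c(10, 20), c(1, 1))$rmean, 15)
})

test_that("KM without censoring equals the empirical survival function", {
  set.seed(13)
  t <- round(rexp(40, 0.05), 1)
  km <- km_curve(t, rep(1, 40))
  emp <- vapply(km$steps$time, function(u) mean(t > u), numeric(1))
  expect_equal(km$steps$surv, emp, tolerance = 1e-12)
  ora <- km_oracle(t, rep(1, 40))
  expect_equal(km$steps$surv[km$steps$n_event > 0], ora$surv,
               tolerance = 1e-12)
})

test_that("restricted mean survival never grows when an event is moved earlier", {
  set.seed(31)
  t <- c(34, 12, 50, 8, 27, 44, 19, 61)
  e <- c(1, 0, 1, 1, 0, 1, 1, 0)
  base <- km_curve(t, e)$rmean
  for (i in which(e == 1)) {
    t2 <- t; t2[i] <- t2[i] / 2
    expect_lte(km_curve(t2, e)$rmean, base + 1e-12)
  }
})

test_that("log-rank agrees with the direct O-E summation oracle", {
  # identical groups: no signal
  t <- c(3, 6, 9, 12); e <- c(1, 1, 0, 1)
  lr0 <- logrank_test(c(t, t), c(e, e), rep(c("a", "b"), each = 4))
  expect_lt(lr0$chi2, 1e-10)
  expect_gt(lr0$p, 0.999)

  set.seed(17)
  for (i in 1:20) {
    n <- sample(10:40, 1)
    time <- round(rexp(n, 0.04), 1)
    ev <- rbinom(n, 1, 0.8)
    g <- rbinom(n, 1, 0.5)
    if (length(unique(g)) < 2 || sum(ev) == 0) next
    lr <- logrank_test(time, ev, g)
    expect_equal(lr$chi2, logrank_oracle(time, ev, g), tolerance = 1e-10)
    # label swap leaves the statistic unchanged
    expect_equal(logrank_test(time, ev, 1 - g)$chi2, lr$chi2,
                 tolerance = 1e-12)
  }

  expect_error(logrank_test(c(1, 2, 3, 4), c(0, 0, 0, 0),
                            c(0, 0, 1, 1)),
               class = "cttasurv_untestable_contrast")
})

test_that("cutpoint search minimizes over admissible splits with stated ties", {
  set.seed(23)
  n <- 40L
  marker <- rnorm(n)
  time <- rexp(n, 0.03 * exp(0.8 * (marker > 0)))
  ev <- as.integer(time < 60); time <- pmin(time, 60)
  cp <- optimal_cutpoint(marker, time, ev)
  # the minimum over candidates cannot exceed the median-split p
  med_p <- logrank_test(time, ev, marker > median(marker))$p
  expect_lte(cp$p_logrank, med_p + 1e-12)
  expect_equal(cp$p_logrank, min(cp$candidates$p, na.rm = TRUE))
  expect_identical(cp$n_above + cp$n_below, n)

  # symmetric construction: two candidates with identical p -> smaller wins
  cp2 <- optimal_cutpoint(c(1, 2, 3, 4), c(10, 20, 20, 10), c(1, 1, 1, 1),
                          min_group = 1)
  cand <- cp2$candidates
  expect_equal(cand$p[cand$threshold == 1.5], cand$p[cand$threshold == 3.5],
               tolerance = 1e-12)
  expect_equal(cp2$threshold, 1.5)

  expect_error(optimal_cutpoint(rep(1, 10), 1:10, rep(1, 10)),
               class = "cttasurv_no_candidate")
  expect_error(optimal_cutpoint(1:6, 1:6, rep(1, 6), min_group = 5),
               class = "cttasurv_groups_too_small")
})

test_that("minimum-p searching is anti-conservative under the null", {
  # marker independent of survival: the optimized-KM p rejects far more than
  # its nominal 5%, which is why the downstream FDR correction is essential.
  set.seed(99)
  n_sim <- 1000
  rej <- logical(n_sim)
  for (i in seq_len(n_sim)) {
    n <- 30
    marker <- rnorm(n)
    t <- rexp(n, 0.03); cens <- runif(n, 0, 60)
    time <- pmin(t, cens); ev <- as.integer(t <= cens)
    p <- tryCatch(optimal_cutpoint(marker, time, ev)$p_logrank,
                  cttasurv_error = function(e) NA_real_)
    rej[i] <- isTRUE(p < 0.05)
  }
  rate <- mean(rej)
  expect_gt(rate, 0.05)
})

test_that("Benjamini-Hochberg step-up matches p.adjust and is monotone in q", {
  res <- bh_adjust(c(0.001, 0.02, 0.8, 0.04, 0.3), q = 0.05)
  expect_identical(res$significant, p.adjust(res$raw_p, "BH") <= 0.05)
  expect_true(all(diff(sort(res$critical_value)) > 0))

  set.seed(41)
  for (i in 1:20) {
    p <- runif(sample(3:12, 1))^2
    qs <- c(0.01, 0.05, 0.1, 0.2)
    sets <- lapply(qs, function(q) which(bh_adjust(p, q)$significant))
    for (j in seq_len(length(qs) - 1))
      expect_true(all(sets[[j]] %in% sets[[j + 1]]))  # rejections grow with q
    expect_identical(bh_adjust(p, 0.05)$significant,
                     p.adjust(p, "BH") <= 0.05)
  }

  expect_identical(sum(bh_adjust(rep(1, 6))$significant), 0L)
})

test_that("Cox fit recovers the two-group exponential rate ratio", {
  set.seed(55)
  lhr <- replicate(50, {
    g <- rbinom(200, 1, 0.5)
    t <- rexp(200, 0.02 * ifelse(g == 1, 2, 1))
    cox_fit(t, rep(1, 200), data.frame(g = g), eliminate = FALSE)$full$log_hr
  })
  expect_lt(abs(mean(lhr) - log(2)), 0.1)
  # Breslow ties option is exposed and consistent in direction
  g <- rbinom(150, 1, 0.5)
  t <- round(rexp(150, 0.02 * ifelse(g == 1, 2, 1)))
  fb <- cox_fit(t, rep(1, 150), data.frame(g = g), ties = "breslow",
                eliminate = FALSE)
  expect_gt(fb$full$hazard_ratio, 1)
})

test_that("degenerate and aliased covariates are dropped, not fatal", {
  set.seed(66)
  n <- 120
  x <- rbinom(n, 1, 0.4)
  t <- rexp(n, 0.02 * exp(x)); ev <- rep(1L, n)
  f1 <- suppressWarnings(
    cox_fit(t, ev, data.frame(x = x, z = rep(0, n)), eliminate = FALSE))
  expect_true("z" %in% f1$dropped)
  f0 <- cox_fit(t, ev, data.frame(x = x), eliminate = FALSE)
  expect_equal(f1$full$log_hr, f0$full$log_hr, tolerance = 1e-12)

  # interaction exactly duplicating a main effect: interaction is kept
  a <- rbinom(n, 1, 0.5); b <- a
  f2 <- suppressWarnings(cox_fit(t, ev,
    data.frame(a = a, b = b, a_x_b = a * b), eliminate = FALSE))
  expect_true("a_x_b" %in% f2$full$term)
  expect_identical(nrow(f2$full), 1L)
  expect_setequal(f2$dropped, c("a", "b"))
})

test_that("backward elimination removes null terms and keeps real ones", {
  set.seed(88)
  n <- 250
  x <- rbinom(n, 1, 0.5); z <- rbinom(n, 1, 0.5)   # z carries no effect
  t <- rexp(n, 0.02 * exp(1.2 * x))
  cens <- runif(n, 0, 80)
  time <- pmin(t, cens); ev <- as.integer(t <= cens)
  f <- cox_fit(time, ev, data.frame(x = x, z = z))
  expect_true("x" %in% f$final$term)
  expect_false("z" %in% f$final$term)
  expect_true("z" %in% f$eliminated)
  expect_identical(nrow(f$full), 2L)   # the full model is always reported
})

test_that("three-tier assignment follows the iPET/texture rule", {
  expect_identical(
    as.character(stratify_three_groups(
      c(FALSE, TRUE, FALSE, TRUE, NA),
      c("negative", "negative", "positive", "positive", NA))),
    c("lower", "intermediate", "higher", "higher", NA))
  tiers <- stratify_three_groups(c(TRUE, FALSE), c("negative", "negative"))
  expect_true(is.ordered(tiers))
  expect_identical(levels(tiers), c("lower", "intermediate", "higher"))
  expect_error(stratify_three_groups(TRUE, "equivocal"),
               class = "cttasurv_bad_values")
})
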