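test_that("the ROC-optimal cutoff matches a brute-force midpoint scan", {
  # perfectly separating marker: sens + spec = 2 at the separating midpoint
  expr <- c(1, 2, 3, 10, 11, 12)
  status <- c(0, 0, 0, 1, 1, 1)
  cut <- optimal_cutoff(expr, status)
  expect_equal(as.numeric(cut), 6.5)
  expect_equal(attr(cut, "sensitivity") + attr(cut, "specificity"), 2)

  set.seed(14)
  for (i in 1:20) {
    e <- round(stats::rnorm(12), 2)
    s <- sample(0:1, 12, replace = TRUE)
    if (all(s == 0) || all(s == 1)) next
    expect_equal(as.numeric(optimal_cutoff(e, s)), oracle_best_cutoff(e, s))
  }

  expect_error(optimal_cutoff(rep(3, 5), c(0, 1, 0, 1, 0)), "constant")
  expect_error(optimal_cutoff(1:5, rep(1, 5)), "non-empty")
})

test_that("an uninformative marker yields sens + spec near 1", {
  set.seed(71)
  e <- stats::rnorm(2000)
  s <- sample(0:1, 2000, replace = TRUE)
  cut <- optimal_cutoff(e, s)
  expect_lt(attr(cut, "youden"), 0.12)   # max(sens+spec) - 1 ~ KS noise
})

test_that("log-rank statistic matches a first-principles computation", {
  set.seed(31)
  for (i in 1:10) {
    n <- 24
    time <- round(stats::rexp(n, 0.1), 3)
    event <- sample(c(0L, 1L), n, replace = TRUE, prob = c(0.3, 0.7))
    g <- rep(c(TRUE, FALSE), each = n / 2)
    if (sum(event) == 0) next
    lr <- suppressWarnings(km_logrank(time, event, g))
    expect_equal(lr$chisq, oracle_logrank_chisq(time, event, g), tolerance = 1e-10)
  }
  # identical groups: statistic ~ 0, p ~ 1 (duplicate each subject across arms)
  time <- c(3, 5, 7, 9, 3, 5, 7, 9)
  event <- rep(1L, 8)
  lr0 <- km_logrank(time, event, rep(c("a", "b"), each = 4))
  expect_lt(lr0$chisq, 1e-10)
  expect_gt(lr0$p, 0.999)
})

test_that("KM estimate without censoring equals the empirical survival function", {
  time <- c(2, 4, 4, 7, 9, 12)
  event <- rep(1L, 6)
  g <- rep(c("x", "y"), 3)
  fit <- km_logrank(time, event, g)$fit
  sf <- summary(fit)
  # for each group, S(t_i) = fraction of that group's subjects with T > t_i
  groups <- rep(levels(factor(g)), fit$strata)
  for (i in seq_along(sf$time)) {
    grp <- sub("group=", "", as.character(sf$strata[i]))
    in_grp <- g == grp
    expect_equal(sf$surv[i], mean(time[in_grp] > sf$time[i]))
  }
})

test_that("log-rank p agrees with a permutation reference on a small instance", {
  set.seed(8)
  time <- c(1.1, 2.3, 3.2, 4.5, 5.1, 6.7, 7.2, 8.9, 9.4, 10.2, 11.8, 12.3)
  event <- rep(1L, 12)
  g <- rep(c(TRUE, FALSE), each = 6)
  obs <- km_logrank(time, event, g)$chisq
  perm <- replicate(2000, {
    gp <- sample(g)
    oracle_logrank_chisq(time, event, gp)
  })
  p_perm <- mean(perm >= obs - 1e-12)
  p_chisq <- stats::pchisq(obs, 1, lower.tail = FALSE)
  expect_lt(abs(p_perm - p_chisq), 3 * sqrt(p_perm * (1 - p_perm) / 2000) + 0.02)
})

test_that("Cox fit recovers the closed-form MLE on a no-tie toy instance", {
  # subjects (time, event, z): (1,1,1) (2,1,0) (3,1,1) (4,0,0)
  # partial-likelihood score root: u = exp(beta) solves -u^2 + u + 4 = 0
  fit <- cox_univariate(c(1, 2, 3, 4), c(1, 1, 1, 0), c(1, 0, 1, 0))
  beta_closed <- log((1 + sqrt(17)) / 2)
  expect_equal(fit$beta, beta_closed, tolerance = 1e-6)
  expect_equal(fit$hr, exp(beta_closed), tolerance = 1e-6)
  expect_true(fit$ci_low <= fit$hr && fit$hr <= fit$ci_high)

  # identical groups: HR = 1
  time <- rep(c(3, 5, 8, 13), 2)
  fit0 <- cox_univariate(time, rep(1, 8), rep(c(0, 1), each = 4))
  expect_equal(fit0$hr, 1, tolerance = 1e-6)

  # no events in one group: monotone likelihood is flagged, CI unbounded
  fitm <- cox_univariate(c(1, 2, 3, 4, 5, 6), c(1, 1, 1, 0, 0, 0),
                         c(0, 0, 0, 1, 1, 1))
  expect_true(fitm$monotone)
  expect_equal(fitm$ci_high, Inf)
})

test_that("panel screening flags true drivers and respects its precondition", {
  # class_separation 0 keeps the non-driver miRNAs independent of survival
  cfg <- sim_config(seed = 61, n_per_class = 100, censoring_rate = 0.2,
                    class_separation = 0,
                    survival_hr_map = c("miR-124-3p" = 4, "miR-375" = 4,
                                        "miR-96-5p" = 4))
  prof <- make_class_profiles(2, panel = too_panel()[1:20], config = cfg)
  ref <- simulate_reference_cohort(prof, cfg)
  meta <- simulate_survival(ref$meta, ref$matrix, cfg)
  scr <- screen_panel(ref$matrix, meta)
  expect_s3_class(scr, "survival_screen")
  expect_equal(nrow(scr), 20)
  drivers <- c("miR-124-3p", "miR-375", "miR-96-5p")
  expect_true(all(scr$significant[scr$mirna_id %in% drivers]))
  # false flags among the 17 nulls stay near the alpha = 0.05 expectation
  expect_lte(sum(scr$significant[!scr$mirna_id %in% drivers]), 5)
  # SurvivalFit invariants
  ok <- !is.na(scr$hr)
  expect_true(all(scr$ci_low[ok] <= scr$hr[ok] & scr$hr[ok] <= scr$ci_high[ok]))
  expect_true(all(scr$hr[ok] > 0))
  expect_true(all(scr$logrank_p[ok] >= 0 & scr$logrank_p[ok] <= 1))
  expect_true(all(scr$n_high[ok] + scr$n_low[ok] == sum(!is.na(meta$time_months))))

  # refuses fewer than 10 followed-up samples
  small <- meta
  small$time_months[-(1:9)] <- NA
  expect_error(screen_panel(normalize_median(ref$matrix), small), "at least 10")
})
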