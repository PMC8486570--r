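test_that("class profiles give disjoint discriminant sets with the stated counts", {
  cfg <- sim_config(seed = 3, class_separation = 2)
  panel87 <- setdiff(too_panel(), default_exclusions())
  prof <- make_class_profiles(17, panel = panel87, config = cfg)
  disc <- lapply(prof, `[[`, "discriminant")
  expect_equal(length(unique(unlist(disc))), 17 * 5) # disjoint by construction
  shifted <- unique(unlist(lapply(prof, function(p) {
    names(p$mu)[p$mu > cfg$baseline_log2]
  })))
  expect_equal(length(shifted), 85)          # 85 carry a class shift ...
  expect_equal(length(setdiff(panel87, shifted)), 2)  # ... 2 purely baseline
  # zero effect size: identical means
  prof0 <- make_class_profiles(2, config = sim_config(seed = 3, class_separation = 0))
  expect_equal(prof0[[1]]$mu, prof0[[2]]$mu)
})

test_that("profile construction is deterministic and errors on small panels", {
  a <- make_class_profiles(5, config = sim_config(seed = 11))
  b <- make_class_profiles(5, config = sim_config(seed = 11))
  expect_identical(a, b)
  expect_error(
    make_class_profiles(17, panel = too_panel()[1:30], config = sim_config()),
    "panel too small"
  )
})

test_that("reference cohort has the right shape, positivity, and sex consistency", {
  cfg <- sim_config(seed = 5, n_per_class = 5)
  prof <- make_class_profiles(17, config = cfg)
  ref <- simulate_reference_cohort(prof, cfg)
  expect_equal(dim(ref$matrix), c(85, 89))
  expect_true(all(ref$matrix$values > 0))
  expect_equal(nrow(ref$meta), 85)
  # sex never contradicts the class label
  expect_false(any(ref$meta$sex == "female" & ref$meta$class_label %in% c("TGSC", "PRAD")))
  expect_false(any(ref$meta$sex == "male" & ref$meta$class_label %in% c("OV", "UCEC")))
  # bit-reproducible
  ref2 <- simulate_reference_cohort(prof, cfg)
  expect_identical(ref$matrix$values, ref2$matrix$values)
  expect_identical(ref$meta, ref2$meta)
})

test_that("noise-free cohorts reproduce 2^mu exactly", {
  cfg <- sim_config(seed = 2, sigma_within = 0, n_per_class = 3)
  prof <- make_class_profiles(3, config = cfg)
  ref <- simulate_reference_cohort(prof, cfg)
  for (k in 1:3) {
    rows <- ref$matrix$values[ref$meta$class_label == prof[[k]]$class_label, ]
    expect_equal(rows[1, ], 2^prof[[k]]$mu)
    expect_equal(rows[2, ], 2^prof[[k]]$mu)
  }
})

test_that("empirical class means recover the generative separation (Monte Carlo)", {
  cfg <- sim_config(seed = 9, n_per_class = 200, class_separation = 2,
                    n_discriminant = 3, sigma_within = 0.8)
  prof <- make_class_profiles(2, panel = too_panel()[1:20], config = cfg)
  ref <- simulate_reference_cohort(prof, cfg)
  lab <- ref$meta$class_label
  lg <- log2(ref$matrix$values)
  disc1 <- prof[[1]]$discriminant[1]
  diff_hat <- mean(lg[lab == prof[[1]]$class_label, disc1]) -
    mean(lg[lab == prof[[2]]$class_label, disc1])
  se <- cfg$sigma_within * sqrt(2 / cfg$n_per_class)
  expect_lt(abs(diff_hat - cfg$class_separation), 3 * se)
})

test_that("liver metastases carry the miR-122-5p spike at the configured factor", {
  sites <- data.frame(
    patient_id = sprintf("PT%03d", 1:400),
    origin = "LUAD",
    site = rep(c("liver", "lymph node"), each = 200)
  )
  cfg <- sim_config(seed = 13, liver_spike_factor = 50)
  prof <- make_class_profiles(3, config = cfg,
                              class_labels = c("LUAD", "LBC", "CHOL"))
  met <- simulate_metastases(prof, cfg, sites)
  lg <- log2(met$matrix$values[, "miR-122-5p"])
  is_liver <- met$meta$biopsy_site == "liver"
  d <- mean(lg[is_liver]) - mean(lg[!is_liver])
  se <- cfg$sigma_within * sqrt(2 / 200)
  expect_lt(abs(d - log2(50)), 3 * se)

  # neutral factor: identical distribution generator-wise (same draw law)
  cfg1 <- sim_config(seed = 13, liver_spike_factor = 1)
  met1 <- simulate_metastases(prof, cfg1, sites)
  lg1 <- log2(met1$matrix$values[, "miR-122-5p"])
  expect_lt(abs(mean(lg1[is_liver]) - mean(lg1[!is_liver])), 3 * se)
})

test_that("metastasis bookkeeping: shared patients share truth, sites validated", {
  cfg <- sim_config(seed = 4)
  prof <- make_class_profiles(4, config = cfg,
                              class_labels = c("CHOL", "KICA", "LUAD", "OV"))
  sites <- data.frame(
    patient_id = c("P1", "P1", "P2"),
    origin = c("CHOL", "CHOL", "KICA"),
    site = c("liver", "bone", "lung")
  )
  met <- simulate_metastases(prof, cfg, sites)
  p1 <- met$meta[met$meta$patient_id == "P1", ]
  expect_equal(unique(p1$true_class), "CHOL")
  expect_equal(length(unique(p1$sex)), 1)           # one sex per patient
  expect_true(all(is.na(met$meta$class_label)))     # CUP role hides the label
  expect_error(
    simulate_metastases(prof, cfg, data.frame(
      patient_id = "P9", origin = "CHOL", site = "spleenoid"
    )),
    "unknown biopsy site"
  )
  expect_error(
    simulate_metastases(prof, cfg, data.frame(
      patient_id = c("P1", "P1"), origin = c("CHOL", "KICA"),
      site = c("liver", "bone")
    )),
    "different origins"
  )
})

test_that("survival generator honors censoring and is calibrated under the null", {
  cfg <- sim_config(seed = 21, n_per_class = 30, censoring_rate = 0)
  prof <- make_class_profiles(2, config = cfg)
  ref <- simulate_reference_cohort(prof, cfg)
  meta <- simulate_survival(ref$meta, ref$matrix, cfg)
  expect_true(all(meta$event == 1))                 # no censoring
  expect_true(all(meta$time_months > 0))

  # HR = 1 for every miRNA: log-rank p uniform over repeated simulation
  pvals <- vapply(1:200, function(r) {
    cfgr <- sim_config(seed = 1000 + r, n_per_class = 30, censoring_rate = 0.2)
    profr <- make_class_profiles(2, panel = too_panel()[1:20], config = cfgr)
    refr <- simulate_reference_cohort(profr, cfgr)
    mr <- simulate_survival(refr$meta, refr$matrix, cfgr)
    expr <- refr$matrix$values[, 1]
    g <- expr > stats::median(expr)
    suppressWarnings(km_logrank(mr$time_months, mr$event, g)$p)
  }, numeric(1))
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("survival generator rejects drivers outside the matrix", {
  cfg <- sim_config(seed = 2, survival_hr_map = c("miR-404-nope" = 3))
  prof <- make_class_profiles(2, config = cfg)
  ref <- simulate_reference_cohort(prof, cfg)
  expect_error(simulate_survival(ref$meta, ref$matrix, cfg), "absent from the matrix")
})
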