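test_that("probe sets have unique ids and the configured planted pattern", {
  ps <- make_probe_set(904, n_up = 2, n_down = 2, effect_size = 1, seed = 7)
  expect_equal(nrow(ps), 904)
  expect_equal(anyDuplicated(ps$probe_id), 0L)
  expect_equal(sum(ps$planted_effect > 0), 2)
  expect_equal(sum(ps$planted_effect < 0), 2)
  expect_setequal(unique(abs(ps$planted_effect)), c(0, 1))
  expect_true(any(ps$is_star))

  null_ps <- make_probe_set(10, 0, 0, 0, seed = 1)
  expect_true(all(null_ps$planted_effect == 0))

  expect_error(make_probe_set(5, 3, 3, 1, seed = 1),
               class = "mirscreen_config_error")
})

test_that("cohort simulation matches the array layout and is reproducible", {
  ps <- make_probe_set(904, seed = 2)
  cfg <- generator_config(seed = 2)
  raw <- simulate_cohort(ps, 24, 15, cfg)
  expect_equal(dim(raw$intensities), c(904, 7, 39))
  expect_equal(length(unique(dimnames(raw$intensities)[[1]])), 904)
  expect_false(anyNA(raw$intensities))
  expect_true(all(raw$intensities >= 0))
  expect_equal(table(raw$samples$class_label)[["case"]], 24)
  expect_equal(raw$samples$subtype[raw$samples$class_label == "control"],
               rep("none", 15))

  raw2 <- simulate_cohort(ps, 24, 15, cfg)
  expect_identical(raw$intensities, raw2$intensities)

  # extended serous-style design
  small_ps <- make_probe_set(40, seed = 3)
  small_cfg <- generator_config(n_probes = 40, seed = 3)
  ext <- simulate_cohort(small_ps, 20, 39, small_cfg)
  expect_equal(table(ext$samples$class_label)[["control"]], 39)

  expect_error(simulate_cohort(ps, 0, 15, cfg),
               class = "mirscreen_config_error")
})

test_that("zero-noise configuration collapses to the deterministic signal", {
  ps <- make_probe_set(20, seed = 4, baseline_log_sd = 0.3)
  cfg <- generator_config(n_probes = 20, spot_noise_sd = 0, bio_noise_sd = 0,
                          array_scale_sd = 0, background_sd = 0,
                          background_mean = 10, seed = 4)
  raw <- simulate_cohort(ps, 2, 2, cfg)
  signal <- raw$intensities - raw$backgrounds
  for (s in 2:4) {
    expect_equal(signal[, , s], signal[, , 1])
  }
  expect_equal(unname(signal[, 1, 1]), sinh(ps$baseline_log_mean))
})

test_that("effect-free cohorts give symmetric group differences and nominal type-I error", {
  n_sig <- 0L
  n_tests <- 0L
  diffs <- c()
  for (s in 1:10) {
    cohort <- small_cohort(n_probes = 200, n_case = 6, n_control = 6, seed = s)
    tab <- ttest_per_feature(cohort$em)
    n_sig <- n_sig + sum(tab$p_value < 0.05)
    n_tests <- n_tests + nrow(tab)
    diffs <- c(diffs, tab$mean_case - tab$mean_control)
  }
  band <- qnorm(c(0.005, 0.995), n_tests * 0.05,
                sqrt(n_tests * 0.05 * 0.95))
  expect_gt(n_sig, band[1])
  expect_lt(n_sig, band[2])
  # symmetry of group-mean differences about zero
  expect_lt(abs(mean(diffs)) / sd(diffs), 0.05)
  expect_gt(mean(diffs > 0), 0.45)
  expect_lt(mean(diffs > 0), 0.55)
})

test_that("doubling the planted effect never decreases detection power", {
  power_at <- function(effect) {
    hits <- 0L
    for (s in 1:5) {
      cohort <- small_cohort(n_probes = 100, n_case = 8, n_control = 8,
                             n_up = 5, n_down = 5, effect_size = effect,
                             seed = s)
      tab <- ttest_per_feature(cohort$em)
      planted <- cohort$probes$probe_id[cohort$probes$planted_effect != 0]
      hits <- hits + sum(tab$p_value[match(planted, tab$probe_id)] < 0.05)
    }
    hits / (5 * 10)
  }
  p1 <- power_at(0.05)
  p2 <- power_at(0.10)
  p3 <- power_at(0.20)
  expect_gte(p2, p1)
  expect_gte(p3, p2)
})

test_that("noise calibration is deterministic and hits its targets", {
  cfg <- generator_config(n_probes = 150)
  cal <- calibrate_noise(0.85, 0.005, config = cfg, n_pairs = 10, seed = 5)
  expect_s3_class(cal, "noise_calibration")
  expect_true(cal$spot_noise_sd > 0 && cal$bio_noise_sd > 0)
  expect_lt(abs(cal$corr - 0.85), 0.02)
  expect_lt(abs(cal$diff_var - 0.005) / 0.005, 0.2)

  cal2 <- calibrate_noise(0.85, 0.005, config = cfg, n_pairs = 10, seed = 5)
  expect_identical(cal[c("spot_noise_sd", "bio_noise_sd", "baseline_log_sd")],
                   cal2[c("spot_noise_sd", "bio_noise_sd", "baseline_log_sd")])

  # tighter replicate agreement demands smaller noise
  cal_tight <- calibrate_noise(0.85, 0.001, config = cfg, n_pairs = 10,
                               seed = 5)
  expect_lt(cal_tight$spot_noise_sd, cal$spot_noise_sd)
  expect_lt(cal_tight$bio_noise_sd, cal$bio_noise_sd)

  expect_error(calibrate_noise(1.2, 0.005), class = "mirscreen_config_error")
})
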