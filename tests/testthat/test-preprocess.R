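test_that("background correction subtracts, floors and refuses to run twice", {
  raw <- toy_raw(array(c(100, 10, 50), dim = c(3, 1, 1)),
                 array(c(30, 30, 0), dim = c(3, 1, 1)))
  corrected <- background_correct(raw, floor = 0.5)
  expect_equal(unname(corrected$intensities[, 1, 1]), c(70, 0.5, 50))
  expect_error(background_correct(corrected),
               class = "mirscreen_idempotency_error")

  # zero background: values unchanged (floor below the data)
  raw0 <- toy_raw(array(5:8, dim = c(4, 1, 1)))
  expect_equal(unname(background_correct(raw0, floor = 0.1)$intensities[, 1, 1]),
               5:8)
})

test_that("replicate summarization takes per-probe spot medians", {
  spots <- rbind(1:7, rep(3, 7), c(1, 1, 1, 1, 1, 1, 100))
  raw <- toy_raw(array(rep(spots, 2), dim = c(3, 7, 2)))
  em <- summarize_replicates(background_correct(raw, floor = 0.1))
  expect_equal(unname(em$values[, 1]), c(4, 3, 1))
  expect_equal(em$stage, "raw-summarized")
  expect_error(summarize_replicates(raw), class = "mirscreen_stage_error")

  # summarization commutes with probe reordering
  perm <- c(3, 1, 2)
  raw_perm <- toy_raw(array(rep(spots[perm, ], 2), dim = c(3, 7, 2)))
  em_perm <- summarize_replicates(background_correct(raw_perm, floor = 0.1))
  expect_equal(unname(em_perm$values), unname(em$values)[perm, , drop = FALSE])
})

test_that("normalization undoes exact affine differences between arrays", {
  set.seed(42)
  base <- exp(rnorm(200, 5, 0.6))
  scales <- c(0.7, 1, 1.3, 1.6, 2.4)
  values <- sapply(scales, function(b) b * base)
  em <- expression_matrix(values,
                          probe_ids = sprintf("p%03d", 1:200),
                          sample_ids = sprintf("s%d", 1:5))
  model <- fit_normalization(em)
  norm <- model$trained
  for (j in 2:5) {
    expect_equal(norm$values[, j], norm$values[, 1], tolerance = 1e-6,
                 ignore_attr = TRUE)
  }
  # equivariance: rescaling one raw array (not the median one, so the
  # reference profile is untouched) changes its fitted scale, not its
  # normalized values
  values2 <- values
  values2[, 5] <- values2[, 5] * 10
  em2 <- expression_matrix(values2, probe_ids = em$probe_ids,
                           sample_ids = em$sample_ids)
  model2 <- fit_normalization(em2)
  expect_equal(model2$scales[5], model$scales[5] / 10, tolerance = 1e-6)
  expect_equal(model2$trained$values[, 5], norm$values[, 5],
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("the identity model reduces to a plain glog and preserves order", {
  x <- matrix(exp(seq(0, 6, length.out = 40)), ncol = 2)
  em <- expression_matrix(x, probe_ids = sprintf("p%02d", 1:20),
                          sample_ids = c("a", "b"))
  identity_model <- structure(
    list(offsets = c(0, 0), scales = c(1, 1), cofactor = 1,
         reference = rowMeans(x), probe_ids = em$probe_ids,
         sample_ids = em$sample_ids),
    class = "glog_norm")
  norm <- apply_normalization(identity_model, em)
  expect_equal(unname(norm$values), asinh(unname(x)))
  expect_equal(asinh(0), 0)
  # arsinh is monotone: monotone inputs stay monotone per array
  expect_true(all(diff(norm$values[, 1]) > 0))
})

test_that("fitting is self-consistent and validates its inputs", {
  cohort <- small_cohort(n_probes = 50, n_case = 3, n_control = 3, seed = 9)
  summarized <- summarize_replicates(background_correct(cohort$raw))
  model <- fit_normalization(summarized)
  expect_identical(apply_normalization(model, summarized)$values,
                   model$trained$values)
  expect_identical(predict(model, summarized)$values, model$trained$values)

  single <- expression_matrix(matrix(1:5, ncol = 1),
                              probe_ids = sprintf("p%d", 1:5),
                              sample_ids = "only")
  expect_error(fit_normalization(single),
               class = "mirscreen_insufficient_data")
  expect_error(fit_normalization(model$trained),
               class = "mirscreen_stage_error")
  other <- expression_matrix(matrix(1:10, ncol = 2),
                             probe_ids = sprintf("q%d", 1:5),
                             sample_ids = c("a", "b"))
  expect_error(apply_normalization(model, other),
               class = "mirscreen_schema_error")
})

test_that("normalized variance is flat across the intensity range", {
  # arrays with intensity-dependent raw-scale noise; after glog
  # normalization the per-probe variance must not trend with intensity
  ps <- make_probe_set(600, seed = 11, baseline_log_mean = 6,
                       baseline_log_sd = 1.2)
  cfg <- generator_config(n_probes = 600, seed = 11)
  raw <- simulate_cohort(ps, 6, 6, cfg)
  em <- preprocess_cohort(raw)
  v <- apply(em$values, 1, var)
  m <- rowMeans(em$values)
  decile <- cut(m, quantile(m, seq(0, 1, 0.1)), include.lowest = TRUE)
  decile_var <- tapply(v, decile, mean)
  expect_lt(max(decile_var) / min(decile_var), 3)
})
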