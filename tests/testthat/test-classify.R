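test_that("stratified folds are balanced and contain both classes", {
  labels <- rep(c("case", "control"), c(24, 15))
  folds <- assign_folds(labels, 10, stratified = TRUE, seed = 1)
  sizes <- table(folds)
  expect_equal(length(sizes), 10L)
  expect_true(all(sizes %in% 3:4))
  for (f in 1:10) {
    expect_setequal(unique(labels[folds == f]), c("case", "control"))
  }
  # class ratio per fold within one sample of proportionality
  case_per_fold <- table(folds[labels == "case"])
  expect_true(all(case_per_fold %in% 2:3))

  expect_identical(assign_folds(labels, 10, seed = 3),
                   assign_folds(labels, 10, seed = 3))
  expect_false(identical(assign_folds(labels, 10, seed = 3),
                         assign_folds(labels, 10, seed = 4)))

  # leave-one-out degeneracy
  loo <- assign_folds(labels, 39, stratified = TRUE, seed = 1)
  expect_equal(sort(unique(loo)), 1:39)

  expect_error(assign_folds(rep(c("case", "control"), c(30, 5)), 10,
                            stratified = TRUE, seed = 1),
               class = "mirscreen_config_error")
})

test_that("training-fold feature ranking matches the global DE ordering", {
  cohort <- small_cohort(n_probes = 80, n_case = 8, n_control = 6,
                         n_up = 3, n_down = 3, effect_size = 2, seed = 10)
  ranking <- rank_features(cohort$em$values, cohort$em$labels)
  de <- build_de_table(cohort$em, top_k = 80)
  expect_equal(ranking, de$probe_id)
  planted <- cohort$probes$probe_id[cohort$probes$planted_effect != 0]
  expect_true(all(planted %in% ranking[1:6]))

  expect_error(rank_features(cohort$em$values, rep("case", 14)),
               class = "mirscreen_fold_degeneracy")
})

test_that("pooled metrics satisfy the confusion-matrix identity", {
  cohort <- small_cohort(n_probes = 60, n_case = 9, n_control = 7,
                         n_up = 2, n_down = 2, effect_size = 1, seed = 11)
  folds <- assign_folds(cohort$em$labels, 4, seed = 2)
  m <- evaluate_subset(cohort$em, folds = folds, subset_size = 10,
                       kernel = "radial", cost = 1)
  expect_equal(m[["accuracy"]],
               (m[["sensitivity"]] * 9 + m[["specificity"]] * 7) / 16)

  # invariance under a consistent sample permutation
  set.seed(99)
  perm <- sample(16)
  m2 <- evaluate_subset(cohort$em$values[, perm],
                        as.character(cohort$em$labels)[perm],
                        folds = folds[perm], subset_size = 10,
                        kernel = "radial", cost = 1)
  expect_equal(m2, m, tolerance = 1e-8)

  expect_error(evaluate_subset(cohort$em, folds = folds, subset_size = 0),
               class = "mirscreen_config_error")
})

test_that("repeated CV is reproducible and selects the best grid cell", {
  cohort <- small_cohort(n_probes = 80, n_case = 10, n_control = 8,
                         n_up = 4, n_down = 4, effect_size = 2, seed = 12)
  cfg <- cv_config(n_folds = 5, n_repeats = 3, subset_sizes = c(5, 20),
                   kernels = c("linear", "radial"), cost_grid = c(0.1, 1),
                   seed = 21)
  a <- run_repeated_cv(cohort$em, config = cfg)
  b <- run_repeated_cv(cohort$em, config = cfg)
  expect_identical(a$grid, b$grid)
  expect_identical(a$best, b$best)

  expect_equal(a$best$mean_accuracy, max(a$grid$mean_accuracy))
  expect_equal(a$grid$mean_accuracy,
               unname(colMeans(a$per_repeat$accuracy)))
  expect_equal(nrow(a$grid), 2 * 2 * 2)
})

test_that("permutation nulls sit at chance and flag real signal", {
  cohort <- small_cohort(n_probes = 80, n_case = 8, n_control = 8,
                         n_up = 6, n_down = 6, effect_size = 3, seed = 13)
  cfg <- cv_config(n_folds = 4, n_repeats = 2, subset_sizes = 12,
                   kernels = "radial", cost_grid = 1, seed = 31)
  obs <- run_repeated_cv(cohort$em, config = cfg)
  expect_gt(obs$best$mean_accuracy, 0.9)
  pm <- run_permutation(cohort$em, config = cfg, n_runs = 20, observed = obs)
  expect_equal(dim(pm$permuted), c(20L, 3L))
  expect_true(all(pm$exceedance > 0 & pm$exceedance <= 1))
  expect_lte(pm$exceedance[["accuracy"]], 2 / 21)
  expect_lt(mean(pm$permuted[, "accuracy"]), obs$best$mean_accuracy)
})

test_that("with no filtering the leaky and correct variants coincide", {
  cohort <- small_cohort(n_probes = 30, n_case = 6, n_control = 6, seed = 14)
  cfg <- cv_config(n_folds = 3, n_repeats = 2, subset_sizes = 30,
                   kernels = "radial", cost_grid = 1, seed = 41)
  lp <- leakage_probe(cohort$em, config = cfg)
  expect_equal(lp$difference, 0, tolerance = 1e-10)
})
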