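test_that("pooled and Welch row t-tests agree with stats::t.test", {
  # closed-form pooled example
  x <- rbind(c(1, 2, 3, 4, 5, 6))
  rownames(x) <- "p1"
  labels <- c(rep("case", 3), rep("control", 3))
  tab <- ttest_per_feature(x, labels, var_equal = TRUE)
  expect_equal(tab$t_stat, -3.674, tolerance = 1e-3)
  expect_equal(tab$p_value, 0.0214, tolerance = 1e-2)
  expect_equal(tab$direction, "down")

  # random matrices, both forms, against the reference implementation
  set.seed(1)
  for (var_equal in c(TRUE, FALSE)) {
    m <- matrix(rnorm(30 * 11), 30, 11,
                dimnames = list(sprintf("p%02d", 1:30), NULL))
    labels <- rep(c("case", "control"), c(6, 5))
    tab <- ttest_per_feature(m, labels, var_equal = var_equal)
    for (i in seq_len(nrow(m))) {
      ref <- t.test(m[i, labels == "case"], m[i, labels == "control"],
                    var.equal = var_equal)
      expect_equal(tab$t_stat[i], unname(ref$statistic), tolerance = 1e-10)
      expect_equal(tab$p_value[i], ref$p.value, tolerance = 1e-10)
    }
  }
})

test_that("t-tests are antisymmetric in the group labels and handle degeneracy", {
  set.seed(2)
  m <- matrix(rnorm(20 * 10), 20, 10,
              dimnames = list(sprintf("p%02d", 1:20), NULL))
  labels <- rep(c("case", "control"), each = 5)
  flipped <- rep(c("control", "case"), each = 5)
  a <- ttest_per_feature(m, labels)
  b <- ttest_per_feature(m, flipped)
  expect_equal(a$t_stat, -b$t_stat)
  expect_equal(a$p_value, b$p_value)
  expect_true(all(a$direction != b$direction))

  const <- matrix(5, 2, 8, dimnames = list(c("c1", "c2"), NULL))
  tab <- ttest_per_feature(const, rep(c("case", "control"), each = 4))
  expect_equal(tab$t_stat, c(0, 0))
  expect_equal(tab$p_value, c(1, 1))
  expect_true(all(tab$degenerate))

  expect_error(ttest_per_feature(m, rep(c("case", "control"), c(1, 9))),
               class = "mirscreen_insufficient_data")
})

test_that("BH adjustment matches the brute-force step-up oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(1), 1)
  set.seed(3)
  for (i in 1:200) {
    p <- runif(sample(1:40, 1))^sample(1:3, 1)
    adj <- bh_adjust(p)
    expect_equal(adj, bh_oracle(p))
    expect_true(all(adj >= p) && all(adj <= 1))
  }
  expect_error(bh_adjust(c(0.5, 1.2)), class = "mirscreen_domain_error")
  expect_error(bh_adjust(c(-0.1)), class = "mirscreen_domain_error")
})

test_that("normality screening flags degenerate and heavy-tailed probes", {
  set.seed(4)
  x <- matrix(rnorm(300 * 14), 300, 14,
              dimnames = list(sprintf("p%03d", 1:300), NULL))
  x[1, ] <- 7                      # constant
  labels <- rep(c("case", "control"), each = 7)
  screen <- normality_screen(x, labels, alpha = 0.05)
  expect_false(screen$pass[1])
  # under Gaussian data both groups pass with probability ~0.95^2
  expect_gt(attr(screen, "pass_fraction"), 0.85)
  expect_lt(attr(screen, "pass_fraction"), 0.96)

  # heavy-tailed data fails with high probability
  fails <- 0L
  for (s in 1:200) {
    set.seed(s + 1000)
    y <- rbind(rcauchy(14))
    rownames(y) <- "p1"
    fails <- fails + !normality_screen(y, labels)$pass[1]
  }
  expect_gt(fails / 200, 0.5)

  expect_error(normality_screen(x[, 1:4], rep(c("case", "control"), 2)),
               class = "mirscreen_insufficient_data")
})

test_that("the DE table ranks planted probes first with correct directions", {
  cohort <- small_cohort(n_probes = 120, n_case = 10, n_control = 8,
                         n_up = 2, n_down = 2, effect_size = 2, seed = 6)
  de <- build_de_table(cohort$em, top_k = 10)
  planted <- cohort$probes[cohort$probes$planted_effect != 0, ]
  idx <- match(planted$probe_id, de$probe_id)
  expect_true(all(!is.na(idx) & idx <= 4))
  expect_equal(de$direction[idx],
               ifelse(planted$planted_effect > 0, "up", "down"))
  expect_true(all(de$p_adjusted[idx] < 0.05))
  expect_gte(attr(de, "n_sig_adjusted"), 4)

  full <- build_de_table(cohort$em, top_k = 120)
  expect_equal(full$rank, 1:120)
  expect_true(all(diff(full$p_value) >= 0))
  expect_true(all(full$p_adjusted >= full$p_value))
  expect_warning(build_de_table(cohort$em, top_k = 500), "exceeds")
})

test_that("null cohorts rarely yield BH-significant probes", {
  n_nonzero <- 0L
  for (s in 1:20) {
    cohort <- small_cohort(n_probes = 300, n_case = 5, n_control = 5,
                           seed = s + 40)
    de <- build_de_table(cohort$em, top_k = 1)
    n_nonzero <- n_nonzero + (attr(de, "n_sig_adjusted") > 0)
  }
  expect_lte(n_nonzero, 3)
})
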