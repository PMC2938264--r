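#' Configuration of the repeated cross-validation engine
#'
#' Defaults follow the published design: 100 repetitions of stratified
#' 10-fold cross-validation; linear, polynomial, sigmoid and radial-basis
#' SVM kernels; cost sampled in decimal powers from 0.01 to 10; subset
#' sizes spanning the filter grid. Scale the grid down (fewer repeats, one
#' kernel) for exploratory runs.
#'
#' @param n_folds folds per cross-validation pass.
#' @param n_repeats cross-validation repetitions.
#' @param subset_sizes ascending feature-subset sizes for the t-test filter.
#' @param kernels SVM kernels to sweep.
#' @param cost_grid SVM cost values to sweep.
#' @param stratified preserve class ratios per fold (default `TRUE`).
#' @param var_equal pooled-variance t-test in the filter (default Welch).
#' @param seed master seed; fold assignments of every repeat derive from it.
#' @param max_redraws bounded re-draws when an (unstratified) fold
#'   assignment leaves a training fold single-class.
#' @return A list of class `cv_config`.
#' @export
cv_config <- function(n_folds = 10L, n_repeats = 100L,
                      subset_sizes = c(10L, 20L, 40L, 60L, 100L, 200L),
                      kernels = c("linear", "polynomial", "sigmoid", "radial"),
                      cost_grid = c(0.01, 0.1, 1, 10),
                      stratified = TRUE, var_equal = FALSE,
                      seed = 1L, max_redraws = 10L) {
  kernels <- match.arg(kernels, c("linear", "polynomial", "sigmoid", "radial"),
                       several.ok = TRUE)
  cfg <- list(n_folds = as.integer(n_folds), n_repeats = as.integer(n_repeats),
              subset_sizes = as.integer(sort(subset_sizes)), kernels = kernels,
              cost_grid = as.numeric(cost_grid), stratified = isTRUE(stratified),
              var_equal = isTRUE(var_equal), seed = as.integer(seed),
              max_redraws = as.integer(max_redraws))
  if (cfg$n_folds < 2L || cfg$n_repeats < 1L) {
    stop_mirscreen("need n_folds >= 2 and n_repeats >= 1",
                   "mirscreen_config_error")
  }
  if (any(cfg$subset_sizes < 1L) || any(cfg$cost_grid <= 0)) {
    stop_mirscreen("subset sizes must be positive integers and costs positive",
                   "mirscreen_config_error")
  }
  class(cfg) <- "cv_config"
  cfg
}

#' Assign samples to cross-validation folds
#'
#' Deterministic, seeded fold assignment with folds sized as evenly as
#' possible. With `stratified = TRUE` (the default, important for small
#' imbalanced cohorts such as 24 cases vs 15 controls) each class is dealt
#' round-robin over a shuffled fold order, with the leftover samples of
#' successive classes placed on disjoint folds, so class ratios per fold
#' are preserved within one sample.
#'
#' @param labels per-sample class labels.
#' @param n_folds number of folds.
#' @param stratified stratify by class.
#' @param seed integer seed.
#' @return Integer fold index (1..n_folds) per sample.
#' @export
assign_folds <- function(labels, n_folds = 10L, stratified = TRUE, seed = 1L) {
  labels <- as.character(labels)
  n <- length(labels)
  n_folds <- as.integer(n_folds)
  if (n_folds < 2L || n_folds > n) {
    stop_mirscreen("n_folds must be between 2 and the sample count",
                   "mirscreen_config_error")
  }
  with_seed(seed, {
    fold <- integer(n)
    if (stratified) {
      classes <- unique(labels)
      counts <- table(labels)
      if (any(counts < n_folds) && n_folds < n) {
        stop_mirscreen(
          "every class must have at least n_folds members for stratified folds",
          "mirscreen_config_error")
      }
      fold_order <- sample.int(n_folds)
      offset <- 0L
      for (cl in classes) {
        idx <- sample(which(labels == cl))
        pos <- ((offset + seq_along(idx) - 1L) %% n_folds) + 1L
        fold[idx] <- fold_order[pos]
        offset <- (offset + length(idx)) %% n_folds
      }
    } else {
      fold <- sample(rep(seq_len(n_folds), length.out = n))
    }
    fold
  })
}

#' Rank features by training-set t-test p-values
#'
#' Orders probes by ascending two-sample t-test p-value (ties: larger
#' `|t|`, then probe id) computed on the supplied samples only. This is
#' the filter applied inside every training fold of the cross-validation;
#' by contract it must never see held-out samples.
#'
#' @param x numeric matrix, probes x training samples.
#' @param labels training-sample class labels; both classes must be present.
#' @param var_equal pooled-variance form (default Welch).
#' @return Probe ids ordered from most to least significant.
#' @export
rank_features <- function(x, labels, var_equal = FALSE) {
  labels <- factor(as.character(labels), levels = c("case", "control"))
  if (length(unique(labels)) < 2L || any(table(labels) < 2L)) {
    stop_mirscreen("training fold must contain both classes (>= 2 each)",
                   "mirscreen_fold_degeneracy")
  }
  tt <- row_ttest(x, labels, var_equal = var_equal)
  rownames(x)[order(tt$p_value, -abs(tt$t_stat), rownames(x))]
}

# One cross-validation pass: for each fold rank features on the training
# part once, then train/predict every (subset_size, kernel, cost) grid
# cell. Returns a n_cells x 3 matrix of pooled accuracy/sensitivity/
# specificity. `global_ranking` (leakage probe) bypasses in-fold ranking.
cv_pass <- function(x, labels, folds, grid, var_equal = FALSE,
                    global_ranking = NULL) {
  labels <- factor(as.character(labels), levels = c("case", "control"))
  n_cells <- nrow(grid)
  pred <- matrix(NA_character_, nrow = length(labels), ncol = n_cells)
  for (f in sort(unique(folds))) {
    test_idx <- which(folds == f)
    train_idx <- which(folds != f)
    ranking <- if (is.null(global_ranking)) {
      rank_features(x[, train_idx, drop = FALSE], labels[train_idx],
                    var_equal = var_equal)
    } else {
      global_ranking
    }
    xtr <- x[, train_idx, drop = FALSE]
    xte <- x[, test_idx, drop = FALSE]
    ytr <- droplevels(labels[train_idx])
    for (cell in seq_len(n_cells)) {
      sel <- ranking[seq_len(min(grid$subset_size[cell], length(ranking)))]
      fit <- e1071::svm(x = t(xtr[sel, , drop = FALSE]), y = ytr,
                        kernel = grid$kernel[cell], cost = grid$cost[cell],
                        scale = TRUE)
      pred[test_idx, cell] <-
        as.character(predict(fit, t(xte[sel, , drop = FALSE])))
    }
  }
  truth <- as.character(labels)
  out <- matrix(NA_real_, n_cells, 3,
                dimnames = list(NULL, c("accuracy", "sensitivity",
                                        "specificity")))
  for (cell in seq_len(n_cells)) {
    out[cell, ] <- pooled_metrics(pred[, cell], truth)
  }
  out
}

pooled_metrics <- function(pred, truth) {
  c(accuracy = mean(pred == truth),
    sensitivity = mean(pred[truth == "case"] == "case"),
    specificity = mean(pred[truth == "control"] == "control"))
}

#' Evaluate one feature-subset size in a single cross-validation pass
#'
#' For each fold: rank probes by t-test on the training part, keep the top
#' `subset_size`, train an SVM on the training part and predict the
#' held-out part. Held-out predictions of all folds are pooled into one
#' confusion matrix.
#'
#' @param matrix normalized [expression_matrix()] or plain matrix.
#' @param labels class labels (if not carried by `matrix`).
#' @param folds fold assignment from [assign_folds()].
#' @param subset_size number of top-ranked probes to keep.
#' @param kernel,cost SVM kernel and cost.
#' @param var_equal pooled-variance filter t-test.
#' @return Named vector: pooled `accuracy`, `sensitivity`, `specificity`.
#' @export
evaluate_subset <- function(matrix, labels = NULL, folds, subset_size,
                            kernel = "radial", cost = 1, var_equal = FALSE) {
  xl <- resolve_matrix_labels(matrix, labels)
  if (subset_size < 1L || subset_size > nrow(xl$x)) {
    stop_mirscreen("subset_size must be between 1 and the probe count",
                   "mirscreen_config_error")
  }
  grid <- data.frame(subset_size = as.integer(subset_size), kernel = kernel,
                     cost = cost, stringsAsFactors = FALSE)
  drop(cv_pass(xl$x, xl$labels, folds, grid, var_equal = var_equal))
}

build_grid <- function(config, n_probes) {
  sizes <- unique(pmin(config$subset_sizes, n_probes))
  grid <- expand.grid(cost = config$cost_grid, kernel = config$kernels,
                      subset_size = sizes, stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  grid[, c("subset_size", "kernel", "cost")]
}

#' Repeated cross-validated SVM classification with in-fold feature filtering
#'
#' The central fitting engine: `n_repeats` repetitions of (stratified)
#' k-fold cross-validation; within each repeat and fold, probes are ranked
#' by two-sample t-test on the training fold only (no leakage), the top
#' `s` probes are kept for every subset size `s` of the grid, and an SVM is
#' trained per (subset size, kernel, cost) cell and evaluated on the
#' held-out fold. Held-out predictions are pooled per pass; per-cell
#' metrics are averaged over repeats. The best cell maximizes mean
#' accuracy, with deterministic tie-breaks (smaller subset, kernel order as
#' listed, smaller cost).
#'
#' @param matrix normalized [expression_matrix()] (or plain matrix plus
#'   `labels`).
#' @param labels class labels.
#' @param config a [cv_config()].
#' @return A list of class `cv_report`: `grid` (per-cell mean metrics),
#'   `per_repeat` (matrices of per-repeat metrics), `best` (selected cell),
#'   `selection_rule`, `config`, `n_case`, `n_control`.
#' @examples
#' \donttest{
#' ps <- make_probe_set(80, n_up = 5, n_down = 5, effect_size = 2, seed = 2)
#' raw <- simulate_cohort(ps, 12, 10, generator_config(n_probes = 80, seed = 2))
#' em <- preprocess_cohort(raw)
#' rep <- run_repeated_cv(em, config = cv_config(
#'   n_repeats = 3, subset_sizes = c(10, 20), kernels = "radial",
#'   cost_grid = 1, seed = 9))
#' rep$best$mean_accuracy
#' }
#' @export
run_repeated_cv <- function(matrix, labels = NULL, config = cv_config()) {
  stopifnot(inherits(config, "cv_config"))
  xl <- resolve_matrix_labels(matrix, labels)
  x <- xl$x
  labels <- xl$labels
  if (max(config$subset_sizes) > nrow(x)) {
    warning("subset sizes exceeding the probe count were clipped")
  }
  grid <- build_grid(config, nrow(x))
  n_cells <- nrow(grid)
  seeds <- derive_seeds(config$seed, config$n_repeats * (config$max_redraws + 1L))
  seeds <- matrix(seeds, nrow = config$n_repeats)
  acc <- sens <- spec <- matrix(NA_real_, config$n_repeats, n_cells)
  for (r in seq_len(config$n_repeats)) {
    m <- NULL
    for (attempt in seq_len(config$max_redraws + 1L)) {
      folds <- assign_folds(labels, config$n_folds, config$stratified,
                            seed = seeds[r, attempt])
      m <- tryCatch(
        cv_pass(x, labels, folds, grid, var_equal = config$var_equal),
        mirscreen_fold_degeneracy = function(e) NULL
      )
      if (!is.null(m)) break
    }
    if (is.null(m)) {
      stop_mirscreen(sprintf(
        "repeat %d: fold assignment degenerate after %d re-draws", r,
        config$max_redraws), "mirscreen_run_failure")
    }
    acc[r, ] <- m[, "accuracy"]
    sens[r, ] <- m[, "sensitivity"]
    spec[r, ] <- m[, "specificity"]
  }
  grid$mean_accuracy <- colMeans(acc)
  grid$mean_sensitivity <- colMeans(sens)
  grid$mean_specificity <- colMeans(spec)
  kernel_rank <- match(grid$kernel, config$kernels)
  best_idx <- order(-grid$mean_accuracy, grid$subset_size, kernel_rank,
                    grid$cost)[1L]
  report <- list(
    grid = grid,
    per_repeat = list(accuracy = acc, sensitivity = sens, specificity = spec),
    best = c(as.list(grid[best_idx, , drop = FALSE]), list(index = best_idx)),
    selection_rule = paste("maximize mean accuracy; ties: smaller subset",
                           "size, kernel order as configured, smaller cost"),
    config = config,
    n_case = sum(labels == "case"),
    n_control = sum(labels == "control")
  )
  class(report) <- "cv_report"
  report
}

#' @export
print.cv_report <- function(x, ...) {
  b <- x$best
  cat(sprintf(
    "cv_report: %d repeats of %d-fold CV on %d case / %d control samples\n",
    x$config$n_repeats, x$config$n_folds, x$n_case, x$n_control))
  cat(sprintf("  grid: %d cells (%d subset sizes x %d kernels x %d costs)\n",
              nrow(x$grid), length(unique(x$grid$subset_size)),
              length(unique(x$grid$kernel)), length(unique(x$grid$cost))))
  cat(sprintf(
    "  best: %s SVM, cost %g, subset of %d probes\n", b$kernel, b$cost,
    b$subset_size))
  cat(sprintf(
    "  mean accuracy %.1f%%, specificity %.1f%%, sensitivity %.1f%%\n",
    100 * b$mean_accuracy, 100 * b$mean_specificity,
    100 * b$mean_sensitivity))
  invisible(x)
}

#' @export
summary.cv_report <- function(object, ...) {
  g <- object$grid[order(-object$grid$mean_accuracy), ]
  rownames(g) <- NULL
  g
}

#' @export
plot.cv_report <- function(x, permutation = NULL, ...) {
  i <- x$best$index
  obs <- list(acc = x$per_repeat$accuracy[, i],
              spec = x$per_repeat$specificity[, i],
              sens = x$per_repeat$sensitivity[, i])
  if (is.null(permutation)) {
    boxplot(obs, ylim = c(0, 1), col = "grey25", border = "black",
            ylab = "proportion correctly classified", ...)
  } else {
    stopifnot(inherits(permutation, "permutation_report"))
    vals <- list(acc = obs$acc, spec = obs$spec, sens = obs$sens,
                 `acc (random)` = permutation$permuted[, "accuracy"],
                 `spec (random)` = permutation$permuted[, "specificity"],
                 `sens (random)` = permutation$permuted[, "sensitivity"])
    boxplot(vals, ylim = c(0, 1), col = c(rep("grey25", 3), rep("grey80", 3)),
            ylab = "proportion correctly classified", las = 2, ...)
  }
  invisible(x)
}

#' Permutation-null validation of the classification
#'
#' Re-runs the classification under label permutations to estimate
#' chance-level performance and detect overtraining. Each permutation run
#' draws one fresh random permutation of the class labels (class sizes
#' preserved) and executes the full engine under it -- fold assignment,
#' in-fold feature ranking, training and prediction -- collecting the
#' best-cell metrics. The empirical exceedance of the observed metrics is
#' `(#\{permuted >= observed\} + 1) / (runs + 1)`.
#'
#' @inheritParams run_repeated_cv
#' @param n_runs number of permutation runs.
#' @param observed an existing `cv_report` for the unpermuted labels
#'   (computed with `config` when omitted).
#' @param perm_config `cv_config` used inside each permutation run;
#'   defaults to `config` with `n_repeats = 1` (one full CV pass per
#'   permutation, the published design of "repetitions with permuted
#'   samples").
#' @return A list of class `permutation_report`: `permuted` (runs x 3
#'   metric matrix), `observed`, `exceedance`, `n_runs`.
#' @export
run_permutation <- function(matrix, labels = NULL, config = cv_config(),
                            n_runs = 100L, observed = NULL,
                            perm_config = NULL) {
  xl <- resolve_matrix_labels(matrix, labels)
  if (is.null(observed)) {
    observed <- run_repeated_cv(xl$x, xl$labels, config)
  }
  stopifnot(inherits(observed, "cv_report"))
  if (is.null(perm_config)) {
    perm_config <- config
    perm_config$n_repeats <- 1L
  }
  seeds <- derive_seeds(config$seed + 1L, 2L * n_runs)
  permuted <- matrix(NA_real_, n_runs, 3,
                     dimnames = list(NULL, c("accuracy", "sensitivity",
                                             "specificity")))
  for (i in seq_len(n_runs)) {
    perm_labels <- with_seed(seeds[i], sample(as.character(xl$labels)))
    pcfg <- perm_config
    pcfg$seed <- seeds[n_runs + i]
    rep_i <- run_repeated_cv(xl$x, perm_labels, pcfg)
    b <- rep_i$best
    permuted[i, ] <- c(b$mean_accuracy, b$mean_sensitivity,
                       b$mean_specificity)
  }
  obs <- c(accuracy = observed$best$mean_accuracy,
           sensitivity = observed$best$mean_sensitivity,
           specificity = observed$best$mean_specificity)
  exceed <- (colSums(sweep(permuted, 2L, obs, ">=")) + 1) / (n_runs + 1)
  structure(
    list(n_runs = n_runs, permuted = permuted, observed = obs,
         exceedance = exceed),
    class = "permutation_report"
  )
}

#' @export
print.permutation_report <- function(x, ...) {
  cat(sprintf("permutation_report: %d label-permutation runs\n", x$n_runs))
  cat(sprintf(
    "  observed accuracy %.1f%% vs permuted mean %.1f%% (exceedance p = %.4f)\n",
    100 * x$observed["accuracy"], 100 * mean(x$permuted[, "accuracy"]),
    x$exceedance["accuracy"]))
  invisible(x)
}

#' Demonstrate feature-selection leakage
#'
#' Self-test of the engine's anti-leakage design: runs the repeated CV
#' twice, once correctly (features re-ranked inside each training fold)
#' and once deliberately leaky (features ranked once on all samples before
#' cross-validation). On effect-free data the leaky variant's accuracy
#' exceeds the correct one -- the selection bias the in-fold filter exists
#' to avoid.
#'
#' @inheritParams run_repeated_cv
#' @return A list of class `leakage_probe` with elements `correct`,
#'   `leaky` (best-cell mean accuracies) and `difference`.
#' @export
leakage_probe <- function(matrix, labels = NULL, config = cv_config()) {
  xl <- resolve_matrix_labels(matrix, labels)
  correct <- run_repeated_cv(xl$x, xl$labels, config)
  grid <- build_grid(config, nrow(xl$x))
  global_ranking <- rank_features(xl$x, xl$labels,
                                  var_equal = config$var_equal)
  seeds <- derive_seeds(config$seed, config$n_repeats * (config$max_redraws + 1L))
  seeds <- matrix(seeds, nrow = config$n_repeats)
  acc <- matrix(NA_real_, config$n_repeats, nrow(grid))
  for (r in seq_len(config$n_repeats)) {
    folds <- assign_folds(xl$labels, config$n_folds, config$stratified,
                          seed = seeds[r, 1L])
    m <- cv_pass(xl$x, xl$labels, folds, grid, var_equal = config$var_equal,
                 global_ranking = global_ranking)
    acc[r, ] <- m[, "accuracy"]
  }
  leaky_best <- max(colMeans(acc))
  structure(
    list(correct = correct$best$mean_accuracy, leaky = leaky_best,
         difference = leaky_best - correct$best$mean_accuracy),
    class = "leakage_probe"
  )
}

#' @export
print.leakage_probe <- function(x, ...) {
  cat(sprintf(
    "leakage_probe: correct (in-fold filter) accuracy %.3f, leaky %.3f (bias +%.3f)\n",
    x$correct, x$leaky, x$difference))
  invisible(x)
}
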