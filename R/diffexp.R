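# Vectorized two-sample t statistics over the rows of a matrix.
# Welch (default) or pooled-variance Student form. Sign convention:
# positive t means the case mean exceeds the control mean.
row_ttest <- function(x, labels, var_equal = FALSE) {
  labels <- factor(as.character(labels), levels = c("case", "control"))
  g1 <- labels == "case"
  g2 <- labels == "control"
  n1 <- sum(g1); n2 <- sum(g2)
  if (n1 < 2L || n2 < 2L) {
    stop_mirscreen("each group needs at least two samples for a t-test",
                   "mirscreen_insufficient_data")
  }
  x1 <- x[, g1, drop = FALSE]
  x2 <- x[, g2, drop = FALSE]
  m1 <- rowMeans(x1)
  m2 <- rowMeans(x2)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1L)
  v2 <- rowSums((x2 - m2)^2) / (n2 - 1L)
  diff <- m1 - m2
  if (var_equal) {
    sp2 <- ((n1 - 1L) * v1 + (n2 - 1L) * v2) / (n1 + n2 - 2L)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- rep(n1 + n2 - 2L, length(diff))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1L) + (v2 / n2)^2 / (n2 - 1L))
  }
  t_stat <- diff / se
  p <- 2 * pt(-abs(t_stat), df)
  # degenerate probes: zero variance in both groups
  degen <- se == 0
  if (any(degen)) {
    equal <- degen & diff == 0
    t_stat[equal] <- 0
    p[equal] <- 1
    unequal <- degen & diff != 0
    t_stat[unequal] <- sign(diff[unequal]) * Inf
    p[unequal] <- 0
    df[degen] <- NA_real_
  }
  list(mean_case = m1, mean_control = m2, t_stat = t_stat, df = df,
       p_value = p, degenerate = degen)
}

#' Per-probe two-sample t-tests
#'
#' Unpaired two-tailed t-tests for every probe of a normalized expression
#' matrix. The unequal-variance (Welch) form is the default; the
#' pooled-variance Student form is selectable. A positive t statistic (and
#' direction `"up"`) means the case mean exceeds the control mean. Probes
#' with zero variance in both groups and equal means get `p = 1` by
#' convention and are flagged in the `degenerate` column.
#'
#' @param matrix a normalized [expression_matrix()] with labels, or a
#'   plain numeric matrix if `labels` is given.
#' @param labels class labels (`"case"`/`"control"`), required when
#'   `matrix` is a plain matrix.
#' @param var_equal use the pooled-variance form (default `FALSE`: Welch).
#' @return A `data.frame` with one row per probe: `probe_id`, `mean_case`,
#'   `mean_control`, `direction`, `t_stat`, `p_value`, `degenerate`
#'   (`p_adjusted` and `rank` are filled by [build_de_table()]).
#' @export
ttest_per_feature <- function(matrix, labels = NULL, var_equal = FALSE) {
  xl <- resolve_matrix_labels(matrix, labels)
  tt <- row_ttest(xl$x, xl$labels, var_equal = var_equal)
  data.frame(
    probe_id = rownames(xl$x),
    mean_case = tt$mean_case,
    mean_control = tt$mean_control,
    direction = ifelse(tt$t_stat >= 0, "up", "down"),
    t_stat = tt$t_stat,
    p_value = tt$p_value,
    p_adjusted = NA_real_,
    degenerate = tt$degenerate,
    row.names = NULL, stringsAsFactors = FALSE
  )
}

resolve_matrix_labels <- function(matrix, labels) {
  if (inherits(matrix, "expression_matrix")) {
    x <- matrix$values
    if (is.null(labels)) labels <- matrix$labels
  } else {
    x <- as.matrix(matrix)
    if (is.null(rownames(x))) {
      rownames(x) <- sprintf("probe_%04d", seq_len(nrow(x)))
    }
  }
  if (is.null(labels)) {
    stop_mirscreen("class labels are required", "mirscreen_schema_error")
  }
  list(x = x, labels = factor(as.character(labels),
                              levels = c("case", "control")))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment: sorted p-values are multiplied
#' by `m / rank`, monotonicity is enforced by a cumulative minimum from the
#' largest rank, values are capped at 1 and returned in the input order.
#' Delegates to [stats::p.adjust()] after validating the domain.
#'
#' @param p_values numeric vector of p-values in \[0, 1\].
#' @return Adjusted values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  if (!is.numeric(p_values) || anyNA(p_values) ||
      any(p_values < 0 | p_values > 1)) {
    stop_mirscreen("p-values must be numeric in [0, 1]",
                   "mirscreen_domain_error")
  }
  p.adjust(p_values, method = "BH")
}

#' Per-probe normality screen
#'
#' Shapiro-Wilk tests of each probe within each class. A probe passes when
#' neither group rejects normality at `alpha`; constant-valued (degenerate)
#' probes fail. The screen is advisory: it reports the passing fraction and
#' never gates the downstream t-tests.
#'
#' @param matrix normalized [expression_matrix()] (or plain matrix with
#'   `labels`); at least 3 samples per group.
#' @param labels optional class labels.
#' @param alpha per-group test level.
#' @return A `data.frame` of class `normality_screen` with columns
#'   `probe_id`, `p_case`, `p_control`, `pass`; the passing fraction is in
#'   attribute `"pass_fraction"`.
#' @export
normality_screen <- function(matrix, labels = NULL, alpha = 0.05) {
  xl <- resolve_matrix_labels(matrix, labels)
  x <- xl$x
  g1 <- xl$labels == "case"
  g2 <- xl$labels == "control"
  if (sum(g1) < 3L || sum(g2) < 3L) {
    stop_mirscreen("normality screening needs at least 3 samples per group",
                   "mirscreen_insufficient_data")
  }
  sw <- function(v) {
    tryCatch(shapiro.test(v)$p.value, error = function(e) 0)
  }
  p_case <- apply(x[, g1, drop = FALSE], 1L, sw)
  p_control <- apply(x[, g2, drop = FALSE], 1L, sw)
  out <- data.frame(probe_id = rownames(x), p_case = p_case,
                    p_control = p_control,
                    pass = p_case > alpha & p_control > alpha,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "pass_fraction") <- mean(out$pass)
  attr(out, "alpha") <- alpha
  class(out) <- c("normality_screen", "data.frame")
  out
}

#' @export
print.normality_screen <- function(x, ...) {
  cat(sprintf(
    "normality_screen: %.1f%% of %d probes pass Shapiro-Wilk in both groups (alpha = %g)\n",
    100 * attr(x, "pass_fraction"), nrow(x), attr(x, "alpha")))
  invisible(x)
}

#' Ranked differential-expression table
#'
#' Computes per-probe t-tests and Benjamini-Hochberg adjusted p-values,
#' ranks probes by ascending p-value (ties: larger `|t|` first, then
#' probe id), and truncates to the top `top_k` rows -- the style of a
#' "top deregulated miRNAs" table. Counts of probes significant before
#' (`p < alpha`) and after adjustment are kept as attributes.
#'
#' @inheritParams ttest_per_feature
#' @param top_k rows to keep (clipped to the probe count with a warning).
#' @param alpha significance level used for the summary counts.
#' @return A `data.frame` of class `de_table` with a `rank` column;
#'   attributes `n_probes`, `n_sig_raw`, `n_sig_adjusted`, `alpha`.
#' @examples
#' ps <- make_probe_set(60, n_up = 2, n_down = 2, effect_size = 2, seed = 3)
#' raw <- simulate_cohort(ps, 8, 8, generator_config(n_probes = 60, seed = 3))
#' de <- build_de_table(preprocess_cohort(raw), top_k = 10)
#' de$probe_id[1:4]
#' @export
build_de_table <- function(matrix, labels = NULL, top_k = 30L,
                           var_equal = FALSE, alpha = 0.05) {
  tab <- ttest_per_feature(matrix, labels = labels, var_equal = var_equal)
  tab$p_adjusted <- bh_adjust(tab$p_value)
  ord <- order(tab$p_value, -abs(tab$t_stat), tab$probe_id)
  tab <- tab[ord, , drop = FALSE]
  tab$rank <- seq_len(nrow(tab))
  n_probes <- nrow(tab)
  n_sig_raw <- sum(tab$p_value < alpha)
  n_sig_adj <- sum(tab$p_adjusted < alpha)
  if (top_k > n_probes) {
    warning(sprintf("top_k = %d exceeds the %d probes; returning all rows",
                    top_k, n_probes))
    top_k <- n_probes
  }
  tab <- tab[seq_len(top_k), , drop = FALSE]
  rownames(tab) <- NULL
  attr(tab, "n_probes") <- n_probes
  attr(tab, "n_sig_raw") <- n_sig_raw
  attr(tab, "n_sig_adjusted") <- n_sig_adj
  attr(tab, "alpha") <- alpha
  class(tab) <- c("de_table", "data.frame")
  tab
}

#' @export
print.de_table <- function(x, n = 10L, ...) {
  cat(sprintf(
    "de_table: top %d of %d probes; %d with p < %g unadjusted, %d after BH adjustment\n",
    nrow(x), attr(x, "n_probes"), attr(x, "n_sig_raw"),
    attr(x, "alpha"), attr(x, "n_sig_adjusted")))
  print.data.frame(head(as.data.frame(x), n), digits = 4)
  invisible(x)
}
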