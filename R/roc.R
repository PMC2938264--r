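#' Receiver operating characteristic curve for a single marker
#'
#' Sweeps the decision threshold over the observed scores of one marker and
#' records true- and false-positive rates, one point per distinct score
#' (ties grouped at a single threshold) plus the two degenerate endpoints.
#' The area under the curve is the trapezoidal integral of TPR over FPR and,
#' with the tie convention of [auc_rank()], equals the probability that a
#' randomly chosen positive sample is ranked higher than a randomly chosen
#' negative one. Orientation is explicit and never auto-flipped: an AUC
#' below 0.5 is reported as-is.
#'
#' @param scores numeric per-sample scores (e.g. normalized intensities of
#'   one miRNA).
#' @param labels per-sample class labels.
#' @param positive_label label of the positive class (default `"case"`).
#' @param orientation `"greater"` if high scores indicate the positive
#'   class, `"less"` otherwise.
#' @return A list of class `roc_curve`: `thresholds` (in sweep order, from
#'   most to least stringent), `fpr`, `tpr`, `auc`, `positive_label`,
#'   `orientation`, `n_pos`, `n_neg`.
#' @examples
#' roc_curve(c(3, 1, 2, 0), c("case", "case", "control", "control"))$auc
#' @export
roc_curve <- function(scores, labels, positive_label = "case",
                      orientation = c("greater", "less")) {
  orientation <- match.arg(orientation)
  labels <- as.character(labels)
  if (length(scores) != length(labels)) {
    stop_mirscreen("scores and labels differ in length",
                   "mirscreen_schema_error")
  }
  if (!all(is.finite(scores))) {
    stop_mirscreen("scores must be finite", "mirscreen_domain_error")
  }
  pos <- labels == positive_label
  n_pos <- sum(pos)
  n_neg <- sum(!pos)
  if (n_pos == 0L || n_neg == 0L) {
    stop_mirscreen("ROC is undefined with a single class",
                   "mirscreen_undefined_roc")
  }
  s <- if (orientation == "greater") scores else -scores
  ord <- order(s, decreasing = TRUE)
  s_sorted <- s[ord]
  pos_sorted <- pos[ord]
  distinct <- c(s_sorted[-1] != s_sorted[-length(s_sorted)], TRUE)
  tp <- cumsum(pos_sorted)[distinct]
  fp <- cumsum(!pos_sorted)[distinct]
  tpr <- c(0, tp / n_pos)
  fpr <- c(0, fp / n_neg)
  thr <- s_sorted[distinct]
  if (orientation == "less") thr <- -thr
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  structure(
    list(thresholds = c(Inf * ifelse(orientation == "greater", 1, -1), thr),
         fpr = fpr, tpr = tpr, auc = auc,
         positive_label = positive_label, orientation = orientation,
         n_pos = n_pos, n_neg = n_neg),
    class = "roc_curve"
  )
}

#' Exact rank-statistic AUC
#'
#' Pairwise Mann-Whitney computation of the area under the ROC curve:
#' `(#\{pos > neg\} + 0.5 * #\{pos = neg\}) / (n_pos * n_neg)`, i.e. the
#' probability that a randomly chosen positive sample scores higher than a
#' randomly chosen negative one, with half credit for ties. Serves as the
#' independent oracle for [roc_curve()]'s trapezoidal AUC.
#'
#' @inheritParams roc_curve
#' @return The AUC in \[0, 1\].
#' @export
auc_rank <- function(scores, labels, positive_label = "case") {
  labels <- as.character(labels)
  pos <- scores[labels == positive_label]
  neg <- scores[labels != positive_label]
  if (length(pos) == 0L || length(neg) == 0L) {
    stop_mirscreen("AUC is undefined with a single class",
                   "mirscreen_undefined_roc")
  }
  cmp <- outer(pos, neg, ">") + 0.5 * outer(pos, neg, "==")
  mean(cmp)
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf(
    "roc_curve: AUC = %.4f (%d positive '%s' vs %d negative; orientation: %s)\n",
    x$auc, x$n_pos, x$positive_label, x$n_neg, x$orientation))
  invisible(x)
}

#' @export
plot.roc_curve <- function(x, ...) {
  plot(x$fpr, x$tpr, type = "s", xlim = c(0, 1), ylim = c(0, 1),
       xlab = "False positive rate (1 - specificity)",
       ylab = "True positive rate (sensitivity)",
       main = sprintf("ROC (AUC = %.3f)", x$auc), ...)
  abline(0, 1, lty = 3, col = "grey50")
  invisible(x)
}
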