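#' Construct an expression matrix container
#'
#' Minimal features-by-samples container used throughout the pipeline.
#' `stage` tracks whether values are raw replicate-summarized intensities
#' or glog-normalized values; stage checks keep the chain idempotent (a
#' normalized matrix is rejected by [fit_normalization()] rather than
#' silently re-normalized).
#'
#' @param values numeric matrix, probes in rows, samples in columns.
#' @param probe_ids,sample_ids unique identifiers (default: dimnames).
#' @param labels optional per-sample class labels (`"case"`/`"control"`).
#' @param stage `"raw-summarized"` or `"normalized"`.
#' @return A list of class `expression_matrix`.
#' @export
expression_matrix <- function(values, probe_ids = rownames(values),
                              sample_ids = colnames(values),
                              labels = NULL,
                              stage = c("raw-summarized", "normalized")) {
  stage <- match.arg(stage)
  values <- as.matrix(values)
  if (is.null(probe_ids) || is.null(sample_ids)) {
    stop_mirscreen("probe and sample ids are required", "mirscreen_schema_error")
  }
  if (anyDuplicated(probe_ids) || anyDuplicated(sample_ids)) {
    stop_mirscreen("duplicate probe or sample ids", "mirscreen_schema_error")
  }
  if (length(probe_ids) != nrow(values) || length(sample_ids) != ncol(values)) {
    stop_mirscreen("id lists inconsistent with matrix dimensions",
                   "mirscreen_schema_error")
  }
  if (anyNA(values) || !is.numeric(values)) {
    stop_mirscreen("values must be numeric without missing cells",
                   "mirscreen_schema_error")
  }
  if (!is.null(labels)) {
    labels <- factor(as.character(labels), levels = c("case", "control"))
    if (length(labels) != ncol(values) || anyNA(labels)) {
      stop_mirscreen("labels must be 'case'/'control', one per sample",
                     "mirscreen_schema_error")
    }
  }
  dimnames(values) <- list(probe_ids, sample_ids)
  structure(list(values = values, probe_ids = probe_ids,
                 sample_ids = sample_ids, labels = labels, stage = stage),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d probes x %d samples (stage: %s)\n",
              nrow(x$values), ncol(x$values), x$stage))
  if (!is.null(x$labels)) {
    cat(sprintf("  classes: %d case / %d control\n",
                sum(x$labels == "case"), sum(x$labels == "control")))
  }
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' Subtract per-spot background estimates
#'
#' Replaces each spot intensity by `max(intensity - background, floor)`.
#' The floor keeps corrected values positive ahead of the glog transform;
#' by default it is the 1st percentile of the positive corrected values,
#' but at least 0.5. Correcting an already-corrected set is an error (the
#' subtraction must never be applied twice).
#'
#' @param raw a `raw_array_set` from [simulate_cohort()] or [read_cohort()].
#' @param floor optional fixed positive floor.
#' @return The corrected `raw_array_set` (`corrected = TRUE`).
#' @export
background_correct <- function(raw, floor = NULL) {
  stopifnot(inherits(raw, "raw_array_set"))
  if (isTRUE(raw$corrected)) {
    stop_mirscreen("raw_array_set is already background-corrected",
                   "mirscreen_idempotency_error")
  }
  corrected <- raw$intensities - raw$backgrounds
  if (is.null(floor)) {
    pos <- corrected[corrected > 0]
    floor <- if (length(pos)) max(0.5, quantile(pos, 0.01)) else 0.5
  }
  if (floor <= 0) {
    stop_mirscreen("floor must be positive", "mirscreen_config_error")
  }
  raw$intensities <- pmax(corrected, floor)
  raw$corrected <- TRUE
  raw$floor <- floor
  raw
}

#' Median-summarize replicate spots
#'
#' Collapses the replicate spots of each probe on each array to their
#' median, yielding one intensity per (probe, sample).
#'
#' @param corrected a background-corrected `raw_array_set`.
#' @return An [expression_matrix()] with `stage = "raw-summarized"`.
#' @export
summarize_replicates <- function(corrected) {
  stopifnot(inherits(corrected, "raw_array_set"))
  if (!isTRUE(corrected$corrected)) {
    stop_mirscreen("input must be background-corrected first",
                   "mirscreen_stage_error")
  }
  d <- dim(corrected$intensities)
  # median over the spot dimension, vectorized over (probe, sample)
  m <- matrix(aperm(corrected$intensities, c(2, 1, 3)), nrow = d[2])
  med <- apply(m, 2L, median)
  values <- matrix(med, nrow = d[1], ncol = d[3])
  expression_matrix(values,
                    probe_ids = dimnames(corrected$intensities)[[1]],
                    sample_ids = corrected$samples$sample_id,
                    labels = corrected$samples$class_label,
                    stage = "raw-summarized")
}

#' Fit a glog variance-stabilizing normalization model
#'
#' Fits, per array, an affine calibration (offset, scale) against a robust
#' reference profile -- the probe-wise median across arrays -- using
#' iteratively reweighted least squares (Huber loss via [MASS::rlm()]), so
#' that up to ~30% outlying probes do not drive the calibration. Normalized
#' values are `arsinh((offset + scale * x) / cofactor)`, i.e. a generalized
#' log transform of the between-array-calibrated intensities, stabilizing
#' measurement variance across the intensity range.
#'
#' @param matrix an [expression_matrix()] with `stage = "raw-summarized"`
#'   and at least two samples.
#' @param cofactor positive glog cofactor (default 1).
#' @return A list of class `glog_norm` with per-array `offsets` and
#'   `scales`, the `reference` profile, the `cofactor`, and `trained`, the
#'   normalized training matrix.
#' @seealso [apply_normalization()], [predict.glog_norm()]
#' @export
fit_normalization <- function(matrix, cofactor = 1) {
  stopifnot(inherits(matrix, "expression_matrix"))
  if (matrix$stage != "raw-summarized") {
    stop_mirscreen("normalization must be fitted on raw-summarized values",
                   "mirscreen_stage_error")
  }
  if (ncol(matrix$values) < 2L) {
    stop_mirscreen("at least two samples are required to fit normalization",
                   "mirscreen_insufficient_data")
  }
  if (cofactor <= 0) {
    stop_mirscreen("cofactor must be positive", "mirscreen_config_error")
  }
  x <- matrix$values
  reference <- apply(x, 1L, median)
  n_s <- ncol(x)
  offsets <- numeric(n_s)
  scales <- numeric(n_s)
  for (j in seq_len(n_s)) {
    cf <- tryCatch(
      coef(suppressWarnings(MASS::rlm(reference ~ x[, j], maxit = 100))),
      error = function(e) coef(lm(reference ~ x[, j]))
    )
    if (!all(is.finite(cf)) || cf[2] <= 0) {
      cf <- coef(lm(reference ~ x[, j]))
    }
    offsets[j] <- cf[1]
    scales[j] <- cf[2]
  }
  model <- structure(
    list(offsets = offsets, scales = scales, cofactor = cofactor,
         reference = reference, probe_ids = matrix$probe_ids,
         sample_ids = matrix$sample_ids),
    class = "glog_norm"
  )
  model$trained <- apply_normalization(model, matrix)
  model
}

#' Apply a fitted normalization model
#'
#' Transforms a raw-summarized matrix with the per-array affine
#' calibrations and glog transform of a fitted `glog_norm` model. The
#' matrix must have the probe set and sample layout the model was fitted
#' on; applying the model to its own training matrix reproduces the stored
#' normalized values exactly.
#'
#' @param model a [fit_normalization()] result.
#' @param matrix an [expression_matrix()] with `stage = "raw-summarized"`.
#' @return An [expression_matrix()] with `stage = "normalized"`.
#' @export
apply_normalization <- function(model, matrix) {
  stopifnot(inherits(model, "glog_norm"), inherits(matrix, "expression_matrix"))
  if (matrix$stage != "raw-summarized") {
    stop_mirscreen("can only normalize raw-summarized values",
                   "mirscreen_stage_error")
  }
  if (!identical(model$probe_ids, matrix$probe_ids)) {
    stop_mirscreen("probe set of matrix does not match the fitted model",
                   "mirscreen_schema_error")
  }
  if (ncol(matrix$values) != length(model$scales)) {
    stop_mirscreen("sample layout of matrix does not match the fitted model",
                   "mirscreen_schema_error")
  }
  cal <- sweep(sweep(matrix$values, 2L, model$scales, "*"),
               2L, model$offsets, "+")
  expression_matrix(asinh(cal / model$cofactor),
                    probe_ids = matrix$probe_ids,
                    sample_ids = matrix$sample_ids,
                    labels = matrix$labels, stage = "normalized")
}

#' @export
predict.glog_norm <- function(object, newdata, ...) {
  apply_normalization(object, newdata)
}

#' @export
print.glog_norm <- function(x, ...) {
  cat(sprintf("glog_norm: %d arrays calibrated to a %d-probe median reference\n",
              length(x$scales), length(x$reference)))
  cat(sprintf("  scale range [%.3f, %.3f], offset range [%.2f, %.2f], cofactor %.3g\n",
              min(x$scales), max(x$scales), min(x$offsets), max(x$offsets),
              x$cofactor))
  invisible(x)
}

#' Run the full preprocessing chain
#'
#' Convenience wrapper: background correction, median summarization of
#' replicate spots, and glog normalization, in that order.
#'
#' @param raw a `raw_array_set`.
#' @param floor optional background floor (see [background_correct()]).
#' @param cofactor glog cofactor (see [fit_normalization()]).
#' @return A normalized [expression_matrix()]; the fitted `glog_norm`
#'   model is attached as attribute `"normalization"`.
#' @export
preprocess_cohort <- function(raw, floor = NULL, cofactor = 1) {
  summarized <- summarize_replicates(background_correct(raw, floor = floor))
  model <- fit_normalization(summarized, cofactor = cofactor)
  out <- model$trained
  attr(out, "normalization") <- model
  out
}
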