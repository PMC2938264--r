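# Text formats: long probe-level TSV for raw cohorts, wide TSV + JSON
# sidecar for expression matrices, TSV sample sheets. All writers emit
# full float precision (17 significant digits) so write/read round-trips
# are exact.

fmt_num <- function(x) sprintf("%.17g", x)

#' Write a simulated cohort to a directory of TSV files
#'
#' Emits the probe-level long-format table (`cohort.tsv`: probe_id,
#' spot_index, sample_id, intensity, background), the sample sheet
#' (`samples.tsv`: sample_id, class_label, subtype) and the planted truth
#' (`truth.tsv`: probe_id, planted_effect).
#'
#' @param raw a `raw_array_set`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(raw, dir) {
  stopifnot(inherits(raw, "raw_array_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- dim(raw$intensities)
  long <- data.frame(
    probe_id = rep(dimnames(raw$intensities)[[1]], times = d[2] * d[3]),
    spot_index = rep(rep(seq_len(d[2]), each = d[1]), times = d[3]),
    sample_id = rep(raw$samples$sample_id, each = d[1] * d[2]),
    intensity = fmt_num(as.vector(raw$intensities)),
    background = fmt_num(as.vector(raw$backgrounds)),
    stringsAsFactors = FALSE
  )
  write.table(long, file.path(dir, "cohort.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(raw$samples, file.path(dir, "samples.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  truth <- data.frame(probe_id = raw$probes$probe_id,
                      planted_effect = fmt_num(raw$probes$planted_effect),
                      stringsAsFactors = FALSE)
  write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a probe-level cohort written by [write_cohort()]
#'
#' @param dir directory containing `cohort.tsv` and `samples.tsv`.
#' @return A `raw_array_set` (uncorrected; `probes` carries the planted
#'   truth if `truth.tsv` is present).
#' @export
read_cohort <- function(dir) {
  long <- read.delim(file.path(dir, "cohort.tsv"), stringsAsFactors = FALSE)
  samples <- read.delim(file.path(dir, "samples.tsv"),
                        stringsAsFactors = FALSE)
  probe_ids <- unique(long$probe_id)
  spots <- sort(unique(long$spot_index))
  ord <- order(match(long$sample_id, samples$sample_id),
               long$spot_index, match(long$probe_id, probe_ids))
  long <- long[ord, ]
  dims <- c(length(probe_ids), length(spots), nrow(samples))
  if (nrow(long) != prod(dims)) {
    stop_mirscreen("cohort table is incomplete: expected one row per (probe, spot, sample)",
                   "mirscreen_parse_error")
  }
  intens <- array(long$intensity, dim = dims,
                  dimnames = list(probe_ids, sprintf("spot_%d", spots),
                                  samples$sample_id))
  bg <- array(long$background, dim = dims, dimnames = dimnames(intens))
  probes <- NULL
  truth_path <- file.path(dir, "truth.tsv")
  if (file.exists(truth_path)) {
    tr <- read.delim(truth_path, stringsAsFactors = FALSE)
    probes <- structure(
      data.frame(probe_id = tr$probe_id, is_star = grepl("\\*$", tr$probe_id),
                 planted_effect = as.numeric(tr$planted_effect),
                 baseline_log_mean = NA_real_, baseline_log_sd = NA_real_,
                 stringsAsFactors = FALSE),
      class = c("probe_set", "data.frame"))
  }
  structure(
    list(intensities = intens, backgrounds = bg, samples = samples,
         probes = probes, corrected = FALSE, config = NULL),
    class = "raw_array_set"
  )
}

#' Write an expression matrix as wide TSV with a JSON sidecar
#'
#' The TSV has `probe_id` as first column and one column per sample; the
#' sidecar `<path>.json` records the stage and, when present, the
#' normalization parameters; the sample sheet goes to
#' `<path>.samples.tsv` when labels are available.
#'
#' @param em an [expression_matrix()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(em, path) {
  stopifnot(inherits(em, "expression_matrix"))
  df <- data.frame(probe_id = em$probe_ids, stringsAsFactors = FALSE)
  for (j in seq_along(em$sample_ids)) {
    df[[em$sample_ids[j]]] <- fmt_num(em$values[, j])
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  sidecar <- list(stage = em$stage)
  norm <- attr(em, "normalization")
  if (!is.null(norm)) {
    sidecar$normalization <- list(offsets = norm$offsets,
                                  scales = norm$scales,
                                  cofactor = norm$cofactor)
  }
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  if (!is.null(em$labels)) {
    write.table(data.frame(sample_id = em$sample_ids,
                           class_label = as.character(em$labels),
                           stringsAsFactors = FALSE),
                paste0(path, ".samples.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(path)
}

#' Read a wide expression-matrix TSV
#'
#' Validates the file shape before parsing: ragged rows, non-numeric cells
#' and duplicate probe or sample ids are rejected with the offending line
#' named. Labels are taken from `sample_sheet` (TSV with `sample_id`,
#' `class_label`) or from the `<path>.samples.tsv` sidecar if present; the
#' stage is read from the `<path>.json` sidecar, defaulting to
#' `"raw-summarized"`.
#'
#' @param path TSV path as written by [write_expression_matrix()].
#' @param sample_sheet optional sample-sheet TSV path.
#' @return An [expression_matrix()].
#' @export
read_expression_matrix <- function(path, sample_sheet = NULL) {
  fields <- count.fields(path, sep = "\t", quote = "")
  if (length(unique(fields)) != 1L) {
    bad <- which(fields != fields[1L])[1L]
    stop_mirscreen(sprintf("ragged TSV: line %d has %d fields, expected %d",
                           bad, fields[bad], fields[1L]),
                   "mirscreen_parse_error")
  }
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                   colClasses = "character")
  if (names(df)[1L] != "probe_id") {
    stop_mirscreen("first column must be 'probe_id'", "mirscreen_parse_error")
  }
  if (anyDuplicated(df$probe_id)) {
    dup <- which(duplicated(df$probe_id))[1L]
    stop_mirscreen(sprintf("duplicate probe id '%s' at line %d",
                           df$probe_id[dup], dup + 1L),
                   "mirscreen_parse_error")
  }
  sample_ids <- names(df)[-1L]
  if (anyDuplicated(sample_ids)) {
    stop_mirscreen("duplicate sample ids in header", "mirscreen_parse_error")
  }
  values <- matrix(NA_real_, nrow(df), length(sample_ids))
  for (j in seq_along(sample_ids)) {
    v <- suppressWarnings(as.numeric(df[[j + 1L]]))
    if (anyNA(v)) {
      bad <- which(is.na(v))[1L]
      stop_mirscreen(sprintf(
        "non-numeric cell in column '%s' at line %d: '%s'",
        sample_ids[j], bad + 1L, df[[j + 1L]][bad]),
        "mirscreen_parse_error")
    }
    values[, j] <- v
  }
  labels <- NULL
  sheet_path <- if (!is.null(sample_sheet)) sample_sheet
                else paste0(path, ".samples.tsv")
  if (file.exists(sheet_path)) {
    sheet <- read.delim(sheet_path, stringsAsFactors = FALSE)
    labels <- sheet$class_label[match(sample_ids, sheet$sample_id)]
  }
  stage <- "raw-summarized"
  sidecar_path <- paste0(path, ".json")
  if (file.exists(sidecar_path)) {
    stage <- jsonlite::read_json(sidecar_path)$stage
  }
  expression_matrix(values, probe_ids = df$probe_id, sample_ids = sample_ids,
                    labels = labels, stage = stage)
}

#' Configuration of the end-to-end pipeline
#'
#' Nested configuration driving [run_pipeline()]: generator settings,
#' cohort sizes, DE-table depth, cross-validation grid, permutation-run
#' count and the prevalences at which screening metrics are evaluated.
#' All randomness derives from the single `seed`.
#'
#' @param seed master seed of the whole run.
#' @param n_case,n_control cohort sizes.
#' @param generator a [generator_config()] (its seed is overridden by
#'   `seed`).
#' @param top_k rows of the reported DE table.
#' @param cv a [cv_config()] (its seed is overridden by `seed + 1`).
#' @param n_permutation_runs permutation runs (0 disables the null check).
#' @param prevalences named vector of prevalences for the screening
#'   arithmetic.
#' @param target_ppv target used to report the prevalence needed for that
#'   PPV.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, n_case = 24L, n_control = 15L,
                            generator = generator_config(n_up = 2L, n_down = 2L,
                                                         effect_size = 2),
                            top_k = 30L,
                            cv = cv_config(),
                            n_permutation_runs = 100L,
                            prevalences = c(general_population = 4e-4),
                            target_ppv = 0.10) {
  cfg <- list(seed = as.integer(seed), n_case = as.integer(n_case),
              n_control = as.integer(n_control), generator = generator,
              top_k = as.integer(top_k), cv = cv,
              n_permutation_runs = as.integer(n_permutation_runs),
              prevalences = prevalences, target_ppv = target_ppv)
  class(cfg) <- "pipeline_config"
  cfg
}

pipeline_stage <- function(name, expr) {
  t0 <- proc.time()[["elapsed"]]
  out <- tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE)
  })
  message(sprintf("[%s] done in %.1fs", name,
                  proc.time()[["elapsed"]] - t0))
  out
}

#' Run the complete analysis pipeline
#'
#' Chains simulation, preprocessing, differential expression, single-marker
#' ROC, repeated-CV classification with permutation null, and screening
#' arithmetic; writes every artifact plus a manifest with MD5 checksums to
#' `out_dir`. Re-running with an identical configuration reproduces
#' identical files and checksums.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory.
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  if (config$n_case < 1L || config$n_control < 1L) {
    stop_mirscreen("cohort sizes must be positive", "mirscreen_config_error")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  gen <- config$generator
  gen$seed <- config$seed
  raw <- pipeline_stage("simulate", {
    ps <- make_probe_set(gen$n_probes, gen$n_up, gen$n_down,
                         gen$effect_size, seed = gen$seed)
    r <- simulate_cohort(ps, config$n_case, config$n_control, gen)
    write_cohort(r, file.path(out_dir, "cohort"))
    r
  })

  em <- pipeline_stage("preprocess", {
    e <- preprocess_cohort(raw)
    write_expression_matrix(e, file.path(out_dir, "expression_matrix.tsv"))
    e
  })

  de <- pipeline_stage("diffexp", {
    d <- build_de_table(em, top_k = min(config$top_k, gen$n_probes))
    out <- as.data.frame(d)
    out$mean_case <- fmt_num(out$mean_case)
    out$mean_control <- fmt_num(out$mean_control)
    out$t_stat <- fmt_num(out$t_stat)
    out$p_value <- fmt_num(out$p_value)
    out$p_adjusted <- fmt_num(out$p_adjusted)
    write.table(out, file.path(out_dir, "de_table.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    d
  })

  roc <- pipeline_stage("roc", {
    top_probe <- de$probe_id[1L]
    orient <- if (de$direction[1L] == "up") "greater" else "less"
    rc <- roc_curve(em$values[top_probe, ], em$labels,
                    orientation = orient)
    write.table(data.frame(threshold = fmt_num(rc$thresholds),
                           fpr = fmt_num(rc$fpr), tpr = fmt_num(rc$tpr)),
                file.path(out_dir, "roc_curve.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    jsonlite::write_json(list(probe_id = top_probe, auc = rc$auc,
                              orientation = orient),
                         file.path(out_dir, "roc_summary.json"),
                         auto_unbox = TRUE, digits = NA)
    rc
  })

  cv <- config$cv
  cv$seed <- config$seed + 1L
  report <- pipeline_stage("classify", {
    rp <- run_repeated_cv(em, config = cv)
    jsonlite::write_json(
      list(grid = rp$grid, best = rp$best, selection_rule = rp$selection_rule,
           n_case = rp$n_case, n_control = rp$n_control),
      file.path(out_dir, "cv_report.json"), auto_unbox = TRUE, digits = NA)
    write.table(data.frame(repeat_index = seq_len(cv$n_repeats),
                           accuracy = fmt_num(rp$per_repeat$accuracy[, rp$best$index]),
                           sensitivity = fmt_num(rp$per_repeat$sensitivity[, rp$best$index]),
                           specificity = fmt_num(rp$per_repeat$specificity[, rp$best$index])),
                file.path(out_dir, "cv_per_repeat.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    rp
  })

  if (config$n_permutation_runs > 0L) {
    pipeline_stage("permutation", {
      pm <- run_permutation(em, config = cv,
                            n_runs = config$n_permutation_runs,
                            observed = report)
      jsonlite::write_json(
        list(n_runs = pm$n_runs, observed = as.list(pm$observed),
             exceedance = as.list(pm$exceedance),
             permuted_mean = as.list(colMeans(pm$permuted))),
        file.path(out_dir, "permutation_report.json"), auto_unbox = TRUE,
        digits = NA)
      pm
    })
  }

  pipeline_stage("screen-math", {
    sens <- report$best$mean_sensitivity
    spec <- report$best$mean_specificity
    scr <- lapply(config$prevalences, function(p) {
      list(prevalence = p, ppv = ppv(sens, spec, p), npv = npv(sens, spec, p))
    })
    risk_prev <- tryCatch(
      prevalence_for_ppv(sens, spec, config$target_ppv),
      mirscreen_domain_error = function(e) NA_real_)
    out <- list(sensitivity = sens, specificity = spec, at = scr,
                target_ppv = config$target_ppv,
                prevalence_for_target_ppv = risk_prev)
    if (is.finite(risk_prev)) {
      out$npv_at_target_prevalence <- npv(sens, spec, risk_prev)
    }
    jsonlite::write_json(out, file.path(out_dir, "screening.json"),
                         auto_unbox = TRUE, digits = NA)
    out
  })

  files <- sort(setdiff(list.files(out_dir, recursive = TRUE),
                        "manifest.json"))
  checksums <- tools::md5sum(file.path(out_dir, files))
  names(checksums) <- files
  manifest <- list(
    package = "mirscreen",
    version = as.character(packageVersion("mirscreen")),
    seed = config$seed,
    n_case = config$n_case, n_control = config$n_control,
    n_probes = gen$n_probes,
    files = as.list(checksums)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
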