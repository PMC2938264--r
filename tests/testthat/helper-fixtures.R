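# Shared fixtures, all generated in code.

# Small preprocessed case-control cohort with optional planted effects.
small_cohort <- function(n_probes = 60, n_case = 8, n_control = 6,
                         n_up = 0, n_down = 0, effect_size = 0, seed = 1) {
  ps <- make_probe_set(n_probes, n_up = n_up, n_down = n_down,
                       effect_size = effect_size, seed = seed)
  cfg <- generator_config(n_probes = n_probes, n_up = n_up, n_down = n_down,
                          effect_size = effect_size, seed = seed)
  raw <- simulate_cohort(ps, n_case, n_control, cfg)
  list(probes = ps, raw = raw, em = preprocess_cohort(raw))
}

# Hand-built raw_array_set from explicit arrays (probe x spot x sample).
toy_raw <- function(intensities, backgrounds = NULL) {
  d <- dim(intensities)
  if (is.null(backgrounds)) backgrounds <- array(0, dim = d)
  dimnames(intensities) <- list(sprintf("p%02d", seq_len(d[1])),
                                sprintf("spot_%d", seq_len(d[2])),
                                sprintf("s%02d", seq_len(d[3])))
  dimnames(backgrounds) <- dimnames(intensities)
  n_case <- ceiling(d[3] / 2)
  samples <- data.frame(
    sample_id = dimnames(intensities)[[3]],
    class_label = rep(c("case", "control"),
                      c(n_case, d[3] - n_case)),
    subtype = "none", stringsAsFactors = FALSE)
  structure(list(intensities = intensities, backgrounds = backgrounds,
                 samples = samples, probes = NULL, corrected = FALSE,
                 config = NULL),
            class = "raw_array_set")
}

# Independent brute-force Benjamini-Hochberg step-up oracle.
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- p[ord] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[ord] <- adj
  out
}
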