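#' @keywords internal
#' @importFrom stats median rnorm runif sd var cor quantile pt p.adjust
#'   shapiro.test t.test predict coef lm
#' @importFrom utils head read.delim write.table count.fields packageVersion
#' @importFrom graphics plot boxplot abline lines legend
"_PACKAGE"

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards so library code never disturbs user randomness.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Derive a stream of child seeds from one master seed (all < 2^31).
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

stop_mirscreen <- function(msg, class) {
  stop(structure(
    class = c(class, "mirscreen_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

check_scalar01 <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop_mirscreen(sprintf("'%s' must be a single number in [0, 1]", name),
                   "mirscreen_domain_error")
  }
  invisible(x)
}

# Row medians of a matrix (no matrixStats dependency); used on the
# probe x spot slices of raw arrays.
row_medians <- function(x) {
  apply(x, 1L, median)
}
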