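#' Positive predictive value under a given prevalence
#'
#' Bayes' rule for the post-test probability that a positive call is
#' correct: `sens * p / (sens * p + (1 - spec) * (1 - p))`. This is what
#' decides the fate of a screening test: a classifier with sensitivity
#' 86.7% and specificity 88.1% has a PPV of only ~0.3% at a
#' general-population prevalence of 4 in 10,000.
#'
#' @param sensitivity,specificity test characteristics in \[0, 1\].
#' @param prevalence disease prevalence in \[0, 1\].
#' @return The PPV in \[0, 1\].
#' @examples
#' ppv(0.867, 0.881, 4e-4)
#' @export
ppv <- function(sensitivity, specificity, prevalence) {
  check_scalar01(sensitivity, "sensitivity")
  check_scalar01(specificity, "specificity")
  check_scalar01(prevalence, "prevalence")
  denom <- sensitivity * prevalence + (1 - specificity) * (1 - prevalence)
  if (denom <= 0) {
    stop_mirscreen("PPV undefined: no positive calls at this operating point",
                   "mirscreen_undefined_value")
  }
  sensitivity * prevalence / denom
}

#' Negative predictive value under a given prevalence
#'
#' Bayes' rule for the post-test probability that a negative call is
#' correct: `spec * (1 - p) / (spec * (1 - p) + (1 - sens) * p)`.
#'
#' @inheritParams ppv
#' @return The NPV in \[0, 1\].
#' @examples
#' npv(0.867, 0.881, 0.015)
#' @export
npv <- function(sensitivity, specificity, prevalence) {
  check_scalar01(sensitivity, "sensitivity")
  check_scalar01(specificity, "specificity")
  check_scalar01(prevalence, "prevalence")
  denom <- specificity * (1 - prevalence) + (1 - sensitivity) * prevalence
  if (denom <= 0) {
    stop_mirscreen("NPV undefined: no negative calls at this operating point",
                   "mirscreen_undefined_value")
  }
  specificity * (1 - prevalence) / denom
}

#' Prevalence required to reach a target PPV
#'
#' Closed-form inversion of [ppv()] in the prevalence argument:
#' `p = t(1 - spec) / (sens(1 - t) + t(1 - spec))` for target `t`. Useful
#' for asking what risk population a screening test needs: e.g. how high
#' the prevalence must be (about 1.5%) before a sensitivity-86.7% /
#' specificity-88.1% test reaches a PPV of 10%.
#'
#' @inheritParams ppv
#' @param target_ppv desired PPV, in (0, 1).
#' @return The prevalence in \[0, 1\]; `ppv()` evaluated there returns the
#'   target to ~1e-15.
#' @examples
#' prevalence_for_ppv(0.867, 0.881, 0.10)
#' @export
prevalence_for_ppv <- function(sensitivity, specificity, target_ppv) {
  check_scalar01(sensitivity, "sensitivity")
  check_scalar01(specificity, "specificity")
  if (!is.numeric(target_ppv) || length(target_ppv) != 1L ||
      target_ppv <= 0 || target_ppv >= 1) {
    stop_mirscreen("target_ppv must lie strictly between 0 and 1",
                   "mirscreen_domain_error")
  }
  if (sensitivity <= 0) {
    stop_mirscreen("target PPV unreachable with zero sensitivity",
                   "mirscreen_domain_error")
  }
  if (specificity >= 1) {
    stop_mirscreen(
      "with perfect specificity the PPV is 1 at any positive prevalence; no finite inversion",
      "mirscreen_domain_error")
  }
  t <- target_ppv
  t * (1 - specificity) /
    (sensitivity * (1 - t) + t * (1 - specificity))
}

#' Bundle screening characteristics with their predictive values
#'
#' @inheritParams ppv
#' @return A list of class `screening_metrics` with the inputs and the
#'   derived `ppv` and `npv`.
#' @export
screening_metrics <- function(sensitivity, specificity, prevalence) {
  structure(
    list(sensitivity = sensitivity, specificity = specificity,
         prevalence = prevalence,
         ppv = ppv(sensitivity, specificity, prevalence),
         npv = npv(sensitivity, specificity, prevalence)),
    class = "screening_metrics"
  )
}

#' @export
print.screening_metrics <- function(x, ...) {
  cat("screening_metrics\n")
  cat(sprintf("  sensitivity %.1f%%, specificity %.1f%%, prevalence %.4g%%\n",
              100 * x$sensitivity, 100 * x$specificity, 100 * x$prevalence))
  cat(sprintf("  PPV %.2f%%, NPV %.2f%%\n", 100 * x$ppv, 100 * x$npv))
  invisible(x)
}
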