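#' Mediation proportion with delta-method confidence interval
#'
#' Two-step MR mediation: with total effect `beta0` (exposure to outcome),
#' `beta1` (exposure to mediator, log-odds scale for a binary mediator) and
#' `beta2` (mediator to outcome, adjusted for the exposure), the indirect
#' effect is `beta1 * beta2` and the proportion mediated is
#' `beta1 * beta2 / beta0`. The variance is propagated to first order under
#' independence of the three estimates (they come from non-overlapping
#' two-sample analyses):
#' `Var(ind) = beta1^2 * var2 + beta2^2 * var1` and
#' `Var(prop) = Var(ind)/beta0^2 + (ind^2/beta0^4) * var0`, the `var0` term
#' switchable off for the simpler variant that treats the total effect as
#' fixed. The interval is symmetric about the point estimate.
#'
#' @param beta1,var1 Exposure-to-mediator effect and its squared standard
#'   error.
#' @param beta2,var2 Mediator-to-outcome direct effect (exposure-adjusted)
#'   and its squared standard error.
#' @param beta0,var0 Total exposure-to-outcome effect and its squared
#'   standard error; `beta0` must be nonzero.
#' @param include_var0 Include the uncertainty of the total effect in the
#'   proportion variance (default `TRUE`).
#' @param conf_level Confidence level (default 0.95).
#' @return Object of class `mediation_ci`: list with `proportion`,
#'   `ci_low`, `ci_high`, `indirect`, `se_indirect`, `se_proportion`,
#'   `include_var0`, `conf_level`.
#' @examples
#' # A protective exposure whose harmful mediator carries part of the effect:
#' mediation_proportion(log(1.0729), 0.02^2, -0.1126, 0.042^2,
#'                      -0.0424, 0.016^2)
#' @export
mediation_proportion <- function(beta1, var1, beta2, var2, beta0, var0,
                                 include_var0 = TRUE, conf_level = 0.95) {
  if (!is.numeric(beta0) || beta0 == 0) {
    mr_abort("the mediation proportion is undefined when the total effect beta0 is zero",
             "mr_undefined_proportion")
  }
  if (any(c(var0, var1, var2) < 0)) {
    mr_abort("variances must be non-negative", "mr_domain_error")
  }
  indirect <- beta1 * beta2
  proportion <- indirect / beta0
  var_ind <- beta1^2 * var2 + beta2^2 * var1
  var_prop <- var_ind / beta0^2 +
    if (include_var0) indirect^2 / beta0^4 * var0 else 0
  q <- crit_quantile(conf_level)
  half <- q * sqrt(var_prop)
  structure(list(proportion = proportion,
                 ci_low = proportion - half, ci_high = proportion + half,
                 indirect = indirect, se_indirect = sqrt(var_ind),
                 se_proportion = sqrt(var_prop),
                 include_var0 = include_var0, conf_level = conf_level),
            class = "mediation_ci")
}

#' @export
print.mediation_ci <- function(x, ...) {
  cat(sprintf("Proportion mediated: %.2f%% (%.0f%% CI %.2f%%, %.2f%%); indirect effect %.4g\n",
              100 * x$proportion, 100 * x$conf_level, 100 * x$ci_low,
              100 * x$ci_high, x$indirect))
  invisible(x)
}

#' Bonferroni-adjusted significance threshold
#'
#' Divides `alpha` by the number of exposure-outcome comparisons.
#'
#' @param n_exposures,n_outcomes Positive integer counts of traits compared.
#' @param alpha Family-wise level (default 0.05).
#' @return The adjusted per-test threshold `alpha / (n_exposures * n_outcomes)`.
#' @export
bonferroni_threshold <- function(n_exposures, n_outcomes, alpha = 0.05) {
  if (!is_count(n_exposures) || !is_count(n_outcomes)) {
    mr_abort("n_exposures and n_outcomes must be positive integers", "mr_domain_error")
  }
  alpha / (n_exposures * n_outcomes)
}

# Interpret a reverse_mr_result for the unidirectionality criterion:
# pass when the back-effect is non-significant, or - with a caveat - when
# the trait had too few instruments for the reverse analysis to run.
.reverse_pass <- function(rev, alpha_reverse, label) {
  if (is.null(rev)) {
    return(list(pass = TRUE, note = sprintf("%s: reverse analysis not run", label)))
  }
  stopifnot(inherits(rev, "reverse_mr_result"))
  if (!rev$evaluable) {
    return(list(pass = TRUE,
                note = sprintf("%s: not evaluable (%s); counted as pass", label, rev$reason)))
  }
  p <- rev$primary$pvalue
  list(pass = p >= alpha_reverse,
       note = sprintf("%s: reverse p = %.3g", label, p))
}

#' Screen a candidate mediator
#'
#' Applies the three mediator-screening criteria: (1) unidirectionality —
#' no reverse causation from outcome to exposure nor from mediator to
#' exposure (a reverse analysis that is not evaluable for lack of
#' instruments counts as a pass, with a recorded caveat); (2) robustness to
#' adjustment — the mediator-to-outcome effect is significant both in
#' univariable MR and after exposure adjustment in multivariable MR;
#' (3) sign consistency — the indirect effect `beta1 * beta2` has the same
#' sign as the total effect `beta0`.
#'
#' @param reverse_outcome [reverse_mr()] result for outcome on exposure (or
#'   `NULL` if not run).
#' @param reverse_mediator [reverse_mr()] result for mediator on exposure.
#' @param uvmr_my_p Univariable mediator-to-outcome p-value.
#' @param mvmr_my_p Exposure-adjusted (MVMR) mediator-to-outcome p-value.
#' @param beta0,beta1,beta2 Total, exposure-to-mediator and adjusted
#'   mediator-to-outcome effects.
#' @param alpha_step Significance threshold for the step-1/step-2 effects
#'   (typically Bonferroni-adjusted; default 0.05).
#' @param alpha_reverse Threshold for the reverse-causation tests (default
#'   0.05).
#' @return Object of class `screen_verdict`: three pass/fail entries
#'   (`unidirectional`, `robust_to_adjustment`, `sign_consistent`, each with
#'   a reason) and `all_pass`.
#' @export
screen_mediator <- function(reverse_outcome, reverse_mediator,
                            uvmr_my_p, mvmr_my_p, beta0, beta1, beta2,
                            alpha_step = 0.05, alpha_reverse = 0.05) {
  r1 <- .reverse_pass(reverse_outcome, alpha_reverse, "outcome->exposure")
  r2 <- .reverse_pass(reverse_mediator, alpha_reverse, "mediator->exposure")
  unidirectional <- list(pass = r1$pass && r2$pass,
                         reason = paste(r1$note, r2$note, sep = "; "))
  robust <- list(
    pass = is.finite(uvmr_my_p) && is.finite(mvmr_my_p) &&
      uvmr_my_p < alpha_step && mvmr_my_p < alpha_step,
    reason = sprintf("mediator->outcome p: UVMR %.3g, MVMR %.3g (threshold %.3g)",
                     uvmr_my_p, mvmr_my_p, alpha_step))
  sign_ok <- list(pass = sign(beta1 * beta2) == sign(beta0),
                  reason = sprintf("sign(beta1*beta2) = %+d vs sign(beta0) = %+d",
                                   sign(beta1 * beta2), sign(beta0)))
  structure(list(unidirectional = unidirectional,
                 robust_to_adjustment = robust,
                 sign_consistent = sign_ok,
                 all_pass = unidirectional$pass && robust$pass && sign_ok$pass),
            class = "screen_verdict")
}

#' @export
print.screen_verdict <- function(x, ...) {
  for (nm in c("unidirectional", "robust_to_adjustment", "sign_consistent")) {
    cat(sprintf("%-21s %s  (%s)\n", nm,
                if (x[[nm]]$pass) "PASS" else "FAIL", x[[nm]]$reason))
  }
  invisible(x)
}
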