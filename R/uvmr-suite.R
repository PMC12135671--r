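#' Full univariable MR analysis with sensitivity diagnostics
#'
#' Runs IVW-FE, IVW-MRE, weighted median, MR-Egger (with intercept test),
#' Cochran's Q and, when at least 4 instruments are available, MR-PRESSO.
#' The primary method follows the heterogeneity rule: IVW-FE when the Q-test
#' p-value is at or above `q_alpha` (default 0.05), IVW-MRE otherwise. The
#' point estimate is unaffected by the switch; only the uncertainty widens.
#'
#' @inheritParams mr_ivw_fe
#' @param config Optional list overriding defaults: `q_alpha` (0.05),
#'   `n_boot` (1000), `n_sim` (1000), `outlier_alpha` (0.05), `seed` (1),
#'   `exponentiate` (FALSE), `run_presso` (TRUE).
#' @return Object of class `uvmr_result`: list with `estimates` (named list
#'   of `mr_estimate`s), `table` (one row per method), `heterogeneity`
#'   (`Q`, `df`, `pvalue`, `egger_intercept`, `egger_intercept_se`,
#'   `egger_intercept_p`), `presso`, `primary` (label), `primary_estimate`.
#' @export
uvmr_suite <- function(h, config = list(), exposure = NULL, outcome = NULL) {
  cfg <- utils::modifyList(list(q_alpha = 0.05, n_boot = 1000, n_sim = 1000,
                                outlier_alpha = 0.05, seed = 1,
                                exponentiate = FALSE, run_presso = TRUE),
                           config)
  fe <- mr_ivw_fe(h, exposure, outcome, cfg$exponentiate)
  q <- cochran_q(h, beta = fe$beta, exposure = exposure, outcome = outcome)
  # With only 2 instruments the MRE/Egger/median estimators are undefined;
  # report the fixed-effect analysis alone.
  few <- fe$n_snps < 3L
  mre <- if (few) NULL else mr_ivw_mre(h, exposure, outcome, cfg$exponentiate)
  egger <- if (few) NULL else mr_egger(h, exposure, outcome, cfg$exponentiate)
  wm <- if (few) NULL else {
    mr_weighted_median(h, n_boot = cfg$n_boot, seed = cfg$seed,
                       exposure = exposure, outcome = outcome,
                       exponentiate = cfg$exponentiate)
  }
  presso <- NULL
  if (isTRUE(cfg$run_presso) && fe$n_snps >= 4L) {
    presso <- mr_presso(h, n_sim = cfg$n_sim, outlier_alpha = cfg$outlier_alpha,
                        seed = cfg$seed, exposure = exposure, outcome = outcome,
                        exponentiate = cfg$exponentiate, q_alpha = cfg$q_alpha)
  }
  heterogeneity <- structure(list(
    Q = q$Q, df = q$df, pvalue = q$pvalue,
    egger_intercept = if (few) NA_real_ else egger$intercept$estimate,
    egger_intercept_se = if (few) NA_real_ else egger$intercept$se,
    egger_intercept_p = if (few) NA_real_ else egger$intercept$pvalue
  ), class = "heterogeneity_report")
  primary <- if (q$pvalue < cfg$q_alpha && !few) "IVW-MRE" else "IVW-FE"
  estimates <- if (few) list(`IVW-FE` = fe) else {
    list(`IVW-FE` = fe, `IVW-MRE` = mre,
         WeightedMedian = wm, MREgger = egger$estimate)
  }
  if (!is.null(presso$corrected)) estimates$`MRPRESSO-corrected` <- presso$corrected
  tab <- do.call(rbind, lapply(estimates, as.data.frame))
  rownames(tab) <- NULL
  structure(list(estimates = estimates, table = tab,
                 heterogeneity = heterogeneity, presso = presso,
                 primary = primary, primary_estimate = estimates[[primary]],
                 n_snps = fe$n_snps, config = cfg),
            class = "uvmr_result")
}

#' @export
print.uvmr_result <- function(x, ...) {
  cat(sprintf("Univariable MR (%d SNPs), primary method: %s\n", x$n_snps, x$primary))
  print(x$table, row.names = FALSE, digits = 4)
  h <- x$heterogeneity
  cat(sprintf("Cochran Q = %.2f (df %d, p = %.3g); Egger intercept = %.4f (p = %.3g)\n",
              h$Q, h$df, h$pvalue, h$egger_intercept, h$egger_intercept_p))
  if (!is.null(x$presso)) {
    cat(sprintf("MR-PRESSO global p = %.4g, %d outlier(s)\n",
                x$presso$global_p, length(x$presso$outliers)))
  }
  invisible(x)
}

#' Reverse-direction MR screen
#'
#' Assesses reverse causation by swapping the roles: instruments are
#' selected for the original outcome trait and its causal effect on the
#' original exposure is estimated with the full univariable suite. When the
#' outcome trait has fewer than two genome-wide-significant instruments
#' after selection, the check is reported as not evaluable rather than
#' failing.
#'
#' @param outcome_stats Summary statistics of the trait whose back-effect is
#'   being tested (instruments are selected from these).
#' @param exposure_stats Summary statistics of the original exposure (now
#'   playing the outcome role).
#' @param ld An [ld_matrix()] or `NULL`.
#' @param config Passed to [uvmr_suite()].
#' @param palindrome_policy,eaf_window Passed to [harmonize()].
#' @param ... Selection thresholds passed to [select_instruments()].
#' @return Object of class `reverse_mr_result`: either
#'   `list(evaluable = FALSE, reason = ...)` or `list(evaluable = TRUE,
#'   suite = <uvmr_result>, primary = <mr_estimate>)`.
#' @export
reverse_mr <- function(outcome_stats, exposure_stats, ld = NULL, config = list(),
                       palindrome_policy = "drop-all", eaf_window = 0.08, ...) {
  not_evaluable <- function(reason) {
    structure(list(evaluable = FALSE, reason = reason), class = "reverse_mr_result")
  }
  sel <- tryCatch(select_instruments(outcome_stats, ld, ...),
                  mr_no_instruments = function(e) NULL)
  if (is.null(sel) || length(sel$snps) < 2L) {
    return(not_evaluable("fewer than 2 genome-wide-significant instruments for the outcome trait"))
  }
  h <- tryCatch(
    harmonize(list(outcome = sel$data, exposure = exposure_stats),
              palindrome_policy = palindrome_policy, eaf_window = eaf_window),
    mr_harmonization_error = function(e) NULL)
  if (is.null(h) || nrow(h$data) < 2L) {
    return(not_evaluable("fewer than 2 instruments shared with the exposure dataset after harmonization"))
  }
  suite <- uvmr_suite(h, config, exposure = "outcome", outcome = "exposure")
  structure(list(evaluable = TRUE, suite = suite,
                 primary = suite$primary_estimate),
            class = "reverse_mr_result")
}

#' @export
print.reverse_mr_result <- function(x, ...) {
  if (!x$evaluable) {
    cat("Reverse MR: not evaluable —", x$reason, "\n")
  } else {
    cat("Reverse MR primary estimate:\n")
    print(x$primary)
  }
  invisible(x)
}
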