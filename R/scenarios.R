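# Frozen study scenarios for validation and examples.  Effect sizes and
# sample sizes mirror the lipid-exposure / bone-density / cardiovascular
# setting the package is built around: a per-SD protective total effect of
# about -0.04 on the continuous outcome, a binary mediator with a log-odds
# exposure effect of about 0.07 and a true mediation proportion of 0.19.

.SCENARIOS <- list(
  "apoB-tbbmd" = list(
    n_snps = 200, theta_total = -0.04, het_multiplier = 1.5
  ),
  "apoB-hf-tbbmd-mediation" = list(
    n_snps = 180, n_med_snps = 160, theta_total = -0.04,
    theta_xm = 0.0703, theta_my = 0.19 * (-0.04) / 0.0703,  # proportion 0.19
    het_multiplier = 1.5
  ),
  "null" = list(
    n_snps = 100, ld_block_size = 1, theta_total = 0,
    palindrome_frac = 0, swap_frac = 0
  ),
  "directional-pleiotropy" = list(
    n_snps = 100, ld_block_size = 1, theta_total = -0.04,
    pleiotropy_frac = 1, pleiotropy_mean = 0.02, pleiotropy_sd = 0.01,
    palindrome_frac = 0, swap_frac = 0
  ),
  "outlier-contaminated" = list(
    n_snps = 100, ld_block_size = 1, theta_total = -0.04, n_outliers = 3,
    palindrome_frac = 0, swap_frac = 0
  ),
  "bidirectional" = list(
    n_snps = 150, n_rev_snps = 150, ld_block_size = 1,
    theta_total = -0.04, theta_rev = -0.01,
    palindrome_frac = 0, swap_frac = 0
  )
)

#' Frozen simulation scenarios
#'
#' Returns the [sim_config()] for a named scenario from the registry:
#' `"apoB-tbbmd"` (protective exposure with heterogeneity),
#' `"apoB-hf-tbbmd-mediation"` (binary mediator carrying a true mediation
#' proportion of 0.19), `"null"` (no causal effects),
#' `"directional-pleiotropy"` (every instrument has a direct outcome effect
#' of mean 0.02), `"outlier-contaminated"` (3 gross outliers among 100
#' loci), and `"bidirectional"` (outcome feeds back on the exposure).
#'
#' @param name Scenario name; see [scenario_names()].
#' @param seed Integer seed placed in the returned configuration.
#' @return A `sim_config`.
#' @export
mr_scenario <- function(name, seed = 1) {
  if (!is.character(name) || length(name) != 1L || !name %in% names(.SCENARIOS)) {
    mr_abort(sprintf("unknown scenario '%s'; available: %s", name,
                     paste(names(.SCENARIOS), collapse = ", ")),
             "mr_lookup_error")
  }
  do.call(sim_config, c(.SCENARIOS[[name]], list(seed = seed)))
}

#' @rdname mr_scenario
#' @export
scenario_names <- function() names(.SCENARIOS)
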