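#' MR-PRESSO: pleiotropy residual sum and outlier test
#'
#' Detects outlier SNPs whose outcome effects deviate from what the
#' remaining instruments predict. The observed global statistic is
#' `RSS = sum_j (beta_Yj - bhat_(-j) * beta_Xj)^2 / SE_Yj^2`, where
#' `bhat_(-j)` is the leave-one-out IVW estimate. Its null distribution is
#' built by parametric simulation: `beta*_Xj ~ Normal(beta_Xj, SE_Xj)` and
#' `beta*_Yj ~ Normal(bhat_(-j) * beta_Xj, SE_Yj)`, recomputing the
#' statistic each time. The global p-value is
#' `(1 + #\{RSS* >= RSS_obs\}) / (n_sim + 1)`. Each SNP's observed
#' contribution is referred to its own simulated distribution and flagged as
#' an outlier when its empirical p-value falls below the
#' Bonferroni-adjusted threshold `outlier_alpha / L`; the IVW estimate is
#' then recomputed without the flagged SNPs (`corrected`, using the same
#' heterogeneity rule as [uvmr_suite()]). The distortion test is not
#' implemented.
#'
#' Note the per-SNP empirical p-value cannot fall below `1/(n_sim + 1)`:
#' resolving the Bonferroni threshold requires `n_sim >= L/outlier_alpha`,
#' and a warning is raised when `n_sim` is too small for any SNP to be
#' flaggable.
#'
#' @inheritParams mr_ivw_fe
#' @param n_sim Number of parametric simulations (at least 100; default
#'   1000).
#' @param outlier_alpha Significance level for the per-SNP outlier test
#'   before Bonferroni adjustment (default 0.05).
#' @param seed Integer seed for the simulations.
#' @param q_alpha Heterogeneity-test level used when re-estimating the
#'   corrected effect (default 0.05).
#' @return Object of class `presso_result`: list with `global_p`,
#'   `rss_obs`, `outliers` (SNP ids), `outlier_p` (named per-SNP empirical
#'   p-values), `corrected` (an `mr_estimate` on the outlier-free set),
#'   `n_sim`, `outlier_alpha`, `seed`.
#' @export
mr_presso <- function(h, n_sim = 1000, outlier_alpha = 0.05, seed = 1,
                      exposure = NULL, outcome = NULL, exponentiate = FALSE,
                      q_alpha = 0.05) {
  if (!is_count(n_sim) || n_sim < 100) {
    mr_abort("n_sim must be an integer of at least 100", "mr_config_error")
  }
  p <- hs_xy(h, exposure, outcome)
  keep <- p$bx != 0
  snp <- p$snp[keep]
  bx <- p$bx[keep]; sx <- p$sx[keep]; by <- p$by[keep]; sy <- p$sy[keep]
  L <- length(bx)
  if (L < 4L) mr_abort("MR-PRESSO needs at least 4 SNPs", "mr_estimation_error")
  if (n_sim < L / outlier_alpha) {
    warning(sprintf(paste0("n_sim = %d cannot resolve the Bonferroni-adjusted ",
                           "outlier threshold %.2g/%d; no SNP can be flagged. ",
                           "Use n_sim >= %d."),
                    n_sim, outlier_alpha, L, ceiling(L / outlier_alpha)),
            call. = FALSE)
  }

  a <- bx * by / sy^2
  b <- bx^2 / sy^2
  b_loo <- (sum(a) - a) / (sum(b) - b)   # leave-one-out IVW estimates
  d_obs <- (by - b_loo * bx)^2 / sy^2
  rss_obs <- sum(d_obs)

  sims <- with_seed(seed, {
    BX <- matrix(stats::rnorm(L * n_sim, mean = bx, sd = sx), nrow = L)
    BY <- matrix(stats::rnorm(L * n_sim, mean = b_loo * bx, sd = sy), nrow = L)
    A <- BX * BY / sy^2
    B <- BX^2 / sy^2
    BL <- sweep(-A, 2, colSums(A), `+`) / sweep(-B, 2, colSums(B), `+`)
    D <- (BY - BL * BX)^2 / sy^2
    list(rss = colSums(D), exceed = rowSums(D >= d_obs))
  })

  global_p <- (1 + sum(sims$rss >= rss_obs)) / (n_sim + 1)
  outlier_p <- stats::setNames((1 + sims$exceed) / (n_sim + 1), snp)
  outliers <- snp[outlier_p < outlier_alpha / L]

  clean <- subset_harmonized(h, setdiff(p$snp, outliers))
  corrected <- tryCatch({
    q <- cochran_q(clean, exposure = exposure, outcome = outcome)
    if (q$pvalue < q_alpha && nrow(clean$data) >= 3L) {
      mr_ivw_mre(clean, exposure, outcome, exponentiate)
    } else {
      mr_ivw_fe(clean, exposure, outcome, exponentiate)
    }
  }, mr_estimation_error = function(e) NULL)
  if (!is.null(corrected)) corrected$method <- "MRPRESSO-corrected"

  structure(list(global_p = global_p, rss_obs = rss_obs, outliers = outliers,
                 outlier_p = outlier_p, corrected = corrected,
                 n_sim = n_sim, outlier_alpha = outlier_alpha, seed = seed),
            class = "presso_result")
}

#' @export
print.presso_result <- function(x, ...) {
  cat(sprintf("MR-PRESSO: global p = %.4g (%d simulations), %d outlier(s)%s\n",
              x$global_p, x$n_sim, length(x$outliers),
              if (length(x$outliers)) paste0(": ", paste(x$outliers, collapse = ", "))
              else ""))
  if (!is.null(x$corrected)) print(x$corrected)
  invisible(x)
}
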