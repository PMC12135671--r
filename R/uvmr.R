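# Univariable two-sample MR estimators on a harmonized exposure/outcome set.
#
# All estimators work from the per-SNP effect pairs (beta_X, SE_X, beta_Y,
# SE_Y).  Weights are first-order: the Wald-ratio se is SE_Yj/|beta_Xj|, so
# the IVW weight is beta_Xj^2/SE_Yj^2 and the IVW estimate coincides with a
# zero-intercept weighted regression of beta_Y on beta_X with weights
# 1/SE_Yj^2.

# Extract aligned exposure/outcome vectors from a harmonized_set.
hs_xy <- function(h, exposure = NULL, outcome = NULL) {
  stopifnot(inherits(h, "harmonized_set"))
  exposure <- exposure %||% h$roles[1]
  outcome <- outcome %||% h$roles[length(h$roles)]
  d <- h$data
  for (r in c(exposure, outcome)) {
    if (is.null(d[[paste0("beta_", r)]])) {
      mr_abort(sprintf("role '%s' not present in the harmonized set", r),
               "mr_input_error")
    }
  }
  list(snp = d$snp_id,
       bx = d[[paste0("beta_", exposure)]],
       sx = d[[paste0("se_", exposure)]],
       by = d[[paste0("beta_", outcome)]],
       sy = d[[paste0("se_", outcome)]])
}

# Shared constructor for method results.
make_estimate <- function(method, beta, se, n_snps, df = NULL,
                          exponentiate = FALSE, conf_level = 0.95) {
  q <- crit_quantile(conf_level, df)
  est <- list(method = method, beta = beta, se = se,
              ci_low = beta - q * se, ci_high = beta + q * se,
              pvalue = two_sided_p(beta, se, df), n_snps = n_snps,
              df = df, conf_level = conf_level)
  if (exponentiate) {
    est$or <- exp(beta)
    est$or_ci_low <- exp(est$ci_low)
    est$or_ci_high <- exp(est$ci_high)
  }
  structure(est, class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, digits = 4, ...) {
  cat(sprintf("%s: beta = %.*f (95%% CI %.*f, %.*f), se = %.*f, p = %.3g, nSNP = %d\n",
              x$method, digits, x$beta, digits, x$ci_low, digits, x$ci_high,
              digits, x$se, x$pvalue, x$n_snps))
  if (!is.null(x$or)) {
    cat(sprintf("  OR = %.*f (95%% CI %.*f, %.*f)\n", digits, x$or,
                digits, x$or_ci_low, digits, x$or_ci_high))
  }
  invisible(x)
}

#' @export
as.data.frame.mr_estimate <- function(x, ...) {
  data.frame(method = x$method, n_snp = x$n_snps, beta = x$beta, se = x$se,
             ci_low = x$ci_low, ci_high = x$ci_high, pvalue = x$pvalue,
             or = x$or %||% NA_real_, or_ci_low = x$or_ci_low %||% NA_real_,
             or_ci_high = x$or_ci_high %||% NA_real_, stringsAsFactors = FALSE)
}

#' Per-SNP Wald ratio estimates
#'
#' `ratio_j = beta_Yj / beta_Xj` with first-order standard error
#' `SE_Yj / |beta_Xj|`. SNPs with a zero exposure effect are excluded with a
#' warning (their ratio is undefined).
#'
#' @param h A `harmonized_set`.
#' @param exposure,outcome Role names; default to the first and last role.
#' @return Data frame with `snp_id`, `ratio`, `ratio_se`.
#' @export
ratio_estimates <- function(h, exposure = NULL, outcome = NULL) {
  p <- hs_xy(h, exposure, outcome)
  bad <- p$bx == 0
  if (any(bad)) {
    warning(sprintf("%d SNP(s) with zero exposure effect excluded from ratio estimates",
                    sum(bad)), call. = FALSE)
  }
  data.frame(snp_id = p$snp[!bad], ratio = p$by[!bad] / p$bx[!bad],
             ratio_se = p$sy[!bad] / abs(p$bx[!bad]), stringsAsFactors = FALSE)
}

# Core IVW quantities (shared by FE/MRE/Q).
.ivw_core <- function(p) {
  keep <- p$bx != 0
  bx <- p$bx[keep]; by <- p$by[keep]; sy <- p$sy[keep]
  w <- bx^2 / sy^2              # 1 / ratio_se^2
  ratio <- by / bx
  sw <- sum(w)
  beta <- sum(w * ratio) / sw
  list(beta = beta, se_fe = 1 / sqrt(sw), w = w, ratio = ratio,
       L = length(ratio))
}

#' Fixed-effect inverse-variance-weighted estimate
#'
#' Meta-analyzes the per-SNP Wald ratios with weights `1/ratio_se^2`
#' (equivalently, a zero-intercept weighted regression of outcome on
#' exposure effects with weights `1/SE_Y^2`). Assumes all instruments
#' estimate one common causal effect.
#'
#' @inheritParams ratio_estimates
#' @param exponentiate Report an odds-ratio scale alongside (for binary
#'   outcomes).
#' @return An `mr_estimate` labelled `"IVW-FE"`.
#' @export
mr_ivw_fe <- function(h, exposure = NULL, outcome = NULL, exponentiate = FALSE) {
  p <- hs_xy(h, exposure, outcome)
  core <- .ivw_core(p)
  if (core$L < 2L) {
    mr_abort("IVW needs at least 2 SNPs with nonzero exposure effects",
             "mr_estimation_error")
  }
  make_estimate("IVW-FE", core$beta, core$se_fe, core$L,
                exponentiate = exponentiate)
}

#' Cochran's Q heterogeneity test
#'
#' `Q = sum w_j (ratio_j - beta)^2` with `w_j = 1/ratio_se_j^2`, referred to
#' a chi-square distribution with `L - 1` degrees of freedom. Large Q means
#' the per-SNP ratios disagree beyond their sampling error.
#'
#' @inheritParams ratio_estimates
#' @param beta Pooled estimate to measure dispersion around; defaults to the
#'   IVW-FE estimate.
#' @return List with `Q`, `df`, `pvalue` (class `cochran_q`).
#' @export
cochran_q <- function(h, beta = NULL, exposure = NULL, outcome = NULL) {
  p <- hs_xy(h, exposure, outcome)
  core <- .ivw_core(p)
  if (core$L < 2L) mr_abort("Cochran's Q needs at least 2 SNPs", "mr_estimation_error")
  beta <- beta %||% core$beta
  Q <- sum(core$w * (core$ratio - beta)^2)
  df <- core$L - 1L
  structure(list(Q = Q, df = df,
                 pvalue = stats::pchisq(Q, df, lower.tail = FALSE)),
            class = "cochran_q")
}

#' Multiplicative-random-effects IVW estimate
#'
#' Identical point estimate to [mr_ivw_fe()]; the standard error is
#' inflated by the overdispersion factor `max(1, sqrt(Q/(L-1)))`, so under
#' homogeneity (Q at or below its degrees of freedom) the result equals the
#' fixed-effect one and the confidence interval never shrinks below it.
#'
#' @inheritParams mr_ivw_fe
#' @return An `mr_estimate` labelled `"IVW-MRE"`.
#' @export
mr_ivw_mre <- function(h, exposure = NULL, outcome = NULL, exponentiate = FALSE) {
  p <- hs_xy(h, exposure, outcome)
  core <- .ivw_core(p)
  if (core$L < 3L) {
    mr_abort("IVW-MRE needs at least 3 SNPs", "mr_estimation_error")
  }
  Q <- sum(core$w * (core$ratio - core$beta)^2)
  infl <- max(1, sqrt(Q / (core$L - 1)))
  make_estimate("IVW-MRE", core$beta, core$se_fe * infl, core$L,
                exponentiate = exponentiate)
}

#' MR-Egger regression
#'
#' Weighted regression of outcome effects on exposure effects with a free
#' intercept (`beta_Yj = alpha + beta * beta_Xj`, weights `1/SE_Yj^2`). The
#' slope is the causal estimate under the InSIDE assumption; a nonzero
#' intercept indicates directional pleiotropy. Because the fit is not
#' invariant to per-SNP allele orientation, exposure effects are oriented
#' non-negative before fitting. Slope and intercept standard errors carry
#' the multiplicative overdispersion factor `max(1, sqrt(RSS/(L-2)))`, and
#' inference uses the t distribution with `L - 2` degrees of freedom.
#'
#' @inheritParams mr_ivw_fe
#' @return List of class `mr_egger_result` with elements `estimate` (an
#'   `mr_estimate` labelled `"MREgger"`) and `intercept` (list with
#'   `estimate`, `se`, `pvalue`, `df`).
#' @export
mr_egger <- function(h, exposure = NULL, outcome = NULL, exponentiate = FALSE) {
  p <- hs_xy(h, exposure, outcome)
  L <- length(p$bx)
  if (L < 3L) mr_abort("MR-Egger needs at least 3 SNPs", "mr_estimation_error")
  flip <- p$bx < 0
  bx <- ifelse(flip, -p$bx, p$bx)
  by <- ifelse(flip, -p$by, p$by)
  w <- 1 / p$sy^2
  sw <- sum(w); swx <- sum(w * bx); swy <- sum(w * by)
  swxx <- sum(w * bx^2); swxy <- sum(w * bx * by)
  den <- sw * swxx - swx^2
  if (den <= .Machine$double.eps * sw * swxx) {
    mr_abort("exposure effects have no spread; Egger slope is unidentified",
             "mr_estimation_error")
  }
  slope <- (sw * swxy - swx * swy) / den
  alpha <- (swxx * swy - swx * swxy) / den
  rss <- sum(w * (by - alpha - slope * bx)^2)
  infl <- max(1, sqrt(rss / (L - 2)))
  se_slope <- sqrt(sw / den) * infl
  se_alpha <- sqrt(swxx / den) * infl
  structure(list(
    estimate = make_estimate("MREgger", slope, se_slope, L, df = L - 2L,
                             exponentiate = exponentiate),
    intercept = list(estimate = alpha, se = se_alpha,
                     pvalue = two_sided_p(alpha, se_alpha, df = L - 2L),
                     df = L - 2L)
  ), class = "mr_egger_result")
}

# Interpolated weighted median of `b` with weights `w`.
.weighted_median <- function(b, w) {
  o <- order(b)
  b <- b[o]
  w <- w[o] / sum(w)
  s <- cumsum(w) - w / 2
  if (s[1] >= 0.5) return(b[1])
  if (s[length(s)] <= 0.5) return(b[length(b)])
  k <- max(which(s < 0.5))
  b[k] + (b[k + 1] - b[k]) * (0.5 - s[k]) / (s[k + 1] - s[k])
}

#' Weighted-median estimate
#'
#' The inverse-variance weighted median of the per-SNP Wald ratios:
#' consistent as long as at least half of the weight comes from valid
#' instruments, which makes it robust to a minority of pleiotropic SNPs.
#' The standard error comes from a parametric bootstrap (each ratio is
#' resampled from `Normal(ratio_j, ratio_se_j)` and the median recomputed).
#'
#' @inheritParams mr_ivw_fe
#' @param n_boot Bootstrap replicates (default 1000).
#' @param seed Integer seed for the bootstrap (the caller's RNG state is
#'   left untouched).
#' @return An `mr_estimate` labelled `"WeightedMedian"`.
#' @export
mr_weighted_median <- function(h, n_boot = 1000, seed = 1,
                               exposure = NULL, outcome = NULL,
                               exponentiate = FALSE) {
  p <- hs_xy(h, exposure, outcome)
  core <- .ivw_core(p)
  if (core$L < 3L) {
    mr_abort("the weighted median needs at least 3 SNPs", "mr_estimation_error")
  }
  beta <- .weighted_median(core$ratio, core$w)
  ratio_se <- 1 / sqrt(core$w)
  boots <- with_seed(seed, {
    draws <- matrix(stats::rnorm(core$L * n_boot, mean = core$ratio, sd = ratio_se),
                    nrow = core$L)
    apply(draws, 2, .weighted_median, w = core$w)
  })
  est <- make_estimate("WeightedMedian", beta, stats::sd(boots), core$L,
                       exponentiate = exponentiate)
  est$n_boot <- n_boot
  est$seed <- seed
  est
}
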