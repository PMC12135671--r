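#' Select instruments for multivariable MR
#'
#' Takes the union of each exposure's genome-wide-significant SNPs,
#' restricts it to SNPs present in every supplied dataset (all exposures
#' and, when given, the outcome), clumps the pooled candidates jointly on
#' the lowest p-value across exposures, and applies the weak-instrument
#' filter using each SNP's strongest exposure association.
#'
#' @param exposure_stats Named list (length at least 2) of summary-statistics
#'   data frames, one per exposure.
#' @param ld An [ld_matrix()] or `NULL`.
#' @param outcome_stats Optional outcome summary statistics; when given,
#'   instruments must also be present there.
#' @inheritParams select_instruments
#' @return An `instrument_set`; its `data` element holds the rows of the
#'   first exposure's dataset for the selected SNPs.
#' @export
select_mvmr_instruments <- function(exposure_stats, ld = NULL,
                                    outcome_stats = NULL, p_threshold = 5e-8,
                                    r2_threshold = 0.001, window_kb = 10000,
                                    f_threshold = 10, strict = FALSE) {
  if (!is.list(exposure_stats) || length(exposure_stats) < 2L) {
    mr_abort("select_mvmr_instruments() needs at least 2 exposures",
             "mr_input_error")
  }
  k <- length(exposure_stats)
  gws <- lapply(exposure_stats, filter_genomewide, p_threshold = p_threshold)
  union_ids <- unique(unlist(lapply(gws, `[[`, "snp_id")))
  present <- lapply(exposure_stats, `[[`, "snp_id")
  if (!is.null(outcome_stats)) present <- c(present, list(outcome_stats$snp_id))
  union_ids <- Reduce(function(acc, ids) acc[acc %in% ids], present, init = union_ids)
  if (length(union_ids) == 0L) {
    mr_abort("no genome-wide-significant SNP is present in every dataset",
             "mr_no_instruments")
  }
  # Pooled candidate list: position from the first exposure carrying the SNP,
  # p-value and F from the exposure with the strongest association.
  pmat <- vapply(exposure_stats, function(s) {
    s$pvalue[match(union_ids, s$snp_id)]
  }, numeric(length(union_ids)))
  pmat <- matrix(pmat, nrow = length(union_ids))
  fmat <- vapply(exposure_stats, function(s) {
    i <- match(union_ids, s$snp_id)
    (s$beta[i] / s$se[i])^2
  }, numeric(length(union_ids)))
  fmat <- matrix(fmat, nrow = length(union_ids))
  first <- exposure_stats[[1]]
  loc <- match(union_ids, first$snp_id)
  cand <- data.frame(snp_id = union_ids,
                     chrom = first$chrom[loc], pos = first$pos[loc],
                     pvalue = apply(pmat, 1, min, na.rm = TRUE),
                     stringsAsFactors = FALSE)
  idx <- clump(cand, ld, r2_threshold = r2_threshold, window_kb = window_kb,
               strict = strict)
  f <- apply(fmat, 1, max, na.rm = TRUE)[match(idx, union_ids)]
  kept <- idx[f >= f_threshold]
  if (length(kept) < k + 1L) {
    mr_abort(sprintf("only %d joint instrument(s) remain; need at least %d (exposures + 1)",
                     length(kept), k + 1L), "mr_no_instruments")
  }
  structure(list(snps = kept,
                 f_stats = stats::setNames(f[f >= f_threshold], kept),
                 thresholds = list(p_threshold = p_threshold,
                                   r2_threshold = r2_threshold,
                                   window_kb = window_kb,
                                   f_threshold = f_threshold),
                 drops = c(not_significant = NA_integer_,
                           ld_pruned = length(union_ids) - length(idx),
                           weak = length(idx) - length(kept)),
                 data = first[match(kept, first$snp_id), , drop = FALSE]),
            class = "instrument_set")
}

#' Multivariable MR by inverse-variance weighting
#'
#' Jointly regresses the outcome effects on the matrix of exposure effects
#' without an intercept, with weights `1/SE_Y^2`, giving each exposure's
#' direct effect conditional on the others. Standard errors come from the
#' weighted-regression covariance inflated by the multiplicative
#' overdispersion factor `max(1, sqrt(RSS/(L-k)))`, mirroring the
#' heterogeneity treatment of the univariable estimators.
#'
#' An exposure whose effects are identically zero carries no information and
#' is reported as `NA`; a rank-deficient (collinear) exposure matrix is an
#' error naming the offending exposures.
#'
#' @param h A `harmonized_set` whose roles are the exposures followed by the
#'   outcome (last role).
#' @param exposures Character vector of exposure roles (default: all roles
#'   but the last).
#' @param outcome Outcome role (default: last role).
#' @return Object of class `mvmr_result`: list with `exposures`, `betas`,
#'   `ses`, `ci_low`, `ci_high`, `pvalues` (all named per exposure),
#'   `n_snps`, `overdispersion`, `excluded` (all-zero exposures), `table`.
#'   `conditional_f` is reserved and currently `NULL`.
#' @export
mvmr_ivw <- function(h, exposures = NULL, outcome = NULL) {
  stopifnot(inherits(h, "harmonized_set"))
  exposures <- exposures %||% h$roles[-length(h$roles)]
  outcome <- outcome %||% h$roles[length(h$roles)]
  d <- h$data
  X <- vapply(exposures, function(r) d[[paste0("beta_", r)]], numeric(nrow(d)))
  X <- matrix(X, nrow = nrow(d), dimnames = list(NULL, exposures))
  y <- d[[paste0("beta_", outcome)]]
  sy <- d[[paste0("se_", outcome)]]
  w <- 1 / sy^2
  L <- nrow(X)

  zero <- colSums(X != 0) == 0L
  act <- exposures[!zero]
  Xa <- X[, !zero, drop = FALSE]
  k <- ncol(Xa)
  if (k == 0L) mr_abort("all exposure effect columns are zero", "mr_estimation_error")
  if (L < k + 1L) {
    mr_abort(sprintf("MVMR needs at least %d SNPs for %d exposure(s); got %d",
                     k + 1L, k, L), "mr_estimation_error")
  }
  qrX <- qr(sqrt(w) * Xa)
  if (qrX$rank < k) {
    dep <- act[qrX$pivot[seq.int(qrX$rank + 1L, k)]]
    mr_abort(sprintf("collinear exposure effects; offending exposure(s): %s",
                     paste(dep, collapse = ", ")), "mr_collinearity_error")
  }
  XtWX <- crossprod(Xa, w * Xa)
  bhat <- drop(solve(XtWX, crossprod(Xa, w * y)))
  rss <- sum(w * (y - drop(Xa %*% bhat))^2)
  infl <- max(1, sqrt(rss / (L - k)))
  se <- sqrt(diag(solve(XtWX))) * infl

  full <- function(v) {
    out <- stats::setNames(rep(NA_real_, length(exposures)), exposures)
    out[act] <- v
    out
  }
  q <- stats::qnorm(0.975)
  betas <- full(bhat); ses <- full(se)
  res <- structure(list(exposures = exposures, betas = betas, ses = ses,
                        ci_low = betas - q * ses, ci_high = betas + q * ses,
                        pvalues = 2 * stats::pnorm(-abs(betas / ses)),
                        n_snps = L, overdispersion = infl,
                        excluded = exposures[zero], conditional_f = NULL),
                   class = "mvmr_result")
  res$table <- data.frame(exposure = exposures, n_snp = L, beta = betas,
                          se = ses, ci_low = res$ci_low, ci_high = res$ci_high,
                          pvalue = res$pvalues, row.names = NULL,
                          stringsAsFactors = FALSE)
  res
}

#' @export
print.mvmr_result <- function(x, ...) {
  cat(sprintf("Multivariable MR (IVW), %d SNPs, overdispersion factor %.3f\n",
              x$n_snps, x$overdispersion))
  print(x$table, row.names = FALSE, digits = 4)
  if (length(x$excluded)) {
    cat("Excluded (all-zero effects):", paste(x$excluded, collapse = ", "), "\n")
  }
  invisible(x)
}
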