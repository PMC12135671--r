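#' Genome-wide significance filter
#'
#' Retains exactly the records with `pvalue <= p_threshold`, preserving the
#' input order. The conventional genome-wide threshold is 5e-8.
#'
#' @param stats Summary-statistics data frame (canonical columns).
#' @param p_threshold Significance level in (0, 1); default `5e-8`.
#' @return The retained rows of `stats`.
#' @export
filter_genomewide <- function(stats, p_threshold = 5e-8) {
  if (!is.numeric(p_threshold) || length(p_threshold) != 1L ||
      p_threshold <= 0 || p_threshold >= 1) {
    mr_abort("p_threshold must be a single number in (0, 1)", "mr_config_error")
  }
  out <- stats[stats$pvalue <= p_threshold, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Greedy LD clumping
#'
#' Repeatedly takes the lowest-p unclaimed candidate as an index SNP and
#' discards all unclaimed candidates on the same chromosome within
#' `window_kb` kilobases whose r-squared with the index exceeds
#' `r2_threshold`. Ties on p-value are broken by ascending chromosome,
#' position, then SNP id, so the selection is deterministic.
#'
#' @param candidates Data frame with at least `snp_id`, `chrom`, `pos`,
#'   `pvalue`.
#' @param ld An [ld_matrix()] (or `NULL`: all candidates unlinked).
#' @param r2_threshold r-squared cutoff in (0, 1); default 0.001.
#' @param window_kb Clumping window in kilobases; default 10000.
#' @param strict If `TRUE`, a candidate absent from `ld` is an error;
#'   otherwise such candidates are assumed unlinked with a warning.
#' @return Character vector of index SNP ids in selection order.
#' @export
clump <- function(candidates, ld = NULL, r2_threshold = 0.001,
                  window_kb = 10000, strict = FALSE) {
  if (!is.numeric(r2_threshold) || r2_threshold <= 0 || r2_threshold >= 1) {
    mr_abort("r2_threshold must lie in (0, 1)", "mr_config_error")
  }
  n <- nrow(candidates)
  if (n == 0L) return(character())
  if (!is.null(ld)) {
    missing <- setdiff(candidates$snp_id, ld$snp_ids)
    if (length(missing)) {
      if (strict) {
        mr_abort(sprintf("%d candidate(s) missing from the LD matrix (first: %s)",
                         length(missing), missing[1]), "mr_ld_error")
      }
      warning(sprintf("%d candidate(s) absent from the LD matrix; treated as unlinked",
                      length(missing)), call. = FALSE)
    }
  }
  chrom <- as.character(candidates$chrom)
  pos <- as.numeric(candidates$pos)
  ord <- order(candidates$pvalue, chrom, pos, candidates$snp_id)
  alive <- rep(TRUE, n)
  sel <- integer(0)
  window_bp <- window_kb * 1000
  for (i in ord) {
    if (!alive[i]) next
    alive[i] <- FALSE
    sel <- c(sel, i)
    near <- which(alive & chrom == chrom[i] & abs(pos - pos[i]) <= window_bp)
    if (length(near)) {
      r2 <- ld_r2(ld, candidates$snp_id[i], candidates$snp_id[near])
      alive[near[r2 > r2_threshold]] <- FALSE
    }
  }
  candidates$snp_id[sel]
}

#' Per-SNP instrument-strength F-statistic
#'
#' The squared Wald statistic `(beta/se)^2` of the SNP-exposure association;
#' instruments with F below 10 are conventionally classified as weak.
#'
#' @param beta SNP-exposure effect estimate(s).
#' @param se Standard error(s), strictly positive.
#' @return Numeric vector of F values.
#' @seealso [f_statistic_r2()] for the variance-explained form.
#' @export
f_statistic <- function(beta, se) {
  if (any(!is.finite(se)) || any(se <= 0)) {
    mr_abort("se must be strictly positive", "mr_domain_error")
  }
  (beta / se)^2
}

#' F-statistic from variance explained
#'
#' Alternative strength measure using the variance in the exposure explained
#' by the SNP: `R2 = 2*eaf*(1-eaf)*beta^2` (per-SD effect scale) and
#' `F = R2*(n-2)/(1-R2)`. Agrees closely with [f_statistic()] when R2 is
#' small, as it is for individual GWAS variants.
#'
#' @param beta Per-SD SNP-exposure effect(s).
#' @param eaf Effect-allele frequency in (0, 1).
#' @param n GWAS sample size.
#' @return Numeric vector of F values.
#' @export
f_statistic_r2 <- function(beta, eaf, n) {
  if (any(eaf <= 0 | eaf >= 1)) mr_abort("eaf must lie in (0, 1)", "mr_domain_error")
  if (any(n <= 2)) mr_abort("n must exceed 2", "mr_domain_error")
  r2 <- 2 * eaf * (1 - eaf) * beta^2
  if (any(r2 >= 1)) mr_abort("implied R2 >= 1; check effect scale", "mr_domain_error")
  r2 * (n - 2) / (1 - r2)
}

#' Select instrumental variables for one exposure
#'
#' Applies, in order: the genome-wide significance filter, greedy LD
#' clumping, and the weak-instrument F filter. The order is part of the
#' contract — permuting the stages can change the result because clumping
#' indexes on the lowest-p candidate among those still present.
#'
#' @param stats Exposure summary statistics (canonical columns).
#' @param ld An [ld_matrix()] or `NULL`.
#' @param p_threshold Genome-wide significance level (default 5e-8).
#' @param r2_threshold,window_kb Clumping parameters (defaults 0.001 and
#'   10000 kb).
#' @param f_threshold Minimum instrument F (default 10).
#' @param f_method `"ratio"` for `(beta/se)^2` (default) or `"r2"` for the
#'   variance-explained form.
#' @param strict Passed to [clump()].
#' @return An object of class `instrument_set`: list with `snps` (ids in
#'   selection order), `f_stats` (named), `thresholds`, `drops` (per-stage
#'   counts) and `data` (the retained summary-statistics rows).
#' @export
select_instruments <- function(stats, ld = NULL, p_threshold = 5e-8,
                               r2_threshold = 0.001, window_kb = 10000,
                               f_threshold = 10,
                               f_method = c("ratio", "r2"), strict = FALSE) {
  f_method <- match.arg(f_method)
  gw <- filter_genomewide(stats, p_threshold)
  n_drop_p <- nrow(stats) - nrow(gw)
  idx <- clump(gw, ld, r2_threshold = r2_threshold, window_kb = window_kb,
               strict = strict)
  clumped <- gw[match(idx, gw$snp_id), , drop = FALSE]
  n_drop_ld <- nrow(gw) - nrow(clumped)
  f <- if (nrow(clumped) == 0L) numeric() else if (f_method == "ratio") {
    f_statistic(clumped$beta, clumped$se)
  } else {
    f_statistic_r2(clumped$beta, clumped$eaf, clumped$n)
  }
  strong <- f >= f_threshold
  n_drop_f <- sum(!strong)
  kept <- clumped[strong, , drop = FALSE]
  if (nrow(kept) == 0L) {
    mr_abort(sprintf(paste0("no instruments survive selection ",
                            "(%d below significance, %d LD-pruned, %d weak)"),
                     n_drop_p, n_drop_ld, n_drop_f), "mr_no_instruments")
  }
  rownames(kept) <- NULL
  structure(list(snps = kept$snp_id,
                 f_stats = stats::setNames(f[strong], kept$snp_id),
                 thresholds = list(p_threshold = p_threshold,
                                   r2_threshold = r2_threshold,
                                   window_kb = window_kb,
                                   f_threshold = f_threshold),
                 drops = c(not_significant = n_drop_p, ld_pruned = n_drop_ld,
                           weak = n_drop_f),
                 data = kept),
            class = "instrument_set")
}

#' @export
print.instrument_set <- function(x, ...) {
  cat(sprintf("Instrument set: %d SNPs (p<=%.3g, r2<%.3g within %g kb, F>=%g)\n",
              length(x$snps), x$thresholds$p_threshold, x$thresholds$r2_threshold,
              x$thresholds$window_kb, x$thresholds$f_threshold))
  cat(sprintf("Dropped: %d below significance, %d LD-pruned, %d weak; min F = %.1f\n",
              x$drops[["not_significant"]], x$drops[["ld_pruned"]],
              x$drops[["weak"]], if (length(x$f_stats)) min(x$f_stats) else NA))
  invisible(x)
}
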