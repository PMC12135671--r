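# Shared fixtures and independent oracles, all built in code.

# Canonical in-memory summary-statistics frame.
make_stats <- function(n = 5, seed = NULL, beta = NULL, se = NULL,
                       pvalue = NULL, chrom = NULL, pos = NULL,
                       ea = NULL, oa = NULL, eaf = NULL, nsamp = 1e5,
                       snp_id = sprintf("rs%03d", seq_len(n))) {
  if (!is.null(seed)) set.seed(seed)
  beta <- beta %||% stats::rnorm(n, 0, 0.05)
  se <- se %||% stats::runif(n, 0.004, 0.01)
  pvalue <- pvalue %||% pmax(2 * stats::pnorm(-abs(beta / se)), 1e-300)
  data.frame(snp_id = snp_id,
             chrom = chrom %||% rep("1", n),
             pos = pos %||% seq(1e6, by = 1e5, length.out = n),
             effect_allele = ea %||% rep("A", n),
             other_allele = oa %||% rep("G", n),
             eaf = eaf %||% stats::runif(n, 0.1, 0.45),
             beta = beta, se = se, pvalue = pvalue, n = nsamp,
             stringsAsFactors = FALSE)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Harmonized exposure/outcome set straight from effect vectors.
make_h <- function(bx, sx, by, sy, snp = sprintf("rs%03d", seq_along(bx))) {
  as_harmonized_set(
    data.frame(snp_id = snp, beta_exposure = bx, se_exposure = sx,
               beta_outcome = by, se_outcome = sy, stringsAsFactors = FALSE),
    roles = c("exposure", "outcome"))
}

# Independent re-implementation of greedy clumping: nested loops over a
# dense r2 matrix, no shared code with clump().
oracle_clump <- function(cand, r2mat, r2_threshold, window_kb) {
  cand <- cand[order(cand$pvalue, as.character(cand$chrom), cand$pos,
                     cand$snp_id), , drop = FALSE]
  sel <- character()
  while (nrow(cand) > 0L) {
    top <- cand[1L, ]
    sel <- c(sel, top$snp_id)
    drop <- rep(FALSE, nrow(cand))
    drop[1L] <- TRUE
    for (j in seq_len(nrow(cand))[-1L]) {
      if (as.character(cand$chrom[j]) == as.character(top$chrom) &&
          abs(cand$pos[j] - top$pos) <= window_kb * 1000) {
        r2 <- r2mat[top$snp_id, cand$snp_id[j]]
        if (r2 > r2_threshold) drop[j] <- TRUE
      }
    }
    cand <- cand[!drop, , drop = FALSE]
  }
  sel
}

# Random symmetric r2 matrix (dense) plus its sparse package form.
random_ld <- function(snp_ids, density = 0.4) {
  n <- length(snp_ids)
  m <- matrix(0, n, n, dimnames = list(snp_ids, snp_ids))
  up <- upper.tri(m)
  vals <- ifelse(stats::runif(sum(up)) < density, stats::runif(sum(up)), 0)
  m[up] <- vals
  m <- m + t(m)
  diag(m) <- 1
  list(dense = m, sparse = as_ld_matrix(m))
}
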