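#' Configuration for the summary-statistics simulator
#'
#' Defines a generative model for two-sample GWAS summary statistics with
#' known ground truth. SNPs come in independent loci of `ld_block_size`
#' correlated variants (within-block r-squared `ld_r2`); `n_snps` counts
#' the exposure's causal loci, each mediator gets `n_med_snps` loci of its
#' own (mediators are real traits with their own genetic architecture), and
#' `n_rev_snps` loci act on the outcome directly with an optional
#' back-effect `theta_rev` on the exposure (for bidirectional scenarios).
#'
#' Per-SNP true exposure effects are drawn from a centered normal scaled to
#' `instrument_zscale` times the median exposure standard error, so most
#' loci reach genome-wide significance at the given sample size. Observed
#' effects add sampling noise with `SE = 1/sqrt(2*eaf*(1-eaf)*n)` for
#' continuous traits and `SE = 1/sqrt(2*eaf*(1-eaf)*n*phi*(1-phi))` for
#' binary ones (`phi` = case fraction, log-odds scale). The outcome's
#' sampling noise is multiplied by `het_multiplier` while its reported SE
#' is not, which plants genuine heterogeneity; `pleiotropy_*` adds direct
#' outcome effects to a fraction of exposure loci (directional when the
#' mean is nonzero); `n_outliers` exposure-locus lead SNPs receive gross
#' outcome offsets of 5-10 reported SEs. `palindrome_frac` of SNPs get A/T
#' or G/C allele pairs and `swap_frac` of non-exposure records are emitted
#' with swapped allele labels (negated beta, complemented frequency), which
#' harmonization must undo.
#'
#' The structural identity `theta_total = theta_direct +
#' sum(theta_xm * theta_my)` is enforced: leave `theta_direct` `NULL` to
#' have it derived.
#'
#' @param n_snps Exposure causal loci (default 200).
#' @param n_med_snps Mediator-specific loci per mediator (default 150).
#' @param n_rev_snps Outcome-specific loci (default 0).
#' @param n_exp,n_out,n_med GWAS sample sizes for exposure, outcome and
#'   mediator(s); defaults mirror large biobank/consortium studies
#'   (435,744 / 56,284 / 977,323).
#' @param case_frac Case fraction of each binary mediator (default 0.05).
#' @param theta_total True total exposure-to-outcome effect (default -0.04,
#'   per-SD scale).
#' @param theta_xm,theta_my Per-mediator exposure-to-mediator (log-odds) and
#'   mediator-to-outcome direct effects; equal-length vectors, empty for no
#'   mediators.
#' @param theta_direct Direct exposure-to-outcome effect; derived from the
#'   identity when `NULL`.
#' @param theta_rev Back-effect of the outcome-specific loci on the exposure
#'   (default 0).
#' @param pleiotropy_frac,pleiotropy_mean,pleiotropy_sd Fraction of exposure
#'   SNPs with direct outcome effects and the normal their effects are drawn
#'   from (defaults 0/0/0).
#' @param het_multiplier Outcome noise inflation (default 1 = none).
#' @param n_outliers Gross outliers planted among significant exposure lead
#'   SNPs (default 0).
#' @param palindrome_frac,swap_frac Harmonization stressors (defaults 0.05
#'   and 0.2).
#' @param ld_block_size,ld_r2 LD block structure (defaults 5 and 0.6).
#' @param eaf_range Uniform range for effect-allele frequencies (default
#'   c(0.05, 0.5)).
#' @param instrument_zscale Scale of true effects in median-SE units
#'   (default 20; about 79% of loci reach p <= 5e-8).
#' @param seed Integer seed.
#' @return Object of class `sim_config`.
#' @seealso [simulate_sumstats()], [mr_scenario()]
#' @export
sim_config <- function(n_snps = 200, n_med_snps = 150, n_rev_snps = 0,
                       n_exp = 435744, n_out = 56284, n_med = 977323,
                       case_frac = 0.05,
                       theta_total = -0.04, theta_xm = numeric(),
                       theta_my = numeric(), theta_direct = NULL,
                       theta_rev = 0,
                       pleiotropy_frac = 0, pleiotropy_mean = 0,
                       pleiotropy_sd = 0,
                       het_multiplier = 1, n_outliers = 0,
                       palindrome_frac = 0.05, swap_frac = 0.2,
                       ld_block_size = 5, ld_r2 = 0.6,
                       eaf_range = c(0.05, 0.5), instrument_zscale = 20,
                       seed = 1) {
  M <- length(theta_xm)
  if (length(theta_my) != M) {
    mr_abort("theta_xm and theta_my must have the same length", "mr_config_error")
  }
  n_med <- rep_len(n_med, max(M, 1L))
  case_frac <- rep_len(case_frac, max(M, 1L))
  for (f in c(pleiotropy_frac, palindrome_frac, swap_frac)) {
    if (f < 0 || f > 1) mr_abort("fractions must lie in [0, 1]", "mr_config_error")
  }
  if (any(c(n_exp, n_out, n_med) <= 0)) {
    mr_abort("sample sizes must be positive", "mr_config_error")
  }
  if (any(case_frac <= 0 | case_frac >= 1)) {
    mr_abort("case_frac must lie in (0, 1)", "mr_config_error")
  }
  if (ld_block_size < 1 || ld_r2 < 0 || ld_r2 > 1) {
    mr_abort("ld_block_size must be >= 1 and ld_r2 in [0, 1]", "mr_config_error")
  }
  if (eaf_range[1] <= 0 || eaf_range[2] >= 1 || eaf_range[1] >= eaf_range[2]) {
    mr_abort("eaf_range must be an increasing interval inside (0, 1)", "mr_config_error")
  }
  indirect <- sum(theta_xm * theta_my)
  if (is.null(theta_direct)) {
    theta_direct <- theta_total - indirect
  } else if (abs(theta_total - theta_direct - indirect) > 1e-8) {
    mr_abort("theta_total must equal theta_direct + sum(theta_xm * theta_my)",
             "mr_config_error")
  }
  structure(list(n_snps = n_snps, n_med_snps = n_med_snps,
                 n_rev_snps = n_rev_snps, n_exp = n_exp, n_out = n_out,
                 n_med = n_med, case_frac = case_frac,
                 theta_total = theta_total, theta_xm = theta_xm,
                 theta_my = theta_my, theta_direct = theta_direct,
                 theta_rev = theta_rev,
                 pleiotropy_frac = pleiotropy_frac,
                 pleiotropy_mean = pleiotropy_mean,
                 pleiotropy_sd = pleiotropy_sd,
                 het_multiplier = het_multiplier, n_outliers = n_outliers,
                 palindrome_frac = palindrome_frac, swap_frac = swap_frac,
                 ld_block_size = ld_block_size, ld_r2 = ld_r2,
                 eaf_range = eaf_range, instrument_zscale = instrument_zscale,
                 seed = seed),
            class = "sim_config")
}

# Non-palindromic ordered allele pairs (effect, other).
.NONPAL_PAIRS <- {
  g <- expand.grid(ea = c("A", "C", "G", "T"), oa = c("A", "C", "G", "T"),
                   stringsAsFactors = FALSE)
  g <- g[g$ea != g$oa & .COMP[g$ea] != g$oa, ]
  rownames(g) <- NULL
  g
}
.PAL_PAIRS <- data.frame(ea = c("A", "T", "C", "G"), oa = c("T", "A", "G", "C"),
                         stringsAsFactors = FALSE)

.make_sumstats_df <- function(ids, chrom, pos, ea, oa, eaf, beta, se, n) {
  data.frame(snp_id = ids, chrom = chrom, pos = pos,
             effect_allele = ea, other_allele = oa, eaf = eaf, beta = beta,
             se = se, pvalue = pmax(2 * stats::pnorm(-abs(beta / se)),
                                    .Machine$double.xmin),
             n = n, stringsAsFactors = FALSE)
}

#' Simulate two-sample GWAS summary statistics with known truth
#'
#' Draws a complete multi-trait summary-statistics panel (exposure, binary
#' mediator(s), continuous outcome) under the generative model described in
#' [sim_config()], together with the block-diagonal LD matrix and a
#' `sim_truth` record of every generative quantity. All traits report the
#' same SNP panel, as real GWAS datasets sharing an imputation backbone do.
#' Output is deterministic in `cfg$seed`.
#'
#' @param cfg A [sim_config()].
#' @return Object of class `sim_data`: list with `exposure`, `mediators`
#'   (named list, possibly empty), `outcome` (canonical summary-statistics
#'   data frames), `ld` (an [ld_matrix()]), `truth` (class `sim_truth`:
#'   per-SNP `snp` table with true effects, pleiotropy and outlier flags,
#'   plus `beta0`, `beta1`, `beta2`, `theta_direct` and the true mediation
#'   `proportions`), and `config`.
#' @export
simulate_sumstats <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  core <- with_seed(cfg$seed, .simulate_core(cfg))
  # Stressors are pure relabelings drawn from a separate stream so that the
  # same seed with different stressor settings shares identical effects.
  with_seed(cfg$seed + 500009L, .apply_stressors(core, cfg))
}

.simulate_core <- function(cfg) {
  M <- length(cfg$theta_xm)
  B <- cfg$ld_block_size
  role_loci <- c(rep("exposure", cfg$n_snps),
                 if (M) rep(sprintf("mediator%d", seq_len(M)),
                            each = cfg$n_med_snps),
                 rep("reverse", cfg$n_rev_snps))
  G <- length(role_loci)
  if (G == 0L) mr_abort("configuration generates no loci", "mr_config_error")
  nsnp <- G * B
  locus <- rep(seq_len(G), each = B)
  within <- rep(seq_len(B), times = G)
  lead <- within == 1L
  role <- role_loci[locus]

  chrom <- as.character(((locus - 1L) %% 22L) + 1L)
  slot <- (locus - 1L) %/% 22L
  pos <- 1e6 + slot * 25e6 + (within - 1L) * 1e4

  ids <- sprintf("rs%07d", seq_len(nsnp))
  eaf <- stats::runif(nsnp, cfg$eaf_range[1], cfg$eaf_range[2])
  info <- 2 * eaf * (1 - eaf)
  se_x <- 1 / sqrt(info * cfg$n_exp)
  se_y <- 1 / sqrt(info * cfg$n_out)
  v <- cfg$case_frac * (1 - cfg$case_frac)
  se_m <- lapply(seq_len(max(M, 1L)), function(i) {
    1 / sqrt(info * cfg$n_med[i] * v[i])
  })

  # True per-SNP effects; satellites carry the lead effect attenuated by
  # sqrt(r2), consistent with LD-induced tagging.
  atten <- ifelse(lead, 1, sqrt(cfg$ld_r2))
  draw_lead <- function(mask, sd) {
    g_lead <- ifelse(role_loci == mask, stats::rnorm(G, 0, sd), 0)
    g_lead[locus] * atten
  }
  gamma <- draw_lead("exposure", cfg$instrument_zscale * stats::median(se_x))
  delta <- lapply(seq_len(M), function(i) {
    draw_lead(sprintf("mediator%d", i),
              cfg$instrument_zscale * stats::median(se_m[[i]]))
  })
  rho <- draw_lead("reverse", cfg$instrument_zscale * stats::median(se_y))

  alpha <- numeric(nsnp)
  if (cfg$pleiotropy_frac > 0) {
    hit <- role == "exposure" & stats::runif(nsnp) < cfg$pleiotropy_frac
    alpha[hit] <- stats::rnorm(sum(hit), cfg$pleiotropy_mean, cfg$pleiotropy_sd)
  }

  true_x <- gamma + cfg$theta_rev * rho
  true_m <- lapply(seq_len(M), function(i) cfg$theta_xm[i] * true_x + delta[[i]])
  true_y <- cfg$theta_direct * true_x + rho + alpha
  for (i in seq_len(M)) true_y <- true_y + cfg$theta_my[i] * true_m[[i]]

  beta_x <- true_x + se_x * stats::rnorm(nsnp)
  beta_m <- lapply(seq_len(M), function(i) true_m[[i]] + se_m[[i]] * stats::rnorm(nsnp))
  beta_y <- true_y + cfg$het_multiplier * se_y * stats::rnorm(nsnp)

  outlier <- logical(nsnp)
  if (cfg$n_outliers > 0) {
    cand <- which(lead & role == "exposure" &
                    2 * stats::pnorm(-abs(beta_x / se_x)) <= 5e-8)
    if (length(cand) < cfg$n_outliers) {
      warning("fewer significant lead SNPs than requested outliers; planting fewer",
              call. = FALSE)
    }
    pick <- if (length(cand)) sample(cand, min(cfg$n_outliers, length(cand))) else integer()
    outlier[pick] <- TRUE
    beta_y[pick] <- beta_y[pick] +
      sample(c(-1, 1), length(pick), replace = TRUE) *
      stats::runif(length(pick), 5, 10) * se_y[pick]
  }

  is_pal <- stats::runif(nsnp) < cfg$palindrome_frac
  pair <- .NONPAL_PAIRS[sample.int(nrow(.NONPAL_PAIRS), nsnp, replace = TRUE), ]
  if (any(is_pal)) {
    pair[is_pal, ] <- .PAL_PAIRS[sample.int(4, sum(is_pal), replace = TRUE), ]
  }

  ld_pairs <- NULL
  if (B > 1 && cfg$ld_r2 > 0) {
    combs <- utils::combn(B, 2)
    a_off <- rep(combs[1, ], G); b_off <- rep(combs[2, ], G)
    base <- rep((seq_len(G) - 1L) * B, each = ncol(combs))
    ld_pairs <- data.frame(snp_a = ids[base + a_off], snp_b = ids[base + b_off],
                           r2 = cfg$ld_r2, stringsAsFactors = FALSE)
  }
  ld <- ld_matrix(ld_pairs, snp_ids = ids)

  exposure <- .make_sumstats_df(ids, chrom, pos, pair$ea, pair$oa, eaf,
                                beta_x, se_x, cfg$n_exp)
  mediators <- stats::setNames(lapply(seq_len(M), function(i) {
    .make_sumstats_df(ids, chrom, pos, pair$ea, pair$oa, eaf,
                      beta_m[[i]], se_m[[i]], cfg$n_med[i])
  }), if (M) sprintf("mediator%d", seq_len(M)) else NULL)
  outcome <- .make_sumstats_df(ids, chrom, pos, pair$ea, pair$oa, eaf,
                               beta_y, se_y, cfg$n_out)

  proportions <- if (M && cfg$theta_total != 0) {
    cfg$theta_xm * cfg$theta_my / cfg$theta_total
  } else {
    rep(NA_real_, M)
  }
  truth <- structure(list(
    snp = data.frame(snp_id = ids, role = role, lead = lead, gamma = true_x,
                     alpha = alpha, outlier = outlier, stringsAsFactors = FALSE),
    beta0 = cfg$theta_total, beta1 = cfg$theta_xm, beta2 = cfg$theta_my,
    theta_direct = cfg$theta_direct, proportions = proportions
  ), class = "sim_truth")

  list(exposure = exposure, mediators = mediators, outcome = outcome,
       ld = ld, truth = truth, config = cfg)
}

# Relabel a fraction of non-exposure records with swapped alleles (negated
# beta, complemented eaf): an exact representation change that harmonization
# must undo.
.apply_stressors <- function(core, cfg) {
  swap_one <- function(df) {
    mask <- stats::runif(nrow(df)) < cfg$swap_frac
    ea <- df$effect_allele[mask]
    df$effect_allele[mask] <- df$other_allele[mask]
    df$other_allele[mask] <- ea
    df$beta[mask] <- -df$beta[mask]
    df$eaf[mask] <- 1 - df$eaf[mask]
    df
  }
  if (cfg$swap_frac > 0) {
    core$mediators <- lapply(core$mediators, swap_one)
    core$outcome <- swap_one(core$outcome)
  }
  structure(core, class = "sim_data")
}

#' @export
print.sim_data <- function(x, ...) {
  cat(sprintf("Simulated summary statistics: %d SNPs, %d mediator(s), seed %d\n",
              nrow(x$exposure), length(x$mediators), x$config$seed))
  invisible(x)
}

#' Write a simulated dataset as delimited files
#'
#' Emits one summary-statistics file per trait (through [write_sumstats()]),
#' the LD matrix in long form, and the per-SNP truth table.
#'
#' @param sim A [simulate_sumstats()] result.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_sim_data <- function(sim, dir) {
  stopifnot(inherits(sim, "sim_data"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_sumstats(sim$exposure, file.path(dir, "exposure.tsv"))
  for (nm in names(sim$mediators)) {
    write_sumstats(sim$mediators[[nm]], file.path(dir, paste0(nm, ".tsv")))
  }
  write_sumstats(sim$outcome, file.path(dir, "outcome.tsv"))
  write_ld_matrix(sim$ld, file.path(dir, "ld.tsv"))
  utils::write.table(sim$truth$snp, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
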