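# Allele complement used by the brute-force expectation table (independent
# of the package's internal map).
comp <- c(A = "T", T = "A", C = "G", G = "C")

test_that("allele swaps flip the outcome sign and strand flips do not", {
  exp <- make_stats(1, ea = "A", oa = "G", beta = 0.1)
  out <- make_stats(1, ea = "G", oa = "A", beta = 0.05, eaf = 0.7)
  h <- harmonize(list(exposure = exp, outcome = out))
  expect_equal(h$data$beta_outcome / h$data$beta_exposure, -0.05 / 0.1)
  expect_equal(h$data$eaf_outcome, 1 - 0.7)

  # same variant reported on the other strand: T/C complements A/G
  out2 <- make_stats(1, ea = "T", oa = "C", beta = 0.05, eaf = exp$eaf)
  h2 <- harmonize(list(exposure = exp, outcome = out2))
  expect_equal(h2$data$beta_outcome / h2$data$beta_exposure, 0.05 / 0.1)
})

test_that("every non-palindromic allele configuration matches a brute-force table", {
  bases <- c("A", "C", "G", "T")
  ref_pairs <- expand.grid(ea = bases, oa = bases, stringsAsFactors = FALSE)
  ref_pairs <- ref_pairs[ref_pairs$ea != ref_pairs$oa &
                           comp[ref_pairs$ea] != ref_pairs$oa, ]
  for (i in seq_len(nrow(ref_pairs))) {
    re <- ref_pairs$ea[i]; ro <- ref_pairs$oa[i]
    for (j in seq_len(nrow(ref_pairs))) {
      oe <- ref_pairs$ea[j]; oo <- ref_pairs$oa[j]
      # brute-force expectation: enumerate swap/strand-flip combinations
      expected <- if (oe == re && oo == ro) "keep"
      else if (oe == ro && oo == re) "flip"
      else if (comp[[oe]] == re && comp[[oo]] == ro) "keep"
      else if (comp[[oe]] == ro && comp[[oo]] == re) "flip"
      else "drop"
      exp <- make_stats(1, ea = re, oa = ro, beta = 0.1, eaf = 0.2)
      out <- make_stats(1, ea = oe, oa = oo, beta = 0.04, eaf = 0.2)
      if (expected == "drop") {
        expect_error(harmonize(list(exposure = exp, outcome = out)),
                     class = "mr_harmonization_error")
      } else {
        h <- harmonize(list(exposure = exp, outcome = out))
        sgn <- if (expected == "keep") 1 else -1
        expect_equal(h$data$beta_outcome / h$data$beta_exposure,
                     sgn * 0.04 / 0.1)
      }
    }
  }
})

test_that("palindromic SNPs follow the configured policy", {
  exp <- make_stats(1, ea = "A", oa = "T", beta = 0.1, eaf = 0.2)
  out <- make_stats(1, ea = "A", oa = "T", beta = 0.04, eaf = 0.2)
  filler_e <- make_stats(1, snp_id = "rs999", beta = 0.2, eaf = 0.3)
  filler_o <- make_stats(1, snp_id = "rs999", beta = 0.1, eaf = 0.3)
  sets <- list(exposure = rbind(exp, filler_e), outcome = rbind(out, filler_o))

  h_all <- harmonize(sets, palindrome_policy = "drop-all")
  expect_false("rs001" %in% h_all$data$snp_id)
  expect_true("palindromic" %in% h_all$dropped$reason)

  # unambiguous frequencies: retained, orientation by frequency concordance
  h_amb <- harmonize(sets, palindrome_policy = "drop-ambiguous", eaf_window = 0.08)
  expect_true("rs001" %in% h_amb$data$snp_id)
  expect_equal(h_amb$data$beta_outcome[h_amb$data$snp_id == "rs001"] /
                 h_amb$data$beta_exposure[h_amb$data$snp_id == "rs001"],
               0.04 / 0.1)

  # discordant frequency side implies a strand flip: sign reversed
  out_flipped <- out
  out_flipped$eaf <- 0.8
  out_flipped$beta <- -0.04
  h_fl <- harmonize(list(exposure = sets$exposure,
                         outcome = rbind(out_flipped, filler_o)),
                    palindrome_policy = "drop-ambiguous")
  expect_equal(h_fl$data$beta_outcome[h_fl$data$snp_id == "rs001"] /
                 h_fl$data$beta_exposure[h_fl$data$snp_id == "rs001"],
               0.04 / 0.1)

  # frequency near 0.5 in any role: dropped as ambiguous
  out_mid <- out
  out_mid$eaf <- 0.5
  h_mid <- harmonize(list(exposure = sets$exposure,
                          outcome = rbind(out_mid, filler_o)),
                     palindrome_policy = "drop-ambiguous", eaf_window = 0.08)
  expect_false("rs001" %in% h_mid$data$snp_id)
  expect_true("palindromic-ambiguous" %in% h_mid$dropped$reason)
})

test_that("harmonization is idempotent and invariant to record flips and row order", {
  set.seed(42)
  n <- 40
  ea <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  oa <- vapply(ea, function(a) sample(setdiff(c("A", "C", "G", "T"),
                                              c(a, comp[[a]])), 1), "")
  exp <- make_stats(n, ea = ea, oa = oa, eaf = runif(n, 0.1, 0.4))
  out <- make_stats(n, ea = ea, oa = oa, eaf = exp$eaf + rnorm(n, 0, 0.01),
                    beta = rnorm(n, 0, 0.02))
  h <- harmonize(list(exposure = exp, outcome = out))

  # idempotence: re-harmonizing the aligned sets changes nothing
  h2 <- do.call(harmonize, list(split_harmonized(h)))
  expect_equal(h2$data, h$data)

  # flip-invariance: rewriting arbitrary records (in either role) with
  # swapped alleles, negated beta, complemented eaf gives identical output
  flip_rows <- function(df, idx) {
    tmp <- df$effect_allele[idx]
    df$effect_allele[idx] <- df$other_allele[idx]
    df$other_allele[idx] <- tmp
    df$beta[idx] <- -df$beta[idx]
    df$eaf[idx] <- 1 - df$eaf[idx]
    df
  }
  exp_f <- flip_rows(exp, c(1, 5, 9))
  out_f <- flip_rows(out, c(2, 5, 30))
  h_f <- harmonize(list(exposure = exp_f, outcome = out_f))
  # equality up to floating-point complement round-trip on eaf
  expect_equal(h_f$data, h$data, tolerance = 1e-15)

  # order-invariance: permuting input rows leaves values untouched
  perm <- sample(n)
  h_p <- harmonize(list(exposure = exp[perm, ], outcome = out[rev(perm), ]))
  ord <- match(h$data$snp_id, h_p$data$snp_id)
  expect_identical(h_p$data[ord, , drop = FALSE]$beta_outcome,
                   h$data$beta_outcome)
  expect_setequal(h_p$data$snp_id, h$data$snp_id)
})

test_that("degenerate inputs raise structured errors", {
  a <- make_stats(3)
  b <- make_stats(3, snp_id = sprintf("rs9%02d", 1:3))
  expect_error(harmonize(list(exposure = a, outcome = b)),
               class = "mr_harmonization_error")   # empty intersection
  dup <- rbind(a, a[1, ])
  expect_error(harmonize(list(exposure = dup, outcome = a)),
               class = "mr_input_error")            # duplicate snp_id
  expect_error(harmonize(list(a, b)), class = "mr_input_error")  # unnamed roles
})
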