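test_that("Wald ratios are elementwise division with first-order errors", {
  h <- make_h(bx = 0.1, sx = 0.005, by = 0.02, sy = 0.01)
  r <- ratio_estimates(h)
  expect_equal(r$ratio, 0.2)
  expect_equal(r$ratio_se, 0.1)

  h0 <- make_h(bx = c(0.1, 0.2), sx = 0.005, by = c(0, 0.01), sy = 0.01)
  expect_equal(ratio_estimates(h0)$ratio[1], 0)

  set.seed(3)
  bx <- rnorm(50, 0, 0.05); by <- rnorm(50, 0, 0.01); sy <- runif(50, 0.005, 0.02)
  r2 <- ratio_estimates(make_h(bx, 0.005, by, sy))
  expect_equal(r2$ratio, by / bx)
  expect_equal(r2$ratio_se, sy / abs(bx))

  hz <- make_h(bx = c(0, 0.1, 0.2), sx = 0.01, by = c(0.01, 0.02, 0.04), sy = 0.01)
  expect_warning(rz <- ratio_estimates(hz), "zero exposure effect")
  expect_equal(nrow(rz), 2)
})

test_that("IVW-FE reproduces hand-computed weights and unanimity", {
  # unanimous ratios: exact pooled value, Q = 0
  h_u <- make_h(bx = c(0.1, 0.2, 0.4), sx = 0.01, by = c(0.02, 0.04, 0.08),
                sy = c(0.01, 0.02, 0.01))
  fe <- mr_ivw_fe(h_u)
  expect_equal(fe$beta, 0.2)
  q <- cochran_q(h_u)
  expect_equal(q$Q, 0)
  expect_equal(q$pvalue, 1)

  # weights 100, 400, 25 -> se = 525^(-1/2)
  h <- make_h(bx = c(0.1, 0.2, 0.1), sx = 0.01,
              by = c(0.02, 0.04, 0.02), sy = c(0.01, 0.01, 0.02))
  fe2 <- mr_ivw_fe(h)
  expect_equal(fe2$se, 1 / sqrt(525), tolerance = 1e-12)
  expect_equal(fe2$beta, 0.2, tolerance = 1e-12)

  expect_error(mr_ivw_fe(make_h(0.1, 0.01, 0.02, 0.01)),
               class = "mr_estimation_error")
})

test_that("IVW closed form equals zero-intercept weighted regression", {
  set.seed(14)
  for (i in 1:25) {
    L <- sample(3:60, 1)
    bx <- rnorm(L, 0, 0.05); sy <- runif(L, 0.004, 0.02)
    by <- 0.1 * bx + rnorm(L, 0, sy)
    h <- make_h(bx, 0.004, by, sy)
    fe <- mr_ivw_fe(h)
    fit <- lm(by ~ 0 + bx, weights = 1 / sy^2)
    expect_equal(fe$beta, unname(coef(fit)), tolerance = 1e-10)
    # FE se is the regression se with the residual dispersion divided out
    se_lm <- summary(fit)$coefficients[1, 2] / summary(fit)$sigma
    expect_equal(fe$se, unname(se_lm), tolerance = 1e-10)
  }
})

test_that("Cochran's Q matches hand arithmetic and its null expectation", {
  # weights (100, 400), ratios (0.1, 0.3): IVW 0.26, Q = 3.2
  h <- make_h(bx = c(1, 2), sx = 0.01, by = c(0.1, 0.6), sy = 0.1)
  fe <- mr_ivw_fe(h)
  expect_equal(fe$beta, 0.26, tolerance = 1e-12)
  q <- cochran_q(h)
  expect_equal(q$Q, 3.2, tolerance = 1e-12)
  expect_equal(q$df, 1)

  # with correct SEs, Q/df has mean ~ 1
  set.seed(8)
  qdf <- replicate(300, {
    L <- 30
    bx <- rnorm(L, 0, 0.05); sy <- runif(L, 0.004, 0.01)
    by <- 0.05 * bx + rnorm(L, 0, sy)
    q <- cochran_q(make_h(bx, 1e-6, by, sy))
    q$Q / q$df
  })
  expect_gt(mean(qdf), 0.9)
  expect_lt(mean(qdf), 1.1)
})

test_that("IVW-MRE shares the FE point estimate and inflates the se by sqrt(Q/df)", {
  set.seed(21)
  for (i in 1:10) {
    L <- sample(3:40, 1)
    bx <- rnorm(L, 0, 0.05); sy <- runif(L, 0.004, 0.02)
    by <- -0.1 * bx + rnorm(L, 0, 2 * sy)   # overdispersed
    h <- make_h(bx, 0.004, by, sy)
    fe <- mr_ivw_fe(h); mre <- mr_ivw_mre(h); q <- cochran_q(h)
    expect_identical(mre$beta, fe$beta)
    expect_gte(mre$se, fe$se)
    expect_equal(mre$se, fe$se * max(1, sqrt(q$Q / q$df)), tolerance = 1e-12)
  }
  # homogeneous data: truncation at 1 makes MRE equal FE exactly
  h_u <- make_h(bx = c(0.1, 0.2, 0.4), sx = 0.01,
                by = c(0.02, 0.04, 0.08), sy = c(0.01, 0.02, 0.01))
  expect_equal(mr_ivw_mre(h_u)$se, mr_ivw_fe(h_u)$se)
})

test_that("MRE intervals restore coverage lost by FE under overdispersion", {
  set.seed(99)
  cover <- replicate(400, {
    L <- 40
    bx <- rnorm(L, 0, 0.05); sy <- runif(L, 0.004, 0.01)
    by <- 0.1 * bx + rnorm(L, 0, 2 * sy)   # heterogeneity multiplier 2
    h <- make_h(bx, 1e-6, by, sy)
    fe <- mr_ivw_fe(h); mre <- mr_ivw_mre(h)
    c(fe = fe$ci_low <= 0.1 && 0.1 <= fe$ci_high,
      mre = mre$ci_low <= 0.1 && 0.1 <= mre$ci_high)
  })
  expect_lt(mean(cover["fe", ]), 0.90)
  expect_gt(mean(cover["mre", ]), 0.91)
})

test_that("MR-Egger recovers an exact linear fit and planted pleiotropy", {
  # three points on the line y = 0.01 + 0.2 x: exact fit, zero residuals
  h <- make_h(bx = c(0.1, 0.2, 0.3), sx = 0.01,
              by = 0.01 + 0.2 * c(0.1, 0.2, 0.3), sy = 0.01)
  eg <- mr_egger(h)
  expect_equal(eg$estimate$beta, 0.2, tolerance = 1e-10)
  expect_equal(eg$intercept$estimate, 0.01, tolerance = 1e-10)

  expect_error(mr_egger(make_h(c(0.1, 0.2), 0.01, c(0.1, 0.2), 0.01)),
               class = "mr_estimation_error")

  # directional pleiotropy with mean 0.02: intercept within 2 se in >= 90%
  set.seed(12)
  hits <- replicate(200, {
    L <- 60
    bx <- abs(rnorm(L, 0.05, 0.02)) + 0.01
    sy <- runif(L, 0.004, 0.01)
    alpha <- rnorm(L, 0.02, 0.01)
    by <- alpha + 0.1 * bx + rnorm(L, 0, sy)
    eg <- mr_egger(make_h(bx, 1e-6, by, sy))
    abs(eg$intercept$estimate - 0.02) <= 2 * eg$intercept$se
  })
  expect_gte(mean(hits), 0.9)
})

test_that("Egger intercept p-values are calibrated under no pleiotropy", {
  set.seed(31)
  pvals <- replicate(300, {
    L <- 50
    bx <- abs(rnorm(L, 0, 0.05))
    sy <- runif(L, 0.004, 0.01)
    by <- 0.05 * bx + rnorm(L, 0, sy)
    mr_egger(make_h(bx, 1e-6, by, sy))$intercept$pvalue
  })
  rej <- mean(pvals < 0.05)
  expect_gt(rej, 0.01)
  expect_lt(rej, 0.10)
})

test_that("the weighted median interpolates correctly and resists invalid instruments", {
  # equal weights, ratios {0.1, 0.2, 0.9} -> the middle element
  h <- make_h(bx = c(1, 1, 1), sx = 0.01, by = c(0.1, 0.2, 0.9), sy = 0.1)
  wm <- mr_weighted_median(h, n_boot = 200, seed = 4)
  expect_equal(wm$beta, 0.2, tolerance = 1e-12)

  # almost all weight on one SNP -> that SNP's ratio
  h2 <- make_h(bx = c(1, 7, 1), sx = 0.01, by = c(0.1, 7 * 0.5, 0.9), sy = 0.1)
  wm2 <- mr_weighted_median(h2, n_boot = 200, seed = 4)
  expect_equal(wm2$beta, 0.5, tolerance = 0.01)

  # 49% invalid weight: median nearly unbiased, IVW pulled > 3x further
  set.seed(55)
  res <- replicate(300, {
    L <- 51
    bad <- seq_len(25)             # 25 of 51 instruments are pleiotropic
    bx <- rep(1, L); sy <- rep(0.015, L)
    by <- 0.5 * bx + rnorm(L, 0, sy)
    by[bad] <- by[bad] + 1
    h <- make_h(bx, 1e-6, by, sy)
    c(med = mr_weighted_median(h, n_boot = 50, seed = 1)$beta,
      ivw = mr_ivw_fe(h)$beta)
  })
  med_bias <- abs(mean(res["med", ]) - 0.5)
  ivw_bias <- abs(mean(res["ivw", ]) - 0.5)
  expect_lt(med_bias, 0.05)          # < 10% of the true effect
  expect_gt(ivw_bias, 3 * med_bias)

  # bootstrap is seed-deterministic
  expect_identical(mr_weighted_median(h, n_boot = 100, seed = 9)$se,
                   mr_weighted_median(h, n_boot = 100, seed = 9)$se)
})

test_that("all estimators are invariant to SNP order and joint allele flips,
           and sign-equivariant in the outcome", {
  set.seed(61)
  L <- 30
  bx <- rnorm(L, 0, 0.05); sx <- runif(L, 0.002, 0.005)
  sy <- runif(L, 0.004, 0.01)
  by <- 0.15 * bx + rnorm(L, 0, 1.5 * sy)
  h <- make_h(bx, sx, by, sy)

  run_all <- function(h) {
    list(fe = mr_ivw_fe(h), mre = mr_ivw_mre(h), eg = mr_egger(h),
         wm = mr_weighted_median(h, n_boot = 100, seed = 2),
         q = cochran_q(h))
  }
  base <- run_all(h)

  perm <- sample(L)
  hp <- make_h(bx[perm], sx[perm], by[perm], sy[perm],
               snp = sprintf("rs%03d", perm))
  permd <- run_all(hp)
  for (m in c("fe", "mre", "eg")) {
    get_beta <- function(r) if (m == "eg") r$eg$estimate$beta else r[[m]]$beta
    expect_equal(get_beta(permd), get_beta(base), tolerance = 1e-12)
  }
  expect_equal(permd$wm$beta, base$wm$beta, tolerance = 1e-12)
  expect_equal(permd$q$Q, base$q$Q, tolerance = 1e-10)

  # joint allele flip of a subset of SNPs
  flip <- seq(1, L, by = 3)
  bx2 <- bx; by2 <- by
  bx2[flip] <- -bx2[flip]; by2[flip] <- -by2[flip]
  hf <- make_h(bx2, sx, by2, sy)
  flipped <- run_all(hf)
  expect_equal(flipped$fe$beta, base$fe$beta, tolerance = 1e-12)
  expect_equal(flipped$eg$estimate$beta, base$eg$estimate$beta, tolerance = 1e-12)
  expect_equal(flipped$eg$intercept$estimate, base$eg$intercept$estimate,
               tolerance = 1e-12)
  expect_equal(flipped$wm$beta, base$wm$beta, tolerance = 1e-12)

  # negating the outcome negates estimates and preserves p-values
  hn <- make_h(bx, sx, -by, sy)
  neg <- run_all(hn)
  expect_equal(neg$fe$beta, -base$fe$beta, tolerance = 1e-12)
  expect_equal(neg$fe$pvalue, base$fe$pvalue, tolerance = 1e-12)
  expect_equal(neg$mre$pvalue, base$mre$pvalue, tolerance = 1e-12)
  expect_equal(neg$eg$estimate$beta, -base$eg$estimate$beta, tolerance = 1e-12)
  expect_equal(neg$eg$estimate$pvalue, base$eg$estimate$pvalue, tolerance = 1e-12)
})

test_that("the suite's primary method follows the heterogeneity rule", {
  set.seed(71)
  L <- 40
  bx <- rnorm(L, 0, 0.05); sy <- runif(L, 0.004, 0.01)

  by_hom <- 0.1 * bx + rnorm(L, 0, 0.2 * sy)
  s_hom <- uvmr_suite(make_h(bx, 1e-6, by_hom, sy),
                      config = list(n_boot = 100, run_presso = FALSE))
  expect_gte(s_hom$heterogeneity$pvalue, 0.05)
  expect_identical(s_hom$primary, "IVW-FE")

  by_het <- 0.1 * bx + rnorm(L, 0, 3 * sy)
  s_het <- uvmr_suite(make_h(bx, 1e-6, by_het, sy),
                      config = list(n_boot = 100, run_presso = FALSE))
  expect_lt(s_het$heterogeneity$pvalue, 0.05)
  expect_identical(s_het$primary, "IVW-MRE")
  expect_identical(s_het$primary_estimate$beta, s_het$estimates$`IVW-FE`$beta)
  expect_gte(s_het$primary_estimate$se, s_het$estimates$`IVW-FE`$se)

  # odds-ratio scale is consistent with the log-scale estimate
  s_or <- uvmr_suite(make_h(bx, 1e-6, by_hom, sy),
                     config = list(n_boot = 100, run_presso = FALSE,
                                   exponentiate = TRUE))
  expect_equal(s_or$primary_estimate$or,
               exp(s_or$primary_estimate$beta), tolerance = 1e-10)
})

test_that("reverse MR runs role-swapped and degrades gracefully", {
  # a bidirectional world: both directions significant
  sim <- simulate_sumstats(mr_scenario("bidirectional", seed = 6))
  cfgq <- list(n_boot = 100, n_sim = 200, run_presso = FALSE)
  sel <- select_instruments(sim$exposure, sim$ld)
  h <- harmonize(list(exposure = sel$data, outcome = sim$outcome))
  fwd <- uvmr_suite(h, cfgq)
  rev <- reverse_mr(sim$outcome, sim$exposure, sim$ld, config = cfgq)
  expect_true(rev$evaluable)
  expect_lt(fwd$primary_estimate$pvalue, 0.05)
  expect_lt(rev$primary$pvalue, 0.05)

  # outcome with no significant SNPs: structured not-evaluable result
  sim0 <- simulate_sumstats(mr_scenario("null", seed = 6))
  rev0 <- reverse_mr(sim0$outcome, sim0$exposure, sim0$ld, config = cfgq)
  expect_false(rev0$evaluable)
  expect_match(rev0$reason, "instruments")
})
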