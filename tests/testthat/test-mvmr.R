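# Three-role harmonized set straight from matrices.
make_h3 <- function(bx1, bx2, by, sy, s1 = 0.002, s2 = 0.002,
                    roles = c("exp1", "exp2", "outcome")) {
  d <- data.frame(snp_id = sprintf("rs%03d", seq_along(by)),
                  stringsAsFactors = FALSE)
  d[[paste0("beta_", roles[1])]] <- bx1; d[[paste0("se_", roles[1])]] <- s1
  d[[paste0("beta_", roles[2])]] <- bx2; d[[paste0("se_", roles[2])]] <- s2
  d[[paste0("beta_", roles[3])]] <- by;  d[[paste0("se_", roles[3])]] <- sy
  as_harmonized_set(d, roles = roles)
}

test_that("an all-zero co-exposure reduces MVMR to the univariable fit", {
  set.seed(4)
  L <- 25
  bx <- rnorm(L, 0, 0.05); sy <- runif(L, 0.004, 0.01)
  by <- 0.2 * bx + rnorm(L, 0, sy)
  mv <- mvmr_ivw(make_h3(bx, rep(0, L), by, sy))
  uv <- mr_ivw_fe(make_h(bx, 0.002, by, sy))
  expect_equal(unname(mv$betas["exp1"]), uv$beta, tolerance = 1e-12)
  expect_true(is.na(mv$betas["exp2"]))
  expect_identical(mv$excluded, "exp2")
})

test_that("MVMR matches weighted least squares and recovers a mediator's direct effect", {
  set.seed(19)
  for (i in 1:10) {
    L <- sample(10:50, 1)
    bx1 <- rnorm(L, 0, 0.05); bx2 <- rnorm(L, 0, 0.1)
    sy <- runif(L, 0.004, 0.01)
    by <- 0.1 * bx1 - 0.2 * bx2 + rnorm(L, 0, sy)
    mv <- mvmr_ivw(make_h3(bx1, bx2, by, sy))
    fit <- lm(by ~ 0 + bx1 + bx2, weights = 1 / sy^2)
    expect_equal(unname(mv$betas), unname(coef(fit)), tolerance = 1e-10)
  }

  # mediator model: direct effects recovered within 2 se in >= 90% of reps
  set.seed(29)
  hits <- replicate(200, {
    L <- 80
    gam <- c(rnorm(L / 2, 0, 0.05), rep(0, L / 2))   # exposure loci
    del <- c(rep(0, L / 2), rnorm(L / 2, 0, 0.1))    # mediator-specific loci
    bm <- 0.5 * gam + del + rnorm(L, 0, 0.005)
    sy <- runif(L, 0.004, 0.01)
    theta_direct <- -0.03; theta_my <- -0.15
    by <- theta_direct * gam + theta_my * (0.5 * gam + del) + rnorm(L, 0, sy)
    mv <- mvmr_ivw(make_h3(gam, bm, by, sy,
                           roles = c("exposure", "mediator", "outcome")))
    abs(mv$betas[["mediator"]] - theta_my) <= 2 * mv$ses[["mediator"]]
  })
  expect_gte(mean(hits), 0.9)
})

test_that("collinear exposures raise an error naming the offenders", {
  set.seed(2)
  L <- 20
  bx <- rnorm(L, 0, 0.05); sy <- runif(L, 0.004, 0.01)
  by <- 0.1 * bx + rnorm(L, 0, sy)
  expect_error(mvmr_ivw(make_h3(bx, bx, by, sy)),
               class = "mr_collinearity_error")
  err <- tryCatch(mvmr_ivw(make_h3(bx, bx, by, sy)), error = identity)
  expect_match(conditionMessage(err), "exp")
})

test_that("single-exposure MVMR collapses to IVW under both heterogeneity regimes", {
  set.seed(9)
  L <- 30
  bx <- rnorm(L, 0, 0.05)
  sy <- runif(L, 0.004, 0.01)

  # homogeneous: Q/df <= 1 virtually surely with tiny noise -> FE se
  by_hom <- 0.1 * bx + rnorm(L, 0, 0.1 * sy)
  h2_hom <- as_harmonized_set(
    data.frame(snp_id = sprintf("rs%03d", 1:L), beta_x = bx, se_x = 0.002,
               beta_outcome = by_hom, se_outcome = sy, stringsAsFactors = FALSE),
    roles = c("x", "outcome"))
  mv <- mvmr_ivw(h2_hom)
  fe <- mr_ivw_fe(h2_hom, exposure = "x")
  expect_equal(unname(mv$betas[[1]]), fe$beta, tolerance = 1e-10)
  if (cochran_q(h2_hom, exposure = "x")$Q <= L - 1) {
    expect_equal(unname(mv$ses[[1]]), fe$se, tolerance = 1e-10)
  }

  # strongly heterogeneous: Q significant -> MRE se
  by_het <- 0.1 * bx + rnorm(L, 0, 4 * sy)
  h2_het <- as_harmonized_set(
    data.frame(snp_id = sprintf("rs%03d", 1:L), beta_x = bx, se_x = 0.002,
               beta_outcome = by_het, se_outcome = sy, stringsAsFactors = FALSE),
    roles = c("x", "outcome"))
  mv2 <- mvmr_ivw(h2_het)
  mre <- mr_ivw_mre(h2_het, exposure = "x")
  expect_lt(cochran_q(h2_het, exposure = "x")$pvalue, 0.05)
  expect_equal(unname(mv2$betas[[1]]), mre$beta, tolerance = 1e-10)
  expect_equal(unname(mv2$ses[[1]]), mre$se, tolerance = 1e-10)
})

test_that("estimates are invariant to exposure column order", {
  set.seed(13)
  L <- 30
  bx1 <- rnorm(L, 0, 0.05); bx2 <- rnorm(L, 0, 0.1)
  sy <- runif(L, 0.004, 0.01)
  by <- 0.1 * bx1 - 0.2 * bx2 + rnorm(L, 0, sy)
  a <- mvmr_ivw(make_h3(bx1, bx2, by, sy))
  d <- data.frame(snp_id = sprintf("rs%03d", 1:L),
                  beta_exp2 = bx2, se_exp2 = 0.002,
                  beta_exp1 = bx1, se_exp1 = 0.002,
                  beta_outcome = by, se_outcome = sy, stringsAsFactors = FALSE)
  b <- mvmr_ivw(as_harmonized_set(d, roles = c("exp2", "exp1", "outcome")))
  expect_equal(a$betas[c("exp1", "exp2")], b$betas[c("exp1", "exp2")],
               tolerance = 1e-12)
})

test_that("MVMR direct effect of a non-causal exposure shrinks with instrument count", {
  set.seed(37)
  med_abs <- vapply(c(25, 50, 100, 200), function(L) {
    median(replicate(120, {
      gam <- rnorm(L, 0, 0.05)
      bm <- 0.5 * gam + rnorm(L, 0, 0.02)  # mediator fully driven by exposure
      sy <- rep(0.006, L)
      by <- -0.15 * bm + rnorm(L, 0, sy)   # pure mediation, no direct path
      mv <- mvmr_ivw(make_h3(gam, bm, by, sy,
                             roles = c("exposure", "mediator", "outcome")))
      abs(mv$betas[["exposure"]])
    }))
  }, 1)
  # attenuation toward zero as instruments accumulate
  expect_lt(med_abs[3], med_abs[1])
  expect_lt(med_abs[4], med_abs[2])
  expect_lt(med_abs[4], med_abs[1])
})

test_that("joint instrument selection pools, de-duplicates and clumps candidates", {
  # disjoint significant sets with no LD: the union is kept
  e1 <- make_stats(10, pvalue = rep(1e-10, 10), beta = 0.1, se = 0.005,
                   pos = seq(1e6, by = 2e7, length.out = 10))
  e2 <- make_stats(12, pvalue = rep(1e-10, 12), beta = 0.1, se = 0.005,
                   pos = seq(2.1e8, by = 2e7, length.out = 12),
                   snp_id = sprintf("rs9%02d", 1:12))
  both <- rbind(e1, e2)
  e1_all <- both; e1_all$pvalue[11:22] <- 0.5   # only first 10 significant for e1
  e2_all <- both; e2_all$pvalue[1:10] <- 0.5
  sel <- select_mvmr_instruments(list(a = e1_all, b = e2_all), ld = NULL)
  expect_setequal(sel$snps, both$snp_id)

  # a SNP significant for both exposures is counted once
  e2_shared <- e2_all; e2_shared$pvalue[1] <- 1e-12
  sel2 <- select_mvmr_instruments(list(a = e1_all, b = e2_shared), ld = NULL)
  expect_equal(sum(sel2$snps == "rs001"), 1)

  # joint clumping equals the brute-force oracle on the pooled list
  set.seed(43)
  n <- 24
  pool <- make_stats(n, chrom = as.character(sample(1:2, n, replace = TRUE)),
                     beta = 0.1, se = 0.005,
                     pos = sample(1e6:2e7, n), pvalue = 10^(-runif(n, 8, 14)))
  pa <- pool; pb <- pool
  pb$pvalue <- 10^(-runif(n, 8, 14))
  ld <- random_ld(pool$snp_id, density = 0.5)
  sel3 <- select_mvmr_instruments(list(a = pa, b = pb), ld$sparse)
  pooled <- pool
  pooled$pvalue <- pmin(pa$pvalue, pb$pvalue)
  expect_setequal(sel3$snps, oracle_clump(pooled, ld$dense, 0.001, 10000))

  # too few joint instruments is a structured error
  tiny <- make_stats(2, pvalue = c(1e-10, 0.5), beta = 0.1, se = 0.005)
  expect_error(select_mvmr_instruments(list(a = tiny, b = tiny), ld = NULL),
               class = "mr_no_instruments")
})
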