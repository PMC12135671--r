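---
title: "Two-step Mendelian randomization mediation with mrmediate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-step Mendelian randomization mediation with mrmediate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrmediate)
```

# The procedure and its assumptions

`mrmediate` estimates how much of a causal exposure–outcome effect flows
through an intermediate trait, using only GWAS summary statistics. The
design is two-sample, two-step Mendelian randomization:

1. **Total effect** β₀: univariable MR of the outcome on the exposure's
   instruments.
2. **Step 1** β₁: univariable MR of each candidate mediator on the same
   instruments (log-odds scale when the mediator is a binary disease
   trait).
3. **Step 2** β₂: multivariable MR of the outcome on exposure and mediator
   jointly, so β₂ is the mediator's *direct* effect conditional on the
   exposure.
4. **Mediation**: indirect effect β₁β₂, proportion mediated β₁β₂/β₀, with a
   delta-method interval.

Every MR step leans on the three instrumental-variable assumptions:
instruments associate with their trait (enforced by the genome-wide
p ≤ 5×10⁻⁸ filter and the F ≥ 10 weak-instrument screen), are independent
of confounders, and affect downstream traits only through their trait
(probed, not guaranteed, by the Egger intercept, MR-PRESSO and the
weighted median). Step 2 additionally assumes the instrument set is
jointly valid for both exposures and that their effects combine linearly.
Mixing a log-odds β₁ with linear β₀ and β₂ follows field practice for
binary mediators; the product β₁β₂ then inherits the noncollapsibility of
the odds ratio, which we document rather than correct.

A mediator is *reported* only when three screens pass: (1)
unidirectionality — reverse-direction MR (outcome→exposure and
mediator→exposure) finds no significant back-effect at 0.05, where a
reverse analysis that cannot run for lack of outcome-trait instruments
counts as a pass with a recorded caveat; (2) robustness — the
mediator→outcome effect is significant both with and without exposure
adjustment, at the Bonferroni-adjusted threshold α/(mediators × outcomes);
(3) sign consistency — sign(β₁β₂) = sign(β₀). Reverse screens deliberately
use unadjusted 0.05: they are falsification tests, where leniency is
conservative for the final report.

# Estimators and numerical choices

**Wald ratios and IVW.** Per-SNP ratios β_Yj/β_Xj carry first-order
standard errors SE_Yj/|β_Xj| (second-order terms are negligible once
F ≥ 10, which bounds the relative error of β_Xj). IVW-FE is their
inverse-variance-weighted mean — algebraically a zero-intercept weighted
regression of β_Y on β_X with weights 1/SE_Y², an identity the test suite
checks against `lm()` to 10⁻¹⁰. IVW-MRE multiplies the standard error by
max(1, √(Q/(L−1))); the floor at 1 means the random-effects interval never
undercuts the fixed-effect one, and under homogeneity the two coincide
exactly. The primary estimate switches from FE to MRE when the Q-test
p-value drops below `q_alpha` (default 0.05); the point estimate is
unaffected.

**MR-Egger.** The fit is not invariant to per-SNP allele orientation, so
exposure effects are oriented non-negative (flipping β_X and β_Y jointly)
before the weighted regression with a free intercept. Slope and intercept
standard errors carry the same multiplicative max(1, √(RSS/(L−2))) factor,
and inference uses t with L−2 degrees of freedom, the small-sample
convention for Egger; the IVW and median estimators use normal quantiles
(1.959964 for 95%). The floored factor makes the intercept test mildly
conservative when the data are underdispersed; at the instrument counts
this package targets (L ≈ 80–180) the distortion is within Monte-Carlo
noise of uniformity, which the test suite verifies by a Kolmogorov–Smirnov
check on 2,000 null datasets.

**Weighted median.** Ratios are sorted, weights normalized, and the
estimate interpolates the weighted quantile at 0.5 on the centered
cumulative weights s_j − w′_j/2. The standard error is a parametric
bootstrap (default 1,000 replicates, ratio_j resampled from
Normal(ratio_j, ratio_se_j), seed from the configuration) — reproducible by
construction, and the bootstrap leaves the caller's RNG state untouched.

**MR-PRESSO.** The observed statistic sums weighted squared residuals of
each SNP's outcome effect from its leave-one-out IVW prediction; the null
distribution comes from parametric simulation (default 1,000 draws) of
both β_X and β_Y. The global p-value is the usual (1 + #exceedances)/(n_sim
+ 1). A SNP is an outlier when its own contribution's empirical p-value
falls below α/L (Bonferroni). Because the empirical p cannot fall below
1/(n_sim + 1), resolving α/L requires n_sim ≥ L/α; `mr_presso()` warns
when it cannot. The corrected estimate re-runs IVW (same Q rule) without
the flagged SNPs. The distortion test is out of scope.

**MVMR.** Zero-intercept weighted least squares of β_Y on the matrix of
exposure effects, closed form via the normal equations, with the
overdispersion factor max(1, √(RSS/(L−k))) applied to the standard errors
for consistency with the univariable treatment. Rank deficiency raises an
error naming the collinear exposures; an exposure whose effects are
identically zero is dropped from the fit and reported as NA, so the
remaining estimates reduce exactly to the nested model. With one exposure
the point estimate equals IVW exactly; the standard error equals the FE one
when Q ≤ L−1 and the MRE one when heterogeneity is significant, and sits
between the two in the narrow intermediate regime — a deliberate
consequence of using the unconditional factor rather than the switching
rule inside the regression.

**Joint instruments for MVMR** are the union of each exposure's
genome-wide-significant SNPs, restricted to SNPs present in every dataset,
clumped greedily on the smallest p-value across exposures, with the
strength screen applied to each SNP's strongest exposure association. This
is the standard recipe; nothing in it is specific to which exposure is
"the" exposure, so estimates are invariant to column order.

**Delta-method interval.** Var(ind) = β₁²var₂ + β₂²var₁ under independence
of the three estimates (they come from non-overlapping two-sample fits;
the shared exposure-instrument noise induces a positive β₀–β₁ correlation
that makes independence conservative for the ratio). By default the
proportion's variance includes the β₀ term, (ind²/β₀⁴)var₀; setting
`include_var0 = FALSE` reproduces the simpler variant that treats the
total effect as fixed — with published interval widths as inputs, that
variant reproduces a published mediation interval almost digit-for-digit,
suggesting it is what analyses in this literature typically report. The
interval is symmetric about the point estimate by construction; it is not
a Fieller interval, and when |β₀| is within ~2.5 standard errors of zero
the proportion's sampling distribution is visibly asymmetric and the
symmetric interval undercovers slightly (see *Limitations*).

# Harmonization

Roles are intersected on SNP id (ids are the join key; positions serve only
clumping windows, since datasets disagree on genome builds). For each SNP,
a role reconcilable with the exposure's allele pair by a label swap gets
its effect negated and frequency complemented; by a strand complement,
accepted unchanged; by both, negated; by neither, dropped. Palindromic
SNPs (A/T, G/C) cannot be disambiguated from labels: under the default
`drop-all` policy they are excluded outright; under `drop-ambiguous` they
are retained when every role's effect-allele frequency is outside
0.5 ± `eaf_window` (default 0.08), with orientation inferred from which
side of 0.5 the frequencies fall. After alignment each SNP is put in a
canonical orientation (alphabetically first allele as effect allele, all
roles flipped together). Canonicalization is what makes harmonization
idempotent and exactly invariant to how any input record — including the
exposure's — happened to be oriented; all estimators are invariant to the
joint flips it introduces. Indels and multi-allelic records are rejected
at read time; alleles are upper-cased.

# The synthetic-data generator

`simulate_sumstats()` draws a complete multi-trait panel with known truth,
emulating the statistical structure of large-biobank summary data:

- **Architecture.** `n_snps` independent exposure loci (default 200), each
  emitting `ld_block_size` correlated variants (default 5, within-block
  r² = 0.6) so clumping does real work; each binary mediator gets
  `n_med_snps` loci of its own (default 150) — without mediator-specific
  instruments the MVMR design matrix is near-collinear and the direct
  effect is unidentified, and real disease mediators do have their own
  GWAS hits; optional outcome-specific loci with a back-effect support
  bidirectional scenarios.
- **Scales.** Effect-allele frequencies are uniform on [0.05, 0.5],
  avoiding degenerate standard errors while keeping palindrome-ambiguity
  meaningful. SE = 1/√(2p(1−p)n) for continuous traits and
  1/√(2p(1−p)n·φ(1−φ)) for binary ones (φ = case fraction, default 0.05,
  log-odds scale) — the standard per-SD and logistic approximations,
  monotone in n. True lead effects are centered normal with sd
  `instrument_zscale` (default 20) times the median SE, so about 79% of
  loci reach p ≤ 5×10⁻⁸ — matching the instrument yields (roughly 120–180
  from 200 loci) reported for well-powered lipid exposures. Satellites
  carry the lead effect attenuated by √r², consistent with LD tagging.
- **Defaults mirror the motivating study sizes**: exposure n = 435,744,
  outcome n = 56,284, mediator n = 977,323; total effect −0.04 per SD.
- **Perturbations.** `het_multiplier` inflates the outcome's sampling
  noise but not its reported SE, planting genuine heterogeneity
  (Q/df ≈ multiplier²); `pleiotropy_*` adds direct outcome effects to a
  fraction of exposure SNPs (directional when the mean is nonzero — the
  Egger intercept's target); `n_outliers` plants offsets of 5–10 reported
  SEs on significant lead SNPs; `palindrome_frac` and `swap_frac` are pure
  representation stressors that harmonization must undo exactly —
  stressors draw from a separate random stream, so the same seed with and
  without them shares identical underlying effects, which the test suite
  exploits for exact round-trip checks.

The frozen scenario registry (`mr_scenario()`) pins the study conditions
used throughout the tests and the validation script: a mediation scenario
with true proportion 0.19 (180 exposure + 160 mediator loci, heterogeneity
multiplier 1.5), a null scenario (100 single-SNP loci, all effects zero),
directional pleiotropy (mean 0.02), outlier contamination (3 among 100),
and a bidirectional world whose back-effect (−0.01) is kept small enough
that outcome loci do not leak through the exposure's significance filter —
a leaked outcome instrument has Wald ratio ≈ 1/back-effect and would
dominate Cochran's Q, which is itself an instructive failure mode of
forward MR under reverse causation.

What the generator does **not** emulate: realistic LD from reference
panels (blocks are exchangeable and block-diagonal), winner's-curse-free
replication instruments, sample overlap between the two samples,
population stratification, or genuinely nonlinear mediator links. Passing
tests therefore certify the statistical machinery under the stated
generative model, not robustness to those real-data features.

# Problem sizes in the validation suite

The test suite and `scripts/acceptance.R` size their simulations to be
informative while remaining quick to run end-to-end: 2,000 replicates for
null calibration (size of the IVW test within [0.03, 0.07]; KS uniformity
of the Egger intercept p at α = 0.01), 200 replicates of the mediation
scenario for recovery (median proportion within [0.14, 0.24]; delta
interval coverage within [90%, 98%]), 100 contaminated replicates for
MR-PRESSO (all three planted outliers flagged in ≥ 95%, with n_sim = 2,000
so the Bonferroni threshold is resolvable at L ≈ 80), 1,000 random
instances for the IVW/regression identity and 200 for clumping against a
brute-force oracle.

# Limitations

- **Delta-interval coverage at moderate β₀ significance.** At the mediation
  scenario's conditions the total effect has |z| ≈ 2.5, and measured
  coverage of the symmetric 95% interval sits essentially on 90%: the
  reported (MRE) standard error of β₀ cannot see the across-replicate
  variation induced by instrument re-selection and winner's curse (about a
  10% shortfall), and the proportion's distribution is right-skewed in
  1/β₀, so misses concentrate where β₀ overshoots. A Fieller-type interval
  would repair the shape at the cost of occasionally unbounded sets; the
  field reports the symmetric delta interval, and so does this package.
- **Winner's curse.** Instruments are selected and estimated in the same
  exposure sample, attenuating β₀ and β₁ multiplicatively by the same
  factor (cancelling in the proportion) and β₂ through the mediator's
  selection (not cancelling; about 1–2% at default instrument strength).
- **Noncollapsibility** of the log-odds β₁ in the mediation product, as
  noted above.
- The MR-PRESSO distortion test, Steiger filtering, proxy-SNP lookup,
  liftover and VCF ingestion are out of scope; the MVMR conditional
  F-statistic field is reserved but not computed.
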