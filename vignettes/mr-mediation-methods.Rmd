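---
title: "Methods: two-sample MR screening and two-step mediation"
author: "mrmediate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample MR screening and two-step mediation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrmediate)
```

## The problem

Two-sample Mendelian randomization (MR) estimates the causal effect of an
exposure (here: the abundance of a gut microbial taxon, or a plasma
protein-to-protein ratio) on an outcome (a binary liver-disease phenotype on
the log-odds scale) using only GWAS summary statistics: per-SNP marginal
effect estimates $\hat\beta_{X i}$ from one study and $\hat\beta_{Y i}$ from
another. A SNP is a valid instrument when it affects the outcome only
through the exposure; the package implements the selection machinery that
tries to enforce this, six estimators with different robustness profiles,
the standard sensitivity diagnostics, batch screening with
false-discovery-rate control, and a two-step mediation analysis that routes
an exposure effect through an intermediate molecular trait.

Because the real microbiome, proteomic and biobank GWAS inputs are external
resources, every claim the package makes about itself is established on
synthetic summary statistics with known ground truth; the simulator is
first-class, tested code.

## Instrument selection

Selection follows five criteria, in pipeline order:

1. **p-value threshold.** SNPs with exposure $p < 5\times10^{-8}$; when
   fewer than `min_snps_for_primary` (default 3) qualify, the relaxed
   threshold $p < 10^{-5}$ is used and reported. The trigger count is not a
   standardized constant; 3 is the package's default and is configurable.
2. **MAF filter.** $\min(f, 1-f) > 0.01$.
3. **Instrument strength.** Per-SNP $F = (\hat\beta/\mathrm{se})^2 > 10$.
   This is the large-sample approximation to the first-stage F; the
   $r^2$-based form $(n-2)r^2/(1-r^2)$ agrees closely at GWAS sample sizes.
4. **LD clumping.** Greedy: take the most significant remaining SNP as
   index, discard SNPs on the same chromosome within 10,000 kb with
   $r^2 > 0.001$ against it; ties in $p$ break lexicographically by variant
   id so the result is deterministic. The LD matrix is supplied by the user
   or the simulator; no remote reference panel is consulted.
5. **Steiger directionality.** A SNP explaining at least as much variance in
   the outcome as in the exposure likely acts on the outcome first and is
   removed. Variance explained is
   $r^2 = \hat\beta^2 v / (\hat\beta^2 v + \mathrm{se}^2 v n)$ with
   $v = 2f(1-f)$; a z-test on the difference of Fisher-transformed
   correlations is reported for transparency, but removal is keyed on the
   direction alone, because the procedure is a removal rule, not a test.

For a binary outcome the Steiger $r^2$ uses log-odds effects with the
study's reported total $n$ (the summary-statistic schema carries no
case/control split). Since the SEs of a low-prevalence case-control GWAS
correspond to a much smaller effective sample size, this deflates the
outcome-side $r^2$ and makes the filter *conservative* — it essentially
never removes forward instruments, but its power against reverse SNPs is
reduced. The reverse-instrument calibration study therefore uses a
quantitative outcome, where the removal rate of simulated reverse-causal
SNPs is effectively 100%.

## Estimators

With Wald ratios $\hat\theta_i = \hat\beta_{Yi}/\hat\beta_{Xi}$ and ratio
weights $w_i = \hat\beta_{Xi}^2/\mathrm{se}_{Yi}^2$:

- **Wald ratio** (single instrument): $\hat\beta_Y/\hat\beta_X$ with the
  first-order delta SE $\mathrm{se}_Y/|\hat\beta_X|$.
- **IVW** (primary): weighted regression of $\hat\beta_Y$ on $\hat\beta_X$
  through the origin with weights $1/\mathrm{se}_Y^2$, equal to the
  inverse-variance-weighted mean of the ratios. The default multiplicative
  random-effects model inflates the fixed-effect SE by
  $\max(1, \sqrt{Q/(k-1)})$; fixed effects are available by flag. The
  choice of default follows common practice for summary-data MR.
- **Maximum likelihood**: the profile likelihood of
  $\hat\beta_{Xi}\sim N(\xi_i, \mathrm{se}_{Xi}^2)$,
  $\hat\beta_{Yi}\sim N(b\,\xi_i, \mathrm{se}_{Yi}^2)$ reduces, after
  profiling the $\xi_i$, to minimizing
  $\sum_i (\hat\beta_{Yi}-b\hat\beta_{Xi})^2/(\mathrm{se}_{Yi}^2+b^2\mathrm{se}_{Xi}^2)$.
  The search starts at the IVW estimate with an expanding bracket
  (tolerance $10^{-10}$, error after 200 expansions); the SE comes from the
  numerical curvature of the profile log-likelihood at the optimum.
- **MR-Egger**: weighted least squares with an intercept after orienting
  every SNP to a non-negative exposure effect (required for the intercept
  to be identifiable). SEs scale by $\max(1,\sqrt{\mathrm{RSS}_w/(k-2)})$;
  inference uses $t_{k-2}$. The intercept estimates directional pleiotropy.
- **Weighted median**: interpolated weighted percentile of the ratios at
  0.5; consistent when valid instruments carry a majority of weight. SE by
  parametric bootstrap (exposure and outcome effects resampled from their
  sampling distributions) with a mandatory explicit seed.
- **Simple/weighted mode**: the argmax over a 512-point grid of a Gaussian
  kernel density over the ratios, bandwidth
  $0.9\min(\mathrm{SD},\mathrm{MAD})k^{-1/5}$ (MAD on the consistent normal
  scale) times a user factor; degenerate all-equal ratios return the common
  value. SE by the same bootstrap.

Dispatch: one instrument gives the Wald ratio; two give IVW and maximum
likelihood; three or more give all six multi-instrument methods. The
"seventh" label in the result schema, `wald_ratio`, appears only for
single-instrument analyses — it has no defined multi-instrument analogue.

Confidence intervals use the exact normal (or $t_{k-2}$ for Egger) 97.5%
point rather than the rounded 1.96, so that "CI excludes zero" and
"$p<0.05$" never disagree.

## Sensitivity diagnostics

- **Cochran's Q / $I^2$** on the ratios about the IVW estimate,
  $\chi^2_{k-1}$ reference, $I^2 = \max(0,(Q-\mathrm{df})/Q)$.
- **MR-PRESSO.** The observed weighted residual sum of squares uses
  leave-one-out IVW fits as each SNP's expected value (the residual
  definition is fixed and documented here because the published procedure
  leaves it open). The null distribution comes from parametric simulation
  of both sides; empirical p-values use $(1+r)/(n_\mathrm{sim}+1)$ so they
  are never zero. Outlier p-values are per-SNP tail probabilities,
  Bonferroni-adjusted by $k$; the distortion test compares the
  outlier-removed IVW shift against the shift under random removal of
  equally many SNPs (index sets drawn without replacement from all SNPs).
  `n_sim` defaults to 1000 — calibration at desk scale; raise it for
  sharper tails.
- **Leave-one-out IVW**, flagging SNPs whose removal shifts the estimate
  outside the refit's CI.

## Screening and FDR

`run_screen()` executes the full pipeline per exposure and applies
Benjamini–Hochberg adjustment across exposures within the primary-method
family (one p-value per exposure: IVW, or Wald for a single instrument).
The family choice is the package's default — per-method families are
available by flag — and reports flag both nominal ($p<0.05$) and
FDR-significant calls. Reverse MR is the same machinery with the roles
swapped (`reverse = TRUE`). Exposures yielding no usable instruments are
listed in a skipped table, never silently dropped.

## Two-step mediation

With beta(A) the exposure→mediator effect, beta(B) the mediator→outcome
effect and the total effect from the primary analysis:
indirect $= A\times B$; direct $=$ total $-$ indirect (an identity by
construction); proportion mediated $= 100\,\times$ indirect/total. The
indirect-effect SE is first-order delta (Sobel),
$\sqrt{B^2\mathrm{se}_A^2 + A^2\mathrm{se}_B^2}$, treating the legs as
independent since they come from separate MR fits; the exact-variance
variant (adding $\mathrm{se}_A^2\mathrm{se}_B^2$) is available by flag.
The proportion's SE treats indirect and total as independent — their
covariance is unobtainable from summary data; this is a documented
limitation — and proportions outside $[0,100]\%$ (inconsistent mediation)
are reported with a flag, never truncated.

Two design choices in `two_step_mediation()` deserve emphasis:

- **Leg-B instrument exclusion.** Mediator instruments that are
  genome-wide significant for the exposure are excluded from the
  mediator→outcome leg. Such SNPs reach the outcome through the exposure's
  direct path as well as through the mediator, violating leg B's exclusion
  restriction; in chain simulations their inclusion visibly biases beta(B)
  away from the truth.
- **Leg estimator.** Each leg defaults to the profile maximum-likelihood
  estimate rather than IVW. A ratio-based leg is attenuated toward the
  null by roughly $1/\bar F$ because exposure-side sampling error sits in
  the ratio denominators, and the product $A\times B$ compounds the two
  attenuations; in calibration runs the IVW-legged decomposition showed a
  small but systematic downward bias in the indirect effect, while the
  ML-legged one is mean-unbiased. `leg_method = "ivw"` reproduces the
  conventional IVW decomposition.

## The simulator

`simulate_pair()`/`simulate_chain()` work on the standardized-genotype
scale: per-SNP joint exposure effects are $N(0, h^2/k)$, marginal effects
propagate through block LD ($\rho^{|i-j|}$ within blocks of configurable
size, zero across), sampling noise is drawn with the LD-implied correlation
at $\mathrm{se} = 1/\sqrt{n}$, and everything is rescaled per-allele by
$1/\sqrt{2f(1-f)}$ with MAF uniform on its configured range. Binary
outcomes are generated directly on the log-odds scale with SEs from the
effective sample size $4/(1/\mathrm{cases}+1/\mathrm{controls})$ — a
documented approximation that avoids individual-level logistic simulation.
Pleiotropic direct effects are drawn on the standardized scale (so their
variance is proportional to the outcome SE and multiplicative
random-effects weighting is correctly specified) and oriented by the sign
of the SNP's exposure effect, which makes a nonzero mean exactly the
directional pleiotropy MR-Egger's intercept targets. Reverse-causal SNPs
originate on the outcome with the exposure association induced through
`theta_rev`, scaled so they pass exposure-side selection and present the
structure Steiger filtering is designed to remove.

Reference defaults — chosen once as the package's study conditions — are 50
instruments at total $h^2 = 0.2$ (mean $F\approx200$, the strength of
protein-trait instruments; microbiome exposures are typically weaker, which
would widen every interval but not change calibration), 50,000 samples per
GWAS, a binary outcome with 0.7% case fraction (a biobank-scale liver
phenotype), causal effect $\theta=0.2$, chain $a=0.3$, $b=0.5$, $c'=0.1$,
no LD (the instrument panel emulates the post-clumping world; LD blocks are
switched on where clumping itself is under test), and `theta_rev = 0.3`.
All randomness descends from a single integer seed; identical configs give
identical bytes.

What the simulator does **not** emulate: real LD panels and allele-frequency
spectra, winner's-curse on externally selected instruments, sample overlap
between studies, population stratification, and the liability-scale link
for binary traits. Passing calibration here shows the machinery is correct
under its own assumptions, not that any real microbiome→liver-disease claim
is validated.

## Calibration studies and problem sizes

The `study_*()` functions re-run the pipeline over many simulated
replicates; the test suite and `scripts/acceptance.R` call them at 500
replicates (estimator recovery and Steiger removal), 2,000 (Q and Egger
intercept type-I error), 300 (mediation recovery), and 200 screens of 100
exposures (null FDR) — sizes at which Monte-Carlo error is small relative
to the effects checked while a full run completes in a few minutes on one
CPU. Estimators inside the calibration studies see selected instruments,
exactly as the pipeline delivers them; feeding them unfiltered panels
(including weak instruments that the F filter exists to remove) makes the
mode estimators erratic, which is a property of unfiltered data, not of the
estimators.

## Numerical choices

- Empirical p-values: $(1+r)/(n+1)$; analytic p-values floored at the
  smallest positive double and capped at 1.
- Clumping ties broken by variant id; export tables use fixed `%.6g`
  formatting so identical results are byte-identical.
- Numeric round trips: summary statistics are written with 17 significant
  digits, so write-then-read is the identity on doubles.
- `n` is stored as an integral-valued double (biobank sample sizes can
  exceed the 32-bit integer range).
- Degenerate inputs: zero exposure effects are a typed error for ratio
  methods; all-identical ratios return the common value with a bootstrap
  SE; a zero total effect leaves the mediated proportion undefined rather
  than infinite; harmonization with no overlapping variants is a typed
  error, while an empty post-filter table is a reported "skipped" outcome.

## Known limitations

- Palindromic-SNP policy (drop when either frequency is within 0.08 of 0.5
  or the aligned frequencies disagree) is a convention, not an inferred
  strand correction; true strand flips are dropped, not repaired.
- Steiger filtering is conservative for low-prevalence binary outcomes
  (see above).
- The proportion-mediated CI ignores the indirect/total covariance and is
  heavy-tailed when the total effect is imprecise; the indirect effect and
  its CI are the better-behaved summaries.
- No multivariable MR, correlated-instrument IVW, proxy-SNP lookup, or
  liftover; inputs are assumed to share a genome build and rsID space.
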