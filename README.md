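# mrmediate

Two-sample Mendelian randomization (MR) with two-step mediation analysis,
for epidemiologists asking not just *whether* an exposure affects an
outcome but *through what*. The motivating setting is environmental
epidemiology — e.g. whether long-term fine-particulate (PM2.5) exposure
shortens life indirectly through age-related diseases such as hypertension,
hypercholesterolaemia or Alzheimer's disease — but every function operates
on generic GWAS summary statistics.

## What it implements

MR uses genetic variants as instrumental variables: because alleles are
randomly assorted at meiosis, a SNP G that robustly associates with an
exposure X can proxy X free of the confounding that plagues observational
estimates. With per-SNP summary statistics from two samples (G→X effects
γ̂ⱼ ± σ_xⱼ, G→Y effects Γ̂ⱼ ± σ_yⱼ), the package provides:

- **Harmonization** of the two studies onto one effect-allele convention
  (allele flips negate Γ̂; palindromic A/T and C/G variants and
  allele-incompatible records are dropped and counted).
- **Instrument selection**: genome-wide significance (p < 5·10⁻⁸), greedy
  LD clumping (r² < 0.001 against a supplied LD matrix), and per-SNP
  strength F = (γ̂/σ_x)², flagging F < 10 as weak.
- **Univariable estimators**: per-SNP Wald ratios Γ̂ⱼ/γ̂ⱼ; the IVW estimate
  θ̂ = Σwⱼγ̂ⱼΓ̂ⱼ / Σwⱼγ̂ⱼ² with wⱼ = 1/σ_yⱼ² (fixed or multiplicative
  random effects); the weighted median (consistent with up to half the
  weight on invalid instruments), with parametric-bootstrap SE; MR-Egger
  regression, whose intercept estimates average directional pleiotropy.
- **MR-PRESSO**: a simulation-based residual-sum-of-squares global test for
  horizontal pleiotropy, per-SNP outlier detection with Bonferroni
  correction, outlier-corrected IVW re-estimation, and a distortion test.
- **Multivariable IVW**: direct effects of K exposures jointly,
  Γ̂ⱼ ≈ Σₖ θₖ γ̂ⱼₖ, with conditional instrument strength per exposure.
- **Two-step mediation**: step 1 estimates the exposure→mediator effect A,
  step 2 the mediator→outcome effect B (from the mediator's own
  instruments); the indirect effect is the product A·B with delta-method
  SE √(A²se_B² + B²se_A²), and the mediated proportion is
  100·|A·B / total| (clipped to [0,100]).
- **A summary-level simulator** with a machine-readable ground truth
  (configurable instrument strength, causal effect, pleiotropy mode, an
  exposure→mediator→outcome chain, LD blocks, palindromic and flipped
  records), so the whole chain is testable without any external GWAS.
- **`runStudy()`** orchestrates the full design: univariable screen across
  candidate mediators, sensitivity analyses, optional multivariable
  adjustment, gated mediation, Bonferroni flags, and a provenance log
  sufficient to reproduce the run bit-identically.

## Worked example

```r
library(mrmediate)

cfg <- simConfig(seed = 42, J = 40, nNullSNPs = 60, palindromicFrac = 0.1,
                 mediatorChain = list(a = 0.5, b = 0.4, cPrime = 0.1))
sim <- simulateSummaryStats(cfg)

sel <- selectInstruments(sim$exposure, sim$ld)
sel
#> InstrumentSelection: 39 SNP(s) (p < 5e-08, r2 < 0.001)
#>   mean F = 109.0; 0 weak (F < 10)

expSel <- asSummaryData(sim$exposure)
expSel <- SummaryStats(expSel[expSel$SNP %in% snpIds(sel), ])
h <- harmonize(expSel, sim$outcome)
h
#> HarmonizedSet: 37 SNP(s) (dropped 2 palindromic, 0 incompatible)

mrIVW(h)
#> MREstimate [ivw_mre], 37 SNP(s)
#>   beta = 0.2477 (se 0.08454), 95% CI [0.08199, 0.4134], p = 0.00339
#>   OR = 1.281, 95% CI [1.085, 1.512]
```

The true total effect here is a·b + c′ = 0.5·0.4 + 0.1 = 0.3; IVW recovers
0.25 ± 0.08, and the odds-ratio columns give the same estimate on the
exponentiated scale. The Egger intercept (−0.036 ± 0.036, p = 0.33) shows
no evidence of directional pleiotropy, as expected from a generator run
with pleiotropy off. Completing the two-step decomposition:

```r
selM   <- selectInstruments(sim$mediator, sim$ld)
medSel <- asSummaryData(sim$mediator)
medSel <- SummaryStats(medSel[medSel$SNP %in% snpIds(selM), ])

a   <- mrIVW(harmonize(expSel, sim$mediator))   # exposure -> mediator
b   <- mrIVW(harmonize(medSel, sim$outcome))    # mediator -> outcome
tot <- mrIVW(h)                                 # exposure -> outcome
twoStepMediation(a, b, tot)
#> Two-step MR mediation
#>   total = 0.2477 (se 0.08454); A = 0.4916 (se 0.02004); B = 0.276 (se 0.07819)
#>   indirect = 0.1357 (se 0.03884), 95% CI [0.05959, 0.2118], p = 0.000475
#>   mediated proportion = 54.79% [24.06%, 85.52%]
```

The truth is a mediated proportion of 100·(0.2/0.3) ≈ 66.7%; one finite
study recovers 54.8% with a CI comfortably covering it.

The same arithmetic applied to published coefficient tables — e.g. direct
effects A = −2.65 and B = −0.068 for diastolic blood pressure mediating
PM2.5's effect on reaching the 90th survival percentile — gives
`indirectEffect(-2.65, 0.676, -0.068, 0.0071)$beta` = 0.1802, printed as
0.18.

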