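---
title: "Methods: two-sample MR and two-step mediation in mrmediate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample MR and two-step mediation in mrmediate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrmediate)
```

## The model

Two-sample Mendelian randomization treats a genetic variant $G_j$ as an
instrument for an exposure $X$ on an outcome $Y$. Validity rests on three
assumptions: (1) relevance — $G_j$ is robustly associated with $X$; (2)
independence — $G_j$ is not associated with confounders of $X$–$Y$; (3)
exclusion restriction — $G_j$ affects $Y$ only through $X$. Under these,
each SNP's Wald ratio $\hat\theta_j = \hat\Gamma_j / \hat\gamma_j$ (outcome
association over exposure association) estimates the causal effect, and the
inverse-variance-weighted (IVW) estimator pools them:

$$\hat\theta_{IVW} = \frac{\sum_j w_j \hat\gamma_j \hat\Gamma_j}
                          {\sum_j w_j \hat\gamma_j^2},
  \qquad w_j = 1/\sigma_{yj}^2,$$

which is the weighted least-squares slope of $\hat\Gamma$ on $\hat\gamma$
through the origin. Assumption (1) is screened by genome-wide significance
and the per-SNP $F = (\hat\gamma/\sigma_x)^2$; assumption (2) is addressed
in study design by multivariable adjustment for measured co-exposures;
assumption (3) is probed by the MR-Egger intercept and MR-PRESSO.

Two-step mediation decomposes a total effect: step 1 estimates the
exposure→mediator effect $A$ with the exposure's instruments; step 2
estimates the mediator→outcome effect $B$ with the *mediator's own*
instruments. The indirect effect is the product $A \cdot B$ and the
mediated proportion is $100\,|AB/\text{total}|$.

## Tunable parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `pThreshold` | 5e-8 | p-value | conventional genome-wide significance; strict `<` |
| `r2Threshold` | 0.001 | squared correlation | conventional strict clumping; strict `<` |
| `weakFThreshold` | 10 | F statistic | conventional weak-instrument bound; flags, does not drop |
| IVW `mode` | mre if $J \ge 4$, else fixed | — | random-effects is conservative under heterogeneity but its residual scale is unstable below ~4 SNPs |
| `nBoot` (weighted median) | 1000 | resamples | bootstrap SE stable to ~3% at this size; seed mandatory |
| `nSim` (MR-PRESSO) | 5000 | simulations | empirical p resolution 1/5001; floor of 1000 enforced |
| `outlierAlpha` | 0.05 | level | Bonferroni-corrected across the $J$ per-SNP tests |
| CI multiplier | 1.96 | — | normal 95% intervals throughout; Egger p-values use $t_{J-2}$ |
| mediation gate | nominal 0.05 on step-1 IVW | p-value | configurable to the Bonferroni level; both flags always reported |

## Estimator details and numerical choices

**Wald ratio SE.** First-order delta: $\sigma_y/|\hat\gamma|$, ignoring
exposure-side noise. The second-order form (adding
$\hat\Gamma^2\sigma_x^2/\hat\gamma^4$) is kept as a test oracle; for
$F > 100$ they differ by under 5%, which is why the first-order form is the
field's default for genome-wide-significant instruments.

**IVW modes.** Fixed-effect SE is $(\sum w_j\hat\gamma_j^2)^{-1/2}$. The
multiplicative random-effects mode scales it by
$\max(1, \hat\sigma)$ with $\hat\sigma^2$ the weighted residual mean square
on $J-1$ df; the floor at 1 prevents an *under*-dispersed sample from
reporting less than the fixed-effect uncertainty. Consequently the
fixed-effect SE never exceeds the random-effects SE.

**Weighted median.** Wald ratios are ordered; the estimate is the linear
interpolation of the mid-point normalized cumulative weight function at
0.5 (weights: inverse Wald-ratio variance). The SE is a parametric
bootstrap — effects redrawn from their sampling normals — because no
closed form exists; the seed is a required argument so results are
reproducible by construction.

**MR-Egger.** SNPs are first oriented so $\hat\gamma_j \ge 0$ (the
estimator is otherwise not invariant to the arbitrary choice of effect
allele). Weighted least squares with free intercept; overdispersion is
handled multiplicatively with the same floor at 1; inference uses
$t_{J-2}$ because the small-$J$ intercept test is anti-conservative under
a normal reference. Forcing the intercept to zero reproduces fixed-effect
IVW exactly (a nesting identity the tests assert). The slope is consistent
under the InSIDE assumption (pleiotropy independent of instrument
strength).

**MR-PRESSO.** The observed statistic is the weighted residual sum of
squares around each SNP's leave-one-out IVW prediction; weighting by
$1/\sigma_{yj}^2$ makes per-SNP contributions comparable across
heteroscedastic instruments. The null distribution is parametric: outcome
effects are redrawn around the leave-one-out predictions with observed
SEs, and the leave-one-out fits are recomputed per draw. Empirical
p-values use the add-one convention $(r+1)/(n_{sim}+1)$, so no p is ever
exactly zero and Monte-Carlo error shrinks as $1/\sqrt{n_{sim}}$. Per-SNP
outliers are flagged at `outlierAlpha`$/J$ and removed; the corrected
estimate is literally `mrIVW()` on the surviving set. The distortion test
(raw-vs-corrected difference against same-size random removals) is
reported but never drives any automatic decision: removal is the only
automatic action.

**Multivariable IVW.** No-intercept weighted least squares of outcome
effects on the $K$ exposure-effect columns. Rank deficiency is detected
by pivoted QR and reported with the offending exposure labels.
Overdispersion is multiplicative on $J-K$ df, floored at 1, for
consistency with the univariable estimator (to which the $K=1$ case
reduces exactly). Conditional instrument strength is reported as the mean
squared standardized residual of regressing each exposure's SNP effects on
the others'; it is a flag, never an automatic filter. The instrument pool
is the union of each exposure's significant clumped instruments,
harmonized to the outcome study's allele convention so that all columns
share one reference.

**Mediation.** The delta-method SE uses the first-order Sobel form
$\sqrt{A^2 se_B^2 + B^2 se_A^2}$; published coefficient tables in this
design are consistent with the first-order form at printed precision, and
the second-order term is available behind a flag. The mediated proportion
is reported as a magnitude, because an indirect effect can oppose a
near-null total effect (ratios above 1 in magnitude clip to 100%); a
sign-discordant pair is flagged as "inconsistent mediation" with a warning
rather than an error. The proportion CI propagates the indirect effect's
CI through the ratio at fixed total — if the signed ratio interval spans
zero, the magnitude lower bound is 0 — with each bound clipped to
[0, 100]; a full bivariate delta CI is available via `method = "delta"`.
Estimates tagged as odds-ratio scale are refused: mediation arithmetic is
only valid on the additive (log-odds) scale.

**Harmonization.** Matching is by SNP identifier only (no chr:pos
fallback); duplicated identifiers are rejected rather than guessed at.
Palindromic variants are always dropped — no frequency-based rescue at
intermediate allele frequencies — because strand cannot be resolved from
alleles alone and the frequency heuristic trades a silent error mode for a
small gain in instrument count. Missing EAF is tolerated (alignment uses
alleles only; frequency is reporting-only).

## The simulator: what it emulates, what it does not

`simulateSummaryStats()` draws true SNP-exposure effects
$\gamma_j \sim N(\mu_\gamma, \sigma_\gamma)$ (defaults 0.1, 0.02 — with
default SE scales this gives per-SNP $F \approx 100$, i.e. the
strong-instrument regime of a well-powered GWAS), builds true outcome
effects $\theta\gamma_j + \alpha_j$ (plus $ab\gamma_j$ under a mediator
chain), and adds independent Gaussian noise at each study's SE scale.
Pleiotropy modes: `balanced` (zero-mean offsets, IVW stays consistent),
`directional` (constant offset, recovered by the Egger intercept),
`inside_violating` (offsets proportional to $\gamma_j$, breaking InSIDE).
Null SNPs, LD blocks, palindromic alleles and flipped-convention records
exercise selection and harmonization.

It deliberately does **not** emulate: individual genotypes or allele
frequencies' effect on precision, sample overlap between the two studies,
population structure, winner's-curse bias from selecting instruments in
the same sample, or non-Gaussian effect distributions. Passing tests
therefore certify the estimators' statistical behaviour under the stated
summary-level model, not robustness to those real-data pathologies.

Seeds are explicit everywhere (`simConfig`, the weighted-median bootstrap,
MR-PRESSO); nothing draws from an implicit RNG state, and package
functions restore the session RNG.

## Problem sizes in the validation suite

The simulation-based checks use: IVW recovery J=50 with 500 replicates;
type-I error J=30 with 5000 replicates (fixed-effect IVW, which is the
exactly calibrated test when SEs are known and heterogeneity absent — the
random-effects floor makes that mode deliberately conservative under the
null); Egger recovery J=100 with 500 replicates; weighted-median
robustness J=30, 40% invalid instruments, 500 replicates; MR-PRESSO
sensitivity/specificity J=30 with 200 replicates at 1000 simulations;
multivariable recovery J=60, K=2 with 300 replicates; mediation-chain
recovery J=100 with 200 replicates. These sizes give Monte-Carlo bands
well inside the asserted tolerances while keeping the default test run in
the order of a minute.

## Known limitations

- No correlated-instrument (generalized) IVW: the LD matrix is used for
  clumping only, and instruments are assumed independent afterwards.
- No mode-based estimators, Steiger filtering, MVMR-Egger or
  weak-instrument-robust MVMR.
- The weighted-median bootstrap redraws both studies' effects but keeps
  the weight structure of the observed data.
- The mediated-proportion CI conditions on the total effect; when the
  total is imprecise (as in the motivating application, where the total
  exposure–longevity effect is itself non-significant) the reported
  interval understates the full uncertainty — the `delta` method is the
  honest alternative there.
- MR-PRESSO simulates outcome effects only; the original formulation also
  redraws exposure effects, which matters little in the strong-instrument
  regime but is a difference worth knowing.
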