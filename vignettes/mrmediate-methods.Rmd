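---
title: "Methods: two-sample MR with two-step mediation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample MR with two-step mediation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrmediate)
```

## The design

Mendelian randomization (MR) uses genetic variants as instrumental
variables for a modifiable exposure: because alleles are assigned at
meiosis, a variant that robustly shifts the exposure supports a causal
reading of its association with an outcome, provided it is independent
of confounders and affects the outcome only through the exposure. In
the two-sample setting the variant–exposure effects $\hat\gamma_j$ (SE
$\sigma_{x,j}$) and variant–outcome effects $\hat\Gamma_j$ (SE
$\sigma_{y,j}$) come from non-overlapping studies, e.g. a microbiome
GWAS and a disease biobank GWAS, with outcome effects on the log-odds
scale so exponentiated estimates are odds ratios.

`mrmediate` implements the complete workflow of a bidirectional,
two-step mediation MR study: (1) a forward screen of many exposures
against one outcome, (2) reverse MR of the outcome against the forward
hits, (3) exposure-to-mediator and (4) mediator-to-outcome screens over
a panel of candidate mediators (e.g. 91 circulating inflammatory
proteins), and finally a decomposition of the total effect into direct
and mediated components for mediators significant in both steps.

## Instruments

Candidate instruments are variants with exposure association
$p < 10^{-5}$ (strict inequality), the customary relaxation for traits
such as microbial taxa with few genome-wide-significant loci. Greedy
clumping then enforces approximate independence: candidates are ranked
by p-value (ties broken lexicographically by identifier, making output
deterministic), the best remaining variant is accepted, and every
remaining variant with $r^2 \ge 0.001$ to an accepted one within
10,000 kb is discarded. Pairs on different chromosomes are never
clumped and a distance exactly equal to the window counts as inside;
without positions, all pairs count as inside. The LD source is any
user-supplied squared-correlation matrix — in tests and simulations a
synthetic block matrix, in applications typically one derived from a
European reference panel.

Instrument strength uses the summary-level variance explained
$$R^2 = \frac{2\beta^2 f(1-f)}{2\beta^2 f(1-f) + 2\,SE^2\,N\,f(1-f)},$$
which simplifies to $\beta^2/(\beta^2 + N\,SE^2)$ (the package computes
the full form and property-tests the identity to $10^{-12}$), and
$F = R^2(N-2)/(1-R^2)$, keeping $F > 10$. Strength is evaluated on the
exposure study, whose $\beta$, SE, EAF and $N$ enter the formula;
variants with missing EAF have incomputable strength and are excluded
with a warning.

## Harmonization

Both studies must code effects on the same allele. Where the outcome
study reports the swapped pair (or its strand complement), the outcome
beta is negated and the EAF replaced by $1-f$. Palindromic variants
(A/T, C/G) cannot be strand-resolved from alleles, so the package
infers orientation from allele frequency: both EAFs must fall outside
$0.5 \pm 0.08$ (i.e. outside 0.42–0.58, the de-facto community
default, exposed as `palindromic_eaf_window`); agreement on which
allele is minor keeps the coding, disagreement flips it, and anything
ambiguous — including a missing EAF — is dropped conservatively.
Indels and multi-allelic records are rejected at read time; this is a
SNP-only pipeline.

## Estimators

Per-variant Wald ratios $\hat\theta_j = \hat\Gamma_j/\hat\gamma_j$
carry the first-order delta SE $\sigma_{y,j}/|\hat\gamma_j|$, ignoring
exposure-side noise — the conventional choice, whose consequences are
discussed under *Limitations*. Five estimators combine them:

* **IVW** (primary): inverse-variance weighted mean of the ratios,
  equivalently weighted regression of $\hat\Gamma$ on $\hat\gamma$
  through the origin with weights $1/\sigma_{y,j}^2$. The default
  multiplicative random-effects model inflates the fixed-effect SE by
  $\max(1, \sqrt{Q/(J-1)})$; a fixed-effect variant is available by
  flag. A single-variant analysis reduces to the Wald ratio.
* **MR-Egger**: the same regression with an intercept after orienting
  all $\hat\gamma_j > 0$; the slope is the causal estimate and the
  intercept measures directional pleiotropy. SEs carry the
  multiplicative overdispersion $\max(1, \hat\sigma)$. P-values are
  two-sided normal by default (consistent across methods); Student-t
  with $J-2$ df by flag.
* **Weighted median**: linear interpolation of the inverse-variance
  weighted empirical CDF of the ratios at probability 0.5; consistent
  when valid instruments carry at least half the weight.
* **Weighted and simple mode**: the argmax of a Gaussian kernel density
  over the ratios (inverse-variance vs equal weights), bandwidth from
  the modified Silverman rule
  $0.9\min(\mathrm{sd},\mathrm{mad})J^{-1/5}$ scaled by
  `bandwidth_factor` (default 1).

Median and mode SEs come from a seeded parametric bootstrap (default
1000 replicates) that redraws $\hat\gamma_j$ and $\hat\Gamma_j$ from
normals at their SEs; results are bit-reproducible given the seed.
Minimum variant counts are 1 for IVW and 3 for the others; methods
below their minimum are reported as missing rather than raising.

## Diagnostics

* **Cochran's Q** against the fixed-effect IVW estimate, $\chi^2_{J-1}$
  under homogeneity.
* **Egger intercept test** for directional pleiotropy.
* **MR-PRESSO-style test**: the observed statistic sums weighted
  squared leave-one-out residuals
  $w_j(\hat\Gamma_j - \hat\gamma_j\hat\beta_{(-j)})^2$; its null
  distribution is simulated by redrawing each $\hat\Gamma_j$ from
  $N(\hat\gamma_j\hat\beta_{(-j)}, \sigma_{y,j})$ (default 1000
  simulations), giving a global p-value with floor $1/(n_{sim}+1)$.
  Per-variant outliers are flagged against their simulated residual
  distributions at a Bonferroni-adjusted 0.05; when outliers exist, the
  distortion test compares the shift in the IVW estimate after their
  removal with shifts from removing random subsets of the same size.
* **Leave-one-out** IVW series using the same model variant as the
  headline fit.

A pair passes QC when the heterogeneity and pleiotropy p-values all
exceed 0.05; tests that cannot run (too few variants) do not fail QC.

## Mediation

The two-step decomposition takes three IVW estimates — exposure to
mediator ($\hat\beta_{xm}$), mediator to outcome ($\hat\beta_{my}$),
exposure to outcome (total) — and reports
$$\text{mediated} = \hat\beta_{xm}\hat\beta_{my}, \qquad
SE = \sqrt{\hat\beta_{xm}^2 se_{my}^2 + \hat\beta_{my}^2 se_{xm}^2},$$
a 95% Wald interval, direct $=$ total $-$ mediated (so the
decomposition is exact by construction, up to one floating-point
rounding when re-summed), and the proportion mediated
mediated/total, undefined for a zero total effect and flagged
"inconsistent mediation" when the signs oppose. Step 2 is univariable
MR with the mediator's own instruments, not multivariable MR adjusting
for the exposure — a deliberate mirror of how such studies are usually
run, and a caveat: variants affecting the mediator only through the
exposure carry no information about $\beta_{my}$ and would bias step 2
if selected (see the simulator notes below).

A mediator *qualifies* in `mediation_screen()` when step 1, step 2 and
the total effect are all significant at the configured $\alpha$
(default 0.05, the nominal threshold used across the screens; every
screen table also carries a clearly-labelled Benjamini–Hochberg column
as a non-primary aid). A mediator whose instruments and effects
coincide with the exposure's is flagged degenerate and excluded.

## The simulator

`simulate_study()` generates the three GWAS directly at the summary
level under the structural model
$$\theta_{total} = \theta_{direct} + \theta_{xm}\theta_{my}.$$
Per variant: MAF $\sim U(0.05, 0.5)$; true exposure effects
$\gamma_j \sim N(0, \gamma_{sd}^2)$; summary SEs
$1/\sqrt{2Nf(1-f)}$ per study (so quadrupling $N$ exactly halves the
SE); observed effects add independent Gaussian noise per study,
honouring two-sample independence. The mediator receives
$\theta_{xm}\gamma_j$ from the exposure's variants **plus its own
directly-instrumenting variants** (`n_snps_mediator`, default equal to
`n_snps`): without these, every mediator-associated variant would act
through the exposure, its Wald ratio would be
$\theta_{my} + \theta_{direct}/\theta_{xm}$, and the
mediator-to-outcome step would be unidentified. All tables share one
variant panel; the generated truth records which variants instrument
which trait for parameter-recovery experiments. Optional pleiotropy
assigns a fraction `prop_invalid` of exposure instruments direct
outcome effects: mean-zero (`balanced`), positive-mean
(`directional`, drawn $N(\sigma_p, \sigma_p^2)$), or proportional to
$\gamma_j$ (`inside_violating`). Everything is reproducible from
`(truth, seed)`.

Default conditions mirror the motivating study design: GWAS sizes
18,340 (microbiome consortium scale), 14,824 (the Olink pQTL study
size) and 187,119 (biobank disease GWAS scale); structural effects
$\theta_{total} = 0.387$ split as direct $0.369$ plus mediated
$0.018$, the latter factored as $\theta_{xm} = 0.3$,
$\theta_{my} = 0.06$ (only the product is constrained by the headline
decomposition; the split is this package's choice); and
$\gamma_{sd} = 0.08$, giving instruments just above the selection
threshold — the realistic regime for microbial taxa. In this default
regime the exposure-to-mediator signals $\theta_{xm}\gamma_j$ sit
below the mediator's selection threshold, so screened step-2
instruments are genuinely the mediator's own.

What the simulator does **not** model: realistic human LD maps (LD
enters only through the synthetic block matrices of
`simulate_ld_blocks()`), case–control ascertainment, sample overlap,
and winner's-curse-corrected effect sizes. Passing tests therefore
demonstrate correctness of the statistical machinery under the stated
structural model, not robustness to every pathology of real consortium
data.

## Validation experiments and their design choices

The experiments in `tests/testthat/test-acceptance.R` and
`scripts/acceptance.R` use these problem sizes, chosen once on
methodological grounds:

* **Recovery** (200 replicates, 100 instruments): run in a
  strong-instrument configuration ($\gamma_{sd} = 0.3$, $N = 2\times
  10^5$ per study, per-variant $F$ in the thousands, as for cis-pQTLs)
  so that what is probed is estimator *consistency*. In the default
  weak-instrument regime the first-order Wald ratio is attenuated
  toward the null by roughly $1 - \sigma_x^2/\gamma_{sd}^2$ (about
  1–2% here, compounded by winner's curse under selection); that is a
  known property of ratio estimators, documented as a limitation, and
  deliberately not what the recovery experiment measures. Mediation
  recovery estimates step 1 and step 2 on the generator's ground-truth
  instrument sets for the same reason. Means are required within 2
  (single check) or 3 (joint checks) Monte-Carlo SEs of the truth.
* **Calibration** (Cochran's Q and the Egger intercept under the full
  null): any single 500-replicate battery judged by an exact binomial
  95% band falsely rejects about 5% of seeds even for an exactly
  calibrated statistic. The experiment therefore aggregates five
  500-replicate batteries against the pooled exact band, with one
  pre-registered confirmation aggregate on a miss, bounding the
  decision rule's own false-alarm rate near 0.25% while retaining
  power against genuine miscalibration. (Under the full null both
  tests are exactly calibrated by construction: conditional on the
  exposure effects, the outcome effects are exactly normal with known
  SEs.)
* **Outlier capture**: 20 seeded 21-variant datasets with one outcome
  effect shifted by 10 SEs; the MR-PRESSO-style outlier test (1000
  simulations, Bonferroni) must flag it in at least 19.
* **Clumping**: block-LD fixtures checked exactly against an
  exhaustive greedy oracle, including window and cross-chromosome
  logic.
* **Determinism**: the demo pipeline rerun under one config/seed must
  be byte-identical, which is why run logs carry no timestamps.

## Numerical and degenerate-input conventions

Variants with $\hat\gamma_j = 0$ are dropped from ratio-based
estimators with a warning. Identical ratios short-circuit the mode
estimators to that value exactly (the kernel bandwidth would otherwise
collapse). Bootstrap and simulation p-values are never exactly zero
($(1 + \#exceedances)/(n+1)$). Simulated p-values are floored at the
smallest positive double. The weighted-median interpolation clamps at
the extreme ratios when 0.5 falls outside the midpoint range. All seeds
flow through an RNG-state-preserving wrapper so library calls never
perturb the caller's stream, and per-pair seeds in the screens are
derived from trait labels, making results invariant to input ordering.

## Limitations

First-order Wald SEs ignore exposure-side noise, so heterogeneity
statistics are mildly anticonservative when instruments are weak and
effects large; IVW inherits the usual weak-instrument attenuation.
Step-2 mediation is univariable, so the direct/mediated split assumes
no exposure-mediated confounding of the mediator-outcome relation.
Proportions mediated are reported from unrounded components; note that
rounded headline figures (e.g. 0.018/0.387) give 4.651%, and published
figures computed from unrounded effects can differ in the second
decimal. The simulator's LD realism is limited to block structures,
and multivariable MR, Steiger filtering and SIMEX-corrected Egger are
intentionally out of scope.
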