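---
title: "Methods: growth decomposition, stoichiometry and the synthetic rhizobox generator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: growth decomposition, stoichiometry and the synthetic rhizobox generator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(earlyvigor)
```

## The analysis model

The package analyses early-vigor rhizobox trials at the genotype level. Its
growth model is classical functional growth analysis under the assumption of
exponential whole-plant growth over the trial:

- **RGR** (relative growth rate, d⁻¹) is the per-day difference of the
  genotype means of natural-log whole-plant biomass between two harvests.
  Biomass is logged per plant *before* averaging; throughout the growth
  analysis "W" denotes `exp(mean ln W)`, the geometric-mean biomass. RGR is
  invariant to the biomass unit.
- **LAP** (leaf area productivity, also called unit leaf rate or net
  assimilation rate; mg cm⁻² d⁻¹) uses the classical interval formula
  `(W₂−W₁)(ln A₂−ln A₁)/((A₂−A₁)(t₂−t₁))`, exact when biomass is a power
  function of leaf area over the interval.
- **LAR** (leaf area ratio, cm² mg⁻¹) and **PNC** (plant N concentration,
  mg mg⁻¹) are *defined as quotients*: LAR = RGR/LAP and PNC = RGR/PNP on the
  shared interval. The literature states RGR = LAR × LAP and RGR = PNC × PNP
  as identities but gives no averaging rule for LAR or PNC; closing the
  identities by the quotient is the one convention under which they hold
  exactly for every input, and it is recorded in the report metadata. The
  endpoint ratios A/W at t₁ and t₂ are emitted as diagnostics; when LAR
  varies smoothly the enforced value lies between them.
- **PNP** (plant N productivity, mg mg(N)⁻¹ d⁻¹) uses the same interval
  formula with the whole-plant N pool in place of leaf area; **NAR_N** is the
  log-rate of the N pool itself.

Two interval conventions coexist, deliberately. The headline RGR, NAR_N, PNC
and PNP use the full harvest interval (default days 1–20). LAR and LAP use a
later window (default days 7–20) because leaves are too small to measure
reliably earlier. Biomass is not harvested at day 7, so the start-of-window
log biomass is back-cast under the exponential model,
`ln W(7) = ln W(20) − RGR·13`; consequently the interval-matched RGR reported
with LAR/LAP equals the headline RGR by construction, and both are labelled
in the output. All quantities are per-day rates and therefore comparable
across the two windows.

Leaf areas at the early endpoint come from the non-destructive manual
measurements via `leaf_area()` (length × maximum width × shape factor,
0.858 for wheat); the final-harvest area is the destructively measured one.
N pools are the arithmetic mean of the pooled-batch concentrations times the
genotype biomass — the geometric mean inside the growth analysis (so the
decompositions stay exact), the arithmetic mean for the stoichiometric pool
tables, a difference that vanishes as noise does and is noted in the
metadata.

## Stoichiometry

Element pools are concentration × biomass per genotype. Expected pools under
optimum nutrition are N-based: `expected = N_pool × ratio/100` with the
default optimum N:P:K:Ca:Mg table 100:14.3:68.3:8.3:8.7; an observed pool
below its expectation is flagged suboptimal. Stoichiometric niche volumes
are plain products of element concentrations (mg g⁻¹ each, no per-element
standardization by default; a geometric-mean standardization is available via
`standardize = TRUE` since the cited construction is not unique — the choice
rescales volumes but not log-scale slopes). The scaling exponent between the
N·P volume and the volume of the other elements (default set K, Ca, S, Mg,
Cu, Fe, Mn, Zn) is the RMA slope of ln V_NP on ln V_other — this orientation
reads "the N and P volume as related to the other elements"; `invert = TRUE`
gives the reciprocal convention. RMA is used because both axes are measured
with error; its slope is `sign(r)·sd(y)/sd(x)` and is invariant to the
logarithm base.

## Trial statistics

Pearson correlations are computed across genotype means (the design's
natural unit once batches are pooled), with two-sided p-values from the t
distribution on n−2 df. One-way ANOVA uses the standard between/within
decomposition; the all-identical degenerate case returns F = 0, p = 1 rather
than erroring. Slope heterogeneity fits
`ln(root length) ~ ln(leaf area) × genotype` on genotype × day means of the
non-destructive measurements (default days 7, 11, 14, 18 — four points per
genotype, so the slope SEs are small-sample and should be read as such);
pairwise slope differences are Tukey-adjusted via the studentized range on
the interaction model's residual df, with unadjusted p-values alongside. No
multiplicity correction is applied elsewhere. Both plain and adjusted R² are
reported for every regression because published figure captions do not
always say which is printed (a negative printed "r²" can only be adjusted).

## The synthetic generator

`generate_experiment()` emulates the study conditions the analysis assumes:

| parameter | default | rationale |
|---|---|---|
| design | 9 genotypes × 8 blocks (RCBD, 72 boxes) | typical early-vigor panel |
| measurement days | 4, 7, 11, 14, 18, 20 (leaves from day 7) | twice-weekly imaging |
| harvests | days 1 and 20 | initial/final destructive sampling |
| true RGR | evenly spaced on 0.09–0.11 d⁻¹ | reported genotype range |
| true LAR | 0.17–0.23 cm² mg⁻¹ | gives ~47–65 cm² leaves at ~300 mg plants |
| initial biomass | 45 mg | wheat seedling dry mass; yields ~300 mg at day 20 |
| true PNC | 0.035–0.045 mg mg⁻¹ | N pools of ~10–15 mg plant⁻¹ |
| root/leaf log-log slope | 1.0–1.4 | allometric spread wide enough to matter |
| element ratios | optimum table ± lognormal (CV 0.10) | genotypes scatter around optimum |
| measurement noise CV | 0.08 | per-observation lognormal |
| AR(1) coefficient | 0.6 | repeated measures on one box are correlated |
| block effect SD | 0.05 (log scale) | mild spatial heterogeneity |
| batches | 2, round-robin by block, biomass-weighted pooling | balances blocks across batches |

Biomass follows `W(t) = W₀ exp(RGR·t)` times lognormal block and residual
effects; leaf area is `LAR(t)·W(t)` (LAR constant by default; `lar_drift`
decouples LAR from LAP); visible root length is log-log allometric in leaf
area; N concentration is constant in time (so NAR_N = RGR in truth); element
pools are proportional to the N pool. LAR, slope and PNC orders are permuted
across genotypes so traits are not artificially collinear with RGR. N is
assayed at both harvests, the other elements only at the final one,
mirroring practice when initial seedlings are too small for multi-element
digestion. All randomness derives from one root seed through a documented
substream scheme (`(seed mod 65011)·33013 + 7919k + 1` for stream k), so an
identical configuration reproduces byte-identical tables.

Two hooks exist purely for validation: `genotype_ratio_multipliers` plants,
e.g., a weak-P genotype (true P ratio 0.7 × optimum), and `niche_exponent`
constructs the other-element concentrations so the true RMA exponent of
ln V_NP on ln V_other is exactly the planted value, including negative
values.

**What the generator does not emulate:** visible (imaged) versus true root
length are generated as distinct traits but with a fixed main-root fraction
and no face-visibility model; root anatomy, SPAD chlorophyll, environment
and irrigation dynamics, and count-trait overdispersion structure are absent;
genotype × time interactions beyond the allometric slopes are not modelled.
Passing recovery tests therefore demonstrates the estimators, not the
biology of any particular trial.

## Numerical choices and degenerate inputs

- Diameter classes exactly at the main/lateral threshold (0.2 mm) are
  refused when they carry length unless a tie side is named; the pipeline
  default assigns them to main roots and records the rule in the metadata.
- `lap()` and `pnp_pnc()` error on unchanged area/pool; the constant-area
  (resp. constant-pool) limit forms are available behind `allow_limit`.
- Zero-variance regressors yield flagged `NA` rows (`degenerate = TRUE`),
  never exceptions, so batch analyses keep running.
- Standard errors use the n−1 sample SD over √n.
- In the noise-free limit every estimator reproduces simulator truth to
  ~1e−15 relative error; tests assert ≤ 1e−10. Decomposition identities are
  asserted at 1e−12, the closure quotient's floating-point round-off.

## Validation problem sizes

The test suite validates by Monte Carlo at the design's own scale: 200
replicate experiments (9 × 8 plants each) for RGR unbiasedness, element-ratio
recovery, the weak-P suboptimality flag, the surrogate-productivity
correlation and slope-heterogeneity detection, and 200 replicates for the
planted niche-exponent recovery. The niche-exponent recovery uses a low
assay-noise setting (CV 0.02) because measurement error attenuates RMA
slopes toward the noise-floor sd ratio — the recovery check isolates the
estimator; the attenuation itself is an inherent property of RMA worth
remembering when interpreting exponents from noisy assays. Slope-heterogeneity
detection uses half the default measurement noise (CV 0.04) as its "low
noise" condition.

## Known limitations

- The analysis unit is the genotype; no per-plant RGR, no mixed-effects
  repeated-measures modelling (AR(1) covariance) and no count-trait GLMs are
  provided.
- Pooled batches preclude within-genotype inference on nutrient traits; the
  correlation surface is across genotype means (n = number of genotypes), so
  p-values are weakly powered by design.
- The back-cast of day-7 biomass inherits the exponential-growth assumption;
  if growth decelerates early, LAP is biased accordingly.
- RMA exponents are attenuated by assay noise (see above) and the niche
  volume's element set and standardization are conventions to be reported,
  not estimated.
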