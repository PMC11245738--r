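---
title: "Methods: two-sample MR for metabolite exposures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample MR for metabolite exposures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metabomr)
```

## The causal model and its assumptions

Two-sample MR treats genetic variants as instruments for an exposure.
A variant is a valid instrument if it (1) associates strongly with the
exposure, (2) is independent of confounders of the exposure–outcome
relation, and (3) affects the outcome only through the exposure.
Given per-SNP summary statistics from two non-overlapping GWAS — the
SNP–exposure effect $\hat\gamma_j$ (SE $\sigma_{Xj}$, per 1 SD of a
metabolite) and the SNP–outcome effect $\hat\Gamma_j$ (SE
$\sigma_{Yj}$, log odds for a binary outcome) — each SNP provides a
Wald ratio $\hat\beta_j = \hat\Gamma_j/\hat\gamma_j$, and estimators
differ in how they pool these ratios when some instruments may violate
assumption (3) (horizontal pleiotropy).

* **IVW** pools with first-order weights
  $w_j = \hat\gamma_j^2/\sigma_{Yj}^2$; it is efficient when all
  instruments are valid but biased by directional pleiotropy.
* **MR-Egger** regresses $\hat\Gamma$ on $\hat\gamma$ *with an
  intercept*; the intercept absorbs the average direct effect and the
  slope remains consistent under InSIDE (instrument strength
  independent of direct effects), at the cost of much lower precision.
* The **weighted median** is consistent while valid instruments carry
  more than half the weight; the **weighted mode** while the largest
  group of instruments agreeing on a ratio is valid.

This hierarchy motivates the decision tree below: IVW is primary, the
others are arbiters when the sensitivity statistics flag trouble.

## Estimator details and numerical choices

* IVW defaults to **multiplicative random effects**: the fixed-effects
  SE $(\sum_j w_j)^{-1/2}$ is scaled by $\sqrt{\max(1, Q/(k-1))}$.
  The floor at 1 means heterogeneity can widen but never narrow the
  interval; with homogeneous instruments the default is therefore
  slightly conservative, and the exact-size estimator is the
  fixed-effects variant (`effects = "fixed"`), which is what the
  calibration checks in the test suite use. IVW p-values use the
  normal distribution.
* Egger uses weights $1/\sigma_{Yj}^2$ after orienting
  $\hat\gamma_j \ge 0$, inflates both coefficient SEs by
  $\sqrt{\max(1, Q_E/(k-2))}$, and tests with $t_{k-2}$. With a
  perfectly collinear configuration $Q_E = 0$ and the floor leaves the
  unit-variance base SE in place rather than reporting a zero SE.
* The weighted median interpolates the weighted 50th percentile
  linearly between the order statistics whose midpoint cumulative
  weights $s_j = \sum_{i\le j} w_i - w_j/2$ bracket $1/2$.
* The weighted mode maximises a weighted normal-kernel density over
  the ratios with bandwidth `bandwidth_factor` times the modified
  Silverman rule $0.9\min(\mathrm{sd},\mathrm{mad})\,k^{-1/5}$;
  degenerate inputs (all ratios equal, or zero mad) fall back to the
  common value / the sd-based bandwidth. The density is evaluated on a
  2048-point grid, so the mode is symmetric under sign flips only to
  grid resolution.
* Median and mode SEs come from a seeded parametric bootstrap that
  redraws $(\hat\gamma_j, \hat\Gamma_j)$ from normals with their SEs;
  `n_boot = 0` skips the bootstrap and reports `NA` SEs, which the
  Monte-Carlo experiments use since they only need point estimates.
* Odds ratios are $e^{\hat\beta}$ with bounds
  $e^{\hat\beta \pm 1.96\,\mathrm{SE}}$ — 1.96 verbatim, matching how
  such tables are conventionally printed.

## Instrument selection and harmonization

Selection applies, in order: a strict $p < 10^{-5}$ screen (the
conventional relaxed threshold for metabolite GWAS, where genome-wide
significant hits are scarce; the threshold is an argument, so the
stricter $5\times10^{-8}$ or looser choices are one keystroke away),
greedy LD clumping, and a strict $F > 10$ filter with
$F = (\hat\gamma/\sigma_X)^2$. The $z^2$ definition of $F$ needs no
allele frequency and equals the single-SNP regression F
asymptotically; when frequency and sample size are available the
$R^2$-based variant is reported alongside for transparency. Clumping
sorts by p-value with lexicographic SNP-id tie-breaks, making the
greedy pass deterministic and independent of input order; the window
is ±500,000 bp inclusive, and removal requires both window overlap on
the same chromosome and $r^2 \ge$ the threshold (0.001 by default).

Harmonization aligns outcome records onto the exposure's effect
allele: direct match, effect/other swap (sign flip), or strand
complement, in that order. Palindromic (A/T, C/G) variants cannot be
resolved by alleles; they are aligned by frequency agreement when both
frequencies are informative, and dropped when either frequency is
missing or the exposure frequency lies in $(0.42, 0.58)$ (tolerance
0.08, the prevailing convention; configurable). Kept rows are then
canonically oriented so $\hat\gamma_j \ge 0$ — allele labels are
arbitrary, estimators are invariant under this choice (unit-tested),
and it makes the median/mode ratio ordering well defined.

## Sensitivity suite

* **Cochran's Q** around the fixed-effects IVW estimate
  ($\chi^2_{k-1}$) or the Egger line ($\chi^2_{k-2}$).
* **Egger intercept test**: $t_{k-2}$ on the intercept.
* **MR-PRESSO**: observed residual sum of squares built from
  leave-one-out IVW slopes; an empirical null from parametric
  replicates of both effect vectors; p-values use the add-one rule
  $(1+\#\{RSS^* \ge RSS\})/(n_{sim}+1)$ so they are never zero.
  Outliers are declared below the Bonferroni level $\alpha/k$ (no
  per-SNP rule is standard, and Bonferroni keeps the family-wise error
  at $\alpha$); the distortion test compares the before/after IVW
  change with removals of random same-size subsets. One exclusion pass
  is performed at most (no iterative re-testing).
* **Leave-one-out** re-runs random-effects IVW k times, matching the
  primary estimator's default.
* **Steiger** compares summed variance explained
  $r^2_j = t_j^2/(t_j^2+n-2)$ across the two samples with a Fisher-z
  test. For binary outcomes the log-odds associations are treated as
  continuous-scale correlations — an approximation that is
  conservative here because outcome-side $r^2$ is tiny in the
  metabolite setting.

## The decision tree and multi-outcome overlap

Per exposure–outcome pair, with all statistics at level $\alpha$
(default 0.05, nominal — consistent with screening designs that report
unadjusted IVW p-values across many metabolites; an FDR/Bonferroni
flag would be a one-line wrapper over `p.adjust` on the caller's side):

1. too few instruments → `insufficient_instruments`;
2. Steiger reversed → `direction_failed`;
3. pleiotropy (Egger intercept; optionally also the PRESSO global test
   under `policy = "egger_or_presso"` — the two tests are reported
   side by side in practice and no combination rule is canonical, so
   the intercept-only default is the least aggressive choice) and
   heterogeneity (Q) are assessed;
4. pleiotropy without heterogeneity → Egger is the primary estimate;
5. heterogeneity without pleiotropy → random-effects IVW stands;
6. neither, IVW significant, and IVW/Egger/median agree in sign →
   `robust_positive` (supplementary estimators need not be
   individually significant);
7. otherwise `not_significant`.

The classification is a pure function of the recorded evidence
booleans. Note a subtlety verified in testing: tightening $\alpha$ is
*not* globally monotone for the robust set, because a borderline
intercept p-value can flip the pleiotropy verdict and move a pair
between branches in either direction; monotonicity holds whenever the
heterogeneity/pleiotropy verdicts are stable, and that is the form the
property test asserts.

`overlap_robust()` intersects per-outcome robust sets and additionally
requires a consistent effect direction across outcomes.

## Pathway over-representation

Robust metabolites are tested against GMT pathway sets with the exact
hypergeometric upper tail $P(X \ge k_{hits})$ over the annotation
universe (default: union of all pathway members). Only
over-representation is implemented — it is the only mode of the usual
web tools that is fully specified by published methods — and raw
p-values are read at $\alpha = 0.10$, the customary relaxed level for
metabolite pathway screens.

## What the simulator emulates — and what it does not

`simulate_study()` draws, per SNP: minor-allele frequency uniform on
`maf_range`; true exposure effect $\gamma_j \sim N(0, \texttt{gamma\_sd}^2)$;
with probability $\pi$ a direct effect
$\alpha_j \sim N(\mu_\alpha, \sigma_\alpha^2)$ *defined on the
exposure-increasing allele*, so that
$\Gamma_j = \beta\gamma_j + \mathrm{sign}(\gamma_j)\,\alpha_j$.
The sign convention matters: allele labels are arbitrary and
harmonization orients $\hat\gamma_j \ge 0$, so a "directional"
pleiotropy defined relative to raw labels would average out after
orientation and could never bias IVW; defining it on the
exposure-increasing allele is what gives $\mu_\alpha \ne 0$ its
intended meaning. `inside_violation` adds a component proportional to
$|\gamma_j|$, breaking InSIDE. SEs follow the first-order law for a
standardized trait, $\sigma = (2p(1-p)n)^{-1/2}$, on both sides —
matching the per-1-SD scale of metabolite GWAS — and observed effects
are normal around the truth with those SEs.

Defaults mirror the motivating study design: exposure GWAS of
$n = 8{,}299$ (a population-cohort metabolite panel), binary outcome
GWAS of $n = 462{,}933$ with a 1:9 case:control split on the log-odds
scale, `gamma_sd = 0.2` so selected instruments have mean
$F \approx 140$, and 15% palindromic variants. LD blocks are
exchangeable (constant within-block $r^2$, zero between, blocks far
apart) — sufficient to exercise the single clumping threshold, not a
model of real LD decay. Not emulated: individual-level genotypes,
sample overlap between the two GWAS, winner's-curse selection from an
external discovery scan, fine-scale LD, or liability-scale binary
traits (outcome effects are simulated directly as log odds, since
two-sample MR consumes only summary statistics). Passing tests
therefore certify the estimators and workflow logic, not robustness to
those unmodelled features of real data.

Batches derive per-replicate sub-seeds by the counter scheme
`(seed + 7919 * rep) mod (2^31 - 1)`, recorded per study, so batches
are reproducible and individual replicates regenerable.

## Problem sizes and regimes used by the checks

The Monte-Carlo checks run at: 500 replicates for recovery/coverage
($\beta \in \{0, 0.1, 0.25\}$, 50 instruments), 2,000 null replicates
for calibration, 500 for the pleiotropy separation and the
weighted-median breakdown, 200 (power) plus 400 (size) for MR-PRESSO
with 400–1,000 resamples, 1,000 random instances for the
clumping-oracle and WLS-oracle equivalences, and 200 for Steiger
orientation. Recovery experiments use a strong-instrument regime
(exposure $n = 5\times10^5$, mean $F \approx 7000$): at the
cohort-scale default ($F \approx 140$) the first-order IVW estimate
carries the known weak-instrument regression dilution of order
$\beta/\bar F$ (about 0.7% of $\beta$), which is a property of
two-sample MR itself, not of this implementation — in that regime an
unbiasedness test at Monte-Carlo precision would measure the
attenuation rather than correctness. The dilution (and the related
winner's-curse attenuation when instruments are selected and estimated
in the same exposure sample) is the main caveat when interpreting
effect sizes at real study scales. The breakdown experiment fixes the
*weight* share of invalid instruments (40% / 60%) rather than their
count, since inverse-variance weight is what the median's breakdown
point is stated in.

## Known limitations

* No proxy-SNP lookup for instruments missing from the outcome, no
  remote LD reference — LD must be supplied locally.
* No MR-RAPS, multivariable MR, radial MR or LD-score regression.
* The Steiger binary-outcome approximation above.
* First-order IVW weights ignore exposure-side noise (NOME); Cochran's
  Q is exact at the null but overdispersed when $\beta \ne 0$ with
  moderate instrument strength, which can flag spurious heterogeneity
  for strong effects.
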