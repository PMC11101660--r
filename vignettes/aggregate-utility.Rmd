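---
title: "Aggregate net utility for gene panel design: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Aggregate net utility for gene panel design: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panelutility)
```

## The decision problem

When a germline screening panel is being designed for asymptomatic,
population-based testing, each candidate gene should earn its place:
identifying carriers is valuable only insofar as the benefit of
forewarning future cases outweighs the harm done to carriers who would
never have developed the disease. `panelutility` formalises this as an
expected-utility comparison between testing and not testing, per
(disease, gene) pair and summed over a panel.

Write $D_i \in \{0,1\}$ for developing disease $i$ and $G_j \in \{0,1\}$
for testing positive for a deleterious variant (DV) in gene $j$. Four
outcome utilities $C_{D,G} > 0$ describe the scenarios; only two
differences matter for the decision:

* $\delta_{G+D-} = C_{0,0} - C_{0,1} > 0$, the disutility of testing
  positive but never developing the disease (surveillance, overtreatment,
  anxiety) — argument name `delta_gpos_dneg`;
* $\delta_{G-D+} = C_{1,1} - C_{1,0} > 0$, the disutility of testing
  negative but developing the disease (false reassurance, foregone
  intensive intervention) — argument name `delta_gneg_dpos`.

Both discordant outcomes arise from incomplete penetrance, not assay
error: the model assumes essentially perfect analytic sensitivity and
specificity of modern sequencing, and treats untested individuals as
equivalent to test-negative ones. With carrier prevalence
$\Pr(G_j = 1)$, penetrance $p = \Pr(D_i = 1 \mid G_j = 1)$ and a
per-test utility term $K$, the net utility of testing is

$$\Delta = \Pr(G_j=1)\left[-\delta_{G+D-} +
  (\delta_{G+D-} + \delta_{G-D+})\,p\right] + K,$$

implemented in `net_utility_pair()`. The long-hand four-outcome
expectations are retained (`utility_with_testing()`,
`utility_without_testing()`) purely as a self-check: their difference
must reproduce $\Delta$ for any valid outcome utilities, and the
property suite verifies this over randomised draws. The no-testing
expectation needs the marginal risk $\Pr(D_i = 1)$, which exceeds
$\Pr(G=1)\,p$ because non-carriers develop the disease too; those
functions therefore take an explicit `background_risk`
($\Pr(D=1 \mid G=0)$). $\Delta$ itself is algebraically independent of
it, which is exactly what makes the reduced form usable with only
prevalence and penetrance.

A note on $K$: it enters additively, so a harm from the act of testing
must be supplied as a *negative* `test_disutility`. The default is 0,
under which every closed form simplifies considerably; all shipped
fixtures use 0.

Panel-level utility is the exact sum of the per-pair values
(`aggregate_utility()`), in declared panel order, so each gene's
inclusion decision depends only on its own term and the aggregate is a
communication device, not a coupling.

## Break-even thresholds

Specifying disutilities is subjective, so the package also reports the
ratio $b = \delta_{G-D+}/\delta_{G+D-}$ at which $\Delta = 0$:

$$b = \frac{1 - (K/\delta_{G+D-})/\Pr(G=1)}{p} - 1,$$

reducing to $1/p - 1$ when $K = 0$, independent of prevalence and of
$\delta_{G+D-}$ (`utility_threshold_pair()`). Ratios above $b$ favour
testing. Degenerate cases are handled explicitly: zero penetrance gives
$b = \infty$ (no finite ratio breaks even); a positive $K$ large enough
that $(K/\delta_{G+D-})/\Pr(G=1) \ge 1$ gives a negative threshold,
flagged `always_beneficial` rather than treated as an error. Under
shared disutilities across pairs the aggregate threshold is the ratio of
sums $\sum_j \Pr(G_j{=}1) / \sum_j \Pr(G_j{=}1)p_j - 1$ (for $K=0$;
`utility_threshold_aggregate()`); panels with heterogeneous per-pair
disutilities violate that derivation and the function refuses them,
pointing at sweep-based root finding over `aggregate_utility()` instead.

## Penetrance uncertainty

Each penetrance estimate carries a precision $n$, and its uncertainty is
modelled as $\mathrm{Beta}(np,\, n(1-p))$ — the posterior from a
notional trial of $n$ carriers, with mean exactly $p$
(`beta_params()`). Uncertainty in carrier prevalence is deliberately
out of scope: prevalences are treated as known, and penetrances are
independent across pairs.

Everything downstream exploits monotonicity where it exists:

* $\Delta$ is affine and increasing in $p$, and $b$ is strictly
  decreasing in $p$, so single-pair credible intervals are **exact**
  monotone transforms of equal-tailed Beta quantiles
  (`threshold_interval_pair()`, single-pair `utility_distribution()`)
  and $\Pr(\Delta > 0)$ is an analytic Beta tail probability
  (`prob_positive_pair()`). Quantiles use the exact regularised
  incomplete-beta inversion (`qbeta`), never a normal approximation —
  at $n = 10$ the Beta is skewed enough that the approximation visibly
  corrupts the second significant figure of the interval bounds.
* Aggregate distributions have no closed form and are propagated by
  Monte Carlo: `sample_penetrances()` draws a matrix of independent
  Beta samples from a single seeded RNG stream, columns in declared
  panel order, and aggregate intervals are empirical equal-tailed
  quantiles of the summed draws. The caller's RNG state is saved and
  restored, so package calls never perturb an enclosing simulation.

Equal-tailed (not highest-posterior-density) intervals are used
throughout, for continuity with the exact single-pair transforms and
because they commute with monotone reparameterisations. The strict
inequality in $\Pr(\Delta > 0)$ is implemented as written; under a
continuous Beta the boundary event has measure zero, and for the
point-mass boundary cases ($p \in \{0, 1\}$) the probability degenerates
to the indicator of the plug-in sign.

Monte-Carlo defaults: 100,000 draws and a **mandatory user seed** on
every stochastic path (functions stop rather than silently seed
themselves). At 100,000 draws the aggregate threshold interval for the
five-gene fixture is stable to well under ±0.05 across seeds, which is
what the two-significant-figure reporting convention needs; fewer than
1,000 draws triggers a quantile-stability warning.

Two worst-case summaries support conservative decision-making: the
fifth-percentile net utility (every penetrance plugged in at its 5th
Beta percentile) and `worst_case_threshold()` (the break-even ratio at
that percentile). The percentile is a tunable probability, default
0.05.

## Grids and sweeps

`ratio_sweep()` fixes $\delta_{G+D-} = 1$ — a pure normalisation, since
$\Delta$ is homogeneous of degree one in
$(\delta_{G+D-}, \delta_{G-D+}, K)$ — and evaluates every pair plus the
aggregate along a ratio grid. The default grid is 21 points
$10^{-1}, 10^{-0.9}, \ldots, 10^{1}$: a step of 0.1 on the $\log_{10}$
scale covers the regime where thresholds for penetrances between 0.1
and 0.9 all fall, while staying dense enough that the piecewise-linear
interpolation of the affine curves is visually smooth. One penetrance
draw matrix is reused across the entire grid, so the aggregate interval
band and $\Pr(\Delta>0)$ curve are smooth functions of the ratio rather
than independently noisy per grid point.

`disutility_heatmap()` evaluates the plug-in estimate, the probability
of positive utility or the fifth-percentile value over a two-way grid of
$(\delta_{G+D-}, \delta_{G-D+})$, default `seq(1, 96, by = 5)` on both
axes (start-anchored: stepping by 5 from 1 cannot land on 100, so the
last cell is 96). With $K = 0$ the estimate's zero contour is the line
$\delta_{G-D+} = b\,\delta_{G+D-}$ through the origin, and the sign
regions are half-planes; the test suite asserts both. Plotting is left
to the user — the numeric tables are the tested artifact, and a
`pheatmap`/`ggplot2` rendering of `$values` is one line.

## Fixtures and the synthetic generator

`breast_cancer_panel()` returns a five-gene female breast cancer panel
(ATM, BRCA1, BRCA2, CHEK2 1100delC, PALB2) with published carrier
prevalences, lifetime penetrances $\{0.35, 0.73, 0.72, 0.19, 0.38\}$,
precisions $\{100, 10^4, 10^4, 100, 100\}$ and $K = 0$; the same values
ship as JSON/TSV under `inst/extdata/` for the CLI. Two variants exist
because two-decimal display penetrances cannot always reproduce
two-significant-figure threshold tables: with
`high_precision_variant = TRUE` the CHEK2 and BRCA1 penetrances become
the three-decimal values 0.195 and 0.732 implied by the published
range, under which CHEK2's threshold prints 4.1 (versus 4.3 from 0.19)
and BRCA1's interval prints (0.35, 0.38). Residual last-digit
differences remain for ATM and PALB2 interval bounds, whose unpublished
third decimals are unknowable; and BRCA2's published threshold display
of 0.40 implies a penetrance near 0.715 rather than the printed 0.72
(which yields 0.39). The package always reports what the stated inputs
imply. The aggregate threshold interval construction used here — Monte
Carlo quantiles of the per-draw break-even ratio
$\sum_j \Pr(G_j{=}1) / \sum_j \Pr(G_j{=}1)\tilde p_j - 1$ — is
equivalent to reading off where the quantile curves of $\Delta$ cross
zero, which we consider the natural definition.

The prevalences are stored exactly as published. Their documented
provenance is allele-frequency based, and the published prevalence
*range* (0.00114–0.00519) matches the stored values after the
Hardy–Weinberg carrier conversion $1-(1-q)^2$; the conversion is
therefore shipped (`allele_freq_to_carrier_prevalence()`) but applied
only when the user opts in.

`synthetic_panel()` generates seeded random panels with prevalences
uniform on [0.001, 0.004], penetrances uniform on [0.2, 0.99] and
precisions drawn from $\{10, 100, 1000, 10^4\}$ — the ranges typical of
rare monogenic disease genes in clinical practice, and the grid over
which the package's behaviour is property-tested. The generator
emulates parameter heterogeneity only: it does not emulate correlated
penetrance errors across genes (shared study populations), uncertainty
in prevalence, age-dependent penetrance, or variant-level heterogeneity
within a gene. Passing property tests on synthetic panels therefore
demonstrates the mathematics of the utility calculus, not the realism
of any particular parameter set.

## Numerical choices

* All core computation is in full double precision; the two-significant-
  figure convention of published threshold tables lives only in the
  reporting layer (`round_like_paper()`, the CLI's
  `--round-like-paper`).
* The four-outcome identity ($\Delta$ as the difference of the two
  expectations) is tested at $10^{-12}$ relative to the magnitude of the
  expected utilities being differenced. The difference itself is
  typically four or more orders of magnitude below those terms, so
  demanding $10^{-12}$ relative to $\Delta$ would exceed what double
  precision can represent after the cancellation; relative to the
  cancelled terms, the identity holds at machine precision.
* Test-suite and acceptance-check problem sizes: property loops use
  1,000 randomised identity draws and 100–200 randomised
  threshold/monotonicity cases; Monte-Carlo cross-validation uses 20
  random pairs at $10^6$ draws each, with agreement asserted within 3
  Monte-Carlo standard errors on the probability scale; routine
  aggregate summaries in tests use 5,000–50,000 draws. These sizes give
  comfortable statistical resolution for two-significant-figure
  quantities.
* Panel files round-trip exactly: TSV numbers are written as the
  shortest decimal that parses back to the identical double, and JSON
  numbers with 17 significant digits.
* Degenerate inputs are defined, not accidental: an empty panel has
  aggregate utility 0 with a warning; point-mass penetrances yield
  degenerate intervals and indicator probabilities; zero penetrance
  yields an infinite threshold.

## Limitations

The model prices exactly two discordance disutilities plus a per-test
term; richer harm structures (age dependence, polygenic modifiers,
variant-of-uncertain-significance handling, QALY-calibrated utilities)
are out of scope, as is uncertainty in carrier prevalence and any
correlation between penetrance estimates. The framework treats the
panel decision as separable per gene, which follows from additivity but
ignores interactions such as shared counselling costs. Finally, the
disutilities are irreducibly subjective: the threshold and
probability-of-benefit summaries exist precisely so that users can
reason about ranges of defensible values rather than committing to one.
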