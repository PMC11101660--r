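# panelutility

Decision-analytic evaluation of multi-gene germline screening panels:
which genes add net utility to a panel, and which subtract it, once you
account for how uncertain their penetrance estimates are.

## The problem

Panel germline testing screens asymptomatic people for deleterious
variants (DVs) in many genes at once. For a well-studied, highly
penetrant gene the case for inclusion is clear; for genes with moderate
or poorly estimated penetrance, testing can do net harm through
unnecessary surveillance, overtreatment and false reassurance. This
package quantifies that trade-off for every (disease, gene) pair on a
candidate panel.

For a pair with carrier prevalence Pr(G=1), lifetime penetrance
p = Pr(D=1|G=1), disutilities δ₍G+D−₎ (testing positive but never
developing the disease) and δ₍G−D+₎ (testing negative but developing
it), and a per-test utility term K, the net utility of testing versus
not testing is

    Δ = Pr(G=1) · [ −δ₍G+D−₎ + (δ₍G+D−₎ + δ₍G−D+₎) · p ] + K

Testing is beneficial when Δ > 0. The panel aggregate is the sum of the
per-pair Δ values. The **break-even threshold**

    b = [ 1 − (K/δ₍G+D−₎)/Pr(G=1) ] / p − 1      (= 1/p − 1 when K = 0)

is the disutility ratio δ₍G−D+₎/δ₍G+D−₎ at which Δ = 0: ratios above b
favour keeping the gene, so b summarises each gene without committing to
specific disutilities.

Uncertainty in each penetrance estimate is modelled as
Beta(α, β) with α = n·p and β = n·(1−p) — the posterior from a notional
trial of n carriers, where the *precision* n expresses confidence in the
estimate. The package propagates this into equal-tailed credible
intervals for Δ and b (exactly, via monotone transforms of Beta
quantiles, for single pairs; by seeded Monte Carlo for aggregates), the
probability Pr(Δ > 0), and fifth-percentile "near-worst case" summaries.

## Worked example

The built-in fixture is a five-gene female breast cancer panel (ATM,
BRCA1, BRCA2, CHEK2 1100delC, PALB2) with published carrier prevalences
and lifetime penetrances, precisions of 10,000 for BRCA1/2 and 100 for
the rest, and K = 0:

```r
library(panelutility)
panel <- breast_cancer_panel()
threshold_table(panel, seed = 2026)
#>   unit_id estimate ci_lower ci_upper
#> 1     All    1.766    1.464    2.125
#> 2     ATM    1.857    1.244    2.845
#> 3   BRCA1    0.370    0.354    0.386
#> 4   BRCA2    0.389    0.372    0.406
#> 5   CHEK2    4.263    2.676    7.355
#> 6   PALB2    1.632    1.098    2.474
```

BRCA1 and BRCA2 have thresholds well below 1: testing stays beneficial
even if one weighs the harm of a positive test in a never-affected
carrier several-fold above the harm of false reassurance, and their
tight intervals reflect the high precision. CHEK2's threshold of 4.3
with a wide interval (2.7–7.4) says its inclusion is defensible only if
a missed future case is judged at least ~4 times as harmful as an
unnecessary positive — and possibly 7 times, once estimation uncertainty
is taken seriously.

At a concrete disutility choice (δ₍G+D−₎ = 1, δ₍G−D+₎ = 2):

```r
utility_distribution(panel, d = disutility_spec(1, 2), seed = 2026)
#> <utility_result> estimate 0.0005358, 95% CI (-0.0002523, 0.001378)
#>   Pr(positive) 0.9032, 5th-percentile value -0.000533 [monte-carlo]
```

The aggregate panel is probably net-beneficial at that ratio
(Pr(Δ > 0) ≈ 0.90), but the near-worst-case value is negative: if every
penetrance sat at the 5th percentile of its uncertainty distribution,
the panel would do net harm.

Grid sweeps over the disutility ratio (`ratio_sweep()`), two-way
disutility heatmaps (`disutility_heatmap()`), panel file I/O
(`read_panel()`/`write_panel()`, JSON or TSV) and a command-line
interface (`panel_cli()`; thin launcher in `inst/cli/panelutility`) are
also provided. See the vignette in `vignettes/aggregate-utility.Rmd`
for the model's assumptions, numerical choices and known limitations.

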