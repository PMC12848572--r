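---
title: "Comparing paired knockout transcriptomes: models and methods"
author: "koCompare"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing paired knockout transcriptomes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(koCompare)
```

# The scientific question

When two gene knockouts perturb overlapping transcriptional programs — for
instance an upstream regulator and the transcription factor it activates —
bulk RNA-seq contrasts of the form wild type vs knockout can be compared
quantitatively to ask three questions:

1. **Does either knockout change cell-cycle activity?** Cell-cycle phase
   gene sets are scored against the genome-wide fold-change distribution.
2. **Do the two knockouts regulate the same genes?** Regulated gene sets
   are intersected and tested for over-representation.
3. **How much of one knockout's program survives in the other?** Fold
   changes over the dependent genes are correlated, compared against a
   random-gene-set null, and summarised by a linear attenuation slope.

Throughout, the universal data currency is the per-gene
differential-expression record (`DETable`): gene symbol, log2 fold change
oriented wild type over knockout (positive = the factor upregulates the
gene), raw p, and BH-adjusted p. Tables are merged across datasets by an
inner join on the printed gene symbol — no ortholog or alias resolution is
attempted, and mapping (for example, of a human-derived cell-cycle list to
one-to-one mouse orthologs) is the user's responsibility upstream.

# Phase percentile-rank scores

For one contrast, all expressed genes with finite log2 fold change are
ranked ascending and rescaled to percentile ranks
$(r_i - 1)/(N - 1) \in [0, 1]$, with tied values receiving the mean of
their ranks. This convention makes the all-gene median exactly 0.5 for
distinct values, which is the reference the test uses. For each phase
(G1/S, S, G2, M, M/G1), the annotated genes' ranks are summarised by
median and interquartile range and tested against 0.5 with a two-sided
one-sample Wilcoxon signed-rank test on $r_i - 0.5$; the five phases of
one contrast form the BH family.

Numerical conventions, chosen here and documented rather than attributed
to anyone else's pipeline:

* ranks exactly equal to 0.5 carry no sign information and are dropped
  from the test (counted and messaged); the summaries keep them;
* the exact signed-rank null is used for at most 25 usable genes, computed
  by convolution over tie-averaged ranks so that ties are handled exactly
  (the classical exact tables are the special case without ties); larger
  phases use the normal approximation with tie and continuity corrections;
* a phase whose ranks are all exactly 0.5 is degenerate and reported as
  p = 1 with a warning.

# Overlap enrichment

Regulated sets are defined per contrast as log2FC > 0 (or < 0) with
adjusted p < 0.05; genes with a missing adjusted p (e.g. removed by
independent filtering upstream) are treated as not significant but remain
in the expressed universe, keeping backgrounds consistent. Two sets drawn
from a universe of $N$ expressed genes are compared with a one-tailed
(enrichment-only) hypergeometric test,

$$p = P(X \ge k), \qquad X \sim \mathrm{Hypergeom}(N, |B|, |A|),$$

*inclusive* of the observed overlap $k$ — note that a naive
`phyper(k, ..., lower.tail = FALSE)` call computes the exclusive tail
$P(X > k)$ and is anti-conservative by one term. Genes outside the
universe are dropped (messaged), never added. The BH family is exactly the
list of tests the caller submits together, mirroring per-figure
correction; `adjustOverlapFamily()` makes the family explicit. For
cross-dataset comparisons the default universe is the merged table's gene
set; whether a union or intersection background is more appropriate is
left to the caller, who supplies the universe explicitly.

`classifyQuadrants()` assigns each gene significant in at least one of two
contrasts to exactly one of seven categories (up/down in both, up/down in
one only, discordant), and `activatedFraction()` computes the share of a
query set inside an "activated" set (upregulated and promoter-bound in
external binding data) together with its enrichment test.

# Correlation, bootstrap null, and the attenuation slope

Restricted to the dependent genes — by default the genes regulated by the
*predictor* contrast at adjusted p < 0.05, up- and downregulated combined
— the two contrasts' log2 fold changes are correlated (Spearman), with the
two-sided p that $\rho \neq 0$. Because dependent genes are a selected,
correlated subset, the package also builds an explicit null: `nIter` gene
sets of the same size are sampled without replacement (independently
across iterations) from the merged expressed universe, the Spearman
correlation is recorded for each, and the observed $\rho$ is standardised
as $z = (\rho_{obs} - \bar{\rho}_{null}) / s_{null}$. The one-sided
upper-tail normal p-value is reported on the natural-log scale so extreme
enrichments do not underflow; the linear-scale value is available
whenever it is representable. The field-standard `nIter` is 100,000; the
test suite uses 5,000, which already estimates the null mean and sd to
within about 1.5% of the null sd.

The attenuation model is an ordinary least-squares fit over the dependent
genes,

$$y_g = \beta_0 + \beta \, x_g + \varepsilon_g,$$

with $x_g$ the predictor contrast's and $y_g$ the response contrast's
log2 fold change, and a 95% confidence interval for $\beta$ from the t
distribution on $n - 2$ degrees of freedom. $\beta = 1$ means the full
program is retained in the response contrast, $\beta = 0$ none of it, and
intermediate values partial (attenuated) activity. Display clipping of
extreme points is a plotting concern only; computations never clip.

For the group-level question "are these genes' fold changes statistically
similar between the contrasts", `comparePairedLfc()` runs a two-sided
paired Wilcoxon signed-rank test on the per-gene differences (the choice
of test is this package's, documented here). All-zero differences leave
the statistic undefined; p = 1 is reported with a warning as a
conservative convention.

## What the slope does — and does not — estimate

The OLS slope is a *descriptive* attenuation coefficient of observed fold
changes, exactly as plotted. It is not an errors-in-variables estimator:
because the predictor fold changes carry measurement noise, the fitted
slope is attenuated relative to the generative coefficient relating the
*true* effects (classical regression dilution, reliability factor
$\mathrm{Var}(\theta)/(\mathrm{Var}(\theta) + \sigma^2)$), and genes that
enter the dependent set without a true effect in the response contrast
(private-program members and false discoveries of the selection at
adjusted p < 0.05) drag it further toward zero. The synthetic recovery
experiment in the acceptance suite quantifies this at the default
generator settings: with true $\beta = 0.43$, per-gene noise of median
0.3 log2 units and same-strength private programs, the fitted slope
centres near 0.21 and its 95% CI essentially never covers the generative
value. The noiseless limit behaves exactly (slope equal to the true
$\beta$ to 1e-9 when fitted on the shared program with zero noise; a unit
test asserts this). Interpret fitted slopes as what they are — the
measured attenuation of observed fold changes under the given selection —
and compare like with like (same noise level, same selection rule) when
contrasting two designs.

# Labeling-index (EdU) proportion statistics

Genotype-by-EdU-status count tables are compared with a Pearson
chi-squared test of homogeneity; when it rejects, all pairwise 2x2 tests
are run and BH-adjusted across the $k(k-1)/2$ pairs. Continuity
correction follows base R's convention: Yates for 2x2 tables (including
post-hocs), none for larger tables. A single proportion is tested against
a reference with the exact binomial test using the minimum-likelihood
two-sided rule.

`minNForPower()` searches ascending for the smallest test-group size
reaching a target power for the two-sample comparison of proportions with
unequal sample sizes. Two rejection rules are implemented:

* **approximate** (default): the classic large-sample z-test with
  variance pooled under the null — the rule behind the standard
  unequal-sample-size power formulas in common power packages;
* **exact**: the Fisher conditional test, with each group's outcomes
  enumerated over binomial supports truncated below 1e-12 tail mass, and
  a known-proportion limit (`n1 = Inf`) that reduces to the one-sample
  exact binomial test with the central two-sided convention — its p2 = 0
  special case has the closed form
  $n_{min} = \lceil \log(\alpha/2)/\log(1 - p_1) \rceil$, which pins the
  implementation in the tests.

On the package's reference design (reference group 7703 cells at 4.5%
positive, test group truly all-negative, power 0.8, two-sided 0.05) the
approximate rule first crosses the target at a test group of 90 cells and
the exact rule at 89 — one cell apart, the exact conditional test being
marginally less conservative here. The default is the approximate rule
because it is what the widely used power functions for this design
compute; when the two rules disagree, report the rule with the number.

# The synthetic-data generator

`synthConfig()`/`generateContrastPair()` produce two DE tables plus the
generative truth. The structure: a shared program whose true effect in
contrast B is exactly `betaTrue` times its effect in contrast A;
contrast-private programs; phase-annotated cell-cycle genes with fixed
additive shifts; and null genes. Observed log2 fold changes are true
effects plus Normal(0, $\sigma_g$) noise, with $\sigma_g$ drawn
log-normally per gene and contrast; p-values are the two-sided normal
tails of $\hat{\theta}_g/\sigma_g$ and adjusted p-values come from
`bhAdjust()`. All randomness flows from the single config seed, and the
caller's RNG stream is left untouched.

Default choices and their rationale:

* `nGenes` 12,000 (a typical expressed-gene count after a TPM >= 1 in >= 3
  samples filter), shared program 600, private programs 400 each, 320
  phase genes — magnitudes comparable to regulated-set sizes seen in
  knockout ovary datasets;
* true effects are *signed*: magnitude ~ Normal(`muShared` = 1.0,
  `tauShared` = 0.4) with random sign, since knockout volcano plots show
  both up- and downregulation; private programs get the same strength
  (`muAOnly` = `muBOnly` = 1.0) — private regulatory programs are not
  intrinsically weaker than shared ones;
* `betaTrue` = 0.43, a mid-range attenuation representative of a partial
  upstream dependency;
* noise: median scale 0.3 log2 units with log-sd 0.4, mimicking the
  spread of DE standard errors across the expression range, which makes
  adjusted-p selection nontrivial (high-noise genes need larger observed
  effects to be selected);
* phase shifts of ±0.5 log2 units: contrast A raises G1/S and S only
  (a meiotic-initiation-like signature), contrast B lowers all five
  phases (a mitotic-arrest-like signature);
* EdU defaults: the wild-type group at proportion 0.045 over 7703 cells;
  the other genotypes are synthetic plausible values (one knockout
  slightly below wild type, one far above, the double knockout highest).

The count-level generator (`generateCounts()` with `estimateDENaive()`)
exists so the file-reading and expression-filter surfaces can be exercised
end to end; the naive estimator (Welch's t on log2 CPM + 0.5) is a
deliberately simple stand-in and not a substitute for a proper DE engine
on real data.

What the generator does **not** emulate: library-size artifacts and
normalisation error, correlated genes within programs (effects are drawn
independently), batch structure, and any single-cell phenomena. Passing
recovery tests therefore demonstrate correctness of the estimators under
this generative model, not robustness to everything real data can do.

# Problem sizes and determinism in the test suite

The test and acceptance suites run the full pipeline at the default
12,000-gene configuration for the slope-recovery experiment (200
replicates), 4,000 genes for the bootstrap z calibration (200 replicates
at `nIter` 5,000) and 6,000 genes for the phase type-I experiment (400
simulated contrasts) — sizes chosen to estimate each property to useful
precision while keeping a full run in minutes on one CPU. Every
simulation seed is fixed in the test code; brute-force enumeration
oracles (hypergeometric tail sums, sign-assignment enumeration, binomial
enumeration, step-up BH by hand) are implemented independently in the
test helpers and shared with no package code.

# Known limitations

* The attenuation slope is descriptive, not a causal mediation estimate,
  and is biased toward zero relative to generative truth under predictor
  noise and selection (quantified above).
* Gene identity is the printed symbol; no alias handling.
* The exact Fisher power search enumerates both groups' outcomes; it is
  fast for the package's designs (a proportion near zero in one group)
  but can be slow for two large groups with mid-range proportions — use
  the approximate rule there.
* The bootstrap null assumes exchangeability of random gene sets with the
  dependent set with respect to everything except the dependency being
  tested; strong universe-wide structure shifts the null mean, which is
  why the null mean and sd are reported rather than assumed to be 0 and
  $1/\sqrt{n-1}$.
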