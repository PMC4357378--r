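---
title: "Methods: the permutation disequilibrium test for oligoset DNA pooling"
author: "poolGC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the permutation disequilibrium test for oligoset DNA pooling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poolGC)
```

## The design and the statistic

A stratum-matched case-control study recruits $n$ cases, each with $m \ge 1$
controls matched on stratum-delineating variables. Instead of genotyping
every subject, the multiple DNA pooling design randomly allocates each
matched set to one of $J$ pooling sets; within pooling set $j$ the cases are
pooled into one case pool and the controls into $m$ control pools, so the
whole study types $J(1+m)$ pools per marker. Quantitative PCR on each pool
measures the allele frequency of the candidate marker ($i = 0$) and of $L$
unlinked null markers ($i = 1, \dots, L$) chosen for genomic control.

Writing $p_{1ij}$ for the measured case-pool frequency and $p_{0ij}$ for the
average of the $m$ measured control-pool frequencies, the analysis works on
the difference matrix $D_{ij} = p_{1ij} - p_{0ij}$ and the per-marker
statistic

$$\chi^2_i = \frac{\bigl(\sum_{j=1}^J D_{ij}\bigr)^2}{\sum_{j=1}^J D_{ij}^2},
\qquad 0 \le \chi^2_i \le J,$$

with the genomic-control ratio

$$T = \frac{\chi^2_0}{\operatorname{mean}\{\chi^2_1, \dots, \chi^2_L\}}.$$

Residual stratification that survives matching pushes every marker's
$\chi^2$ up together; dividing the candidate's statistic by the null-marker
mean calibrates it away. The upper bound $\chi^2_i \le J$ is
Cauchy–Schwarz, attained exactly when all $J$ differences in a row are
equal and nonzero; an all-zero row is a $0/0$ and is defined to give
$\chi^2 = 0$ — no observed difference in any pooling set is no evidence of
association, and the convention keeps $T$ well defined. If *every* null row
is identically zero the genomic-control denominator cannot be calibrated and
the package raises a degenerate-null error rather than inventing a value.

## The sign-flip permutation null

With few pooling sets ($J < 30$, the oligoset regime) the large-sample
theory for $T$ is unreliable, so the null distribution is generated by
permutation: exchanging the case and control labels within pooling set $j$
leaves the genetic data untouched and simply negates column $j$ of $D$. One
sign per pooling set, shared by the candidate and all null markers — the
exchange of disease status affects every marker measured on those pools
identically, which is why this is the correctness-critical reading and is
not configurable. Each permutation draws $J$ independent fair signs,
recomputes all $L+1$ chi-squares and hence a new $T$ (numerator *and*
denominator vary), and the p-value compares the observed $T$ with the
permuted ones. Because $\sum_j D_{ij}^2$ is invariant under any sign
pattern, only the row sums need recomputing; the implementation evaluates
all $B$ patterns as a single $(L+1) \times J$ by $J \times B$ matrix
product, which is what makes the simulation grids cheap.

Two tie rules are exposed. The literal rule counts strictly larger
permutation statistics, $\#\{T^{(b)} > T_{obs}\}/B$; it can return 0 and be
anti-conservative in the extreme tail. The default is the add-one rule
$(1 + \#\{T^{(b)} \ge T_{obs}\})/(1 + B)$, which is never 0 and guarantees
validity. With the default $B = 10000$ the two differ by at most a few
$10^{-4}$. For $J \le 20$, `exhaustiveTest()` enumerates all $2^J$ patterns
and is exact; the identity pattern always ties, so the exact p-value is at
least $2^{-J}$, and since $s$ and $-s$ give identical $T$ the effective
support has at most $2^{J-1}$ points.

## The large-sample comparator

The classical genomic-control treatment refers $T$ to $\chi^2_1$. We keep
that convention as the default of `largeSamplePValue()`, but it ignores the
sampling variability of the denominator: as $J \to \infty$,
$\chi^2_0 \Rightarrow \chi^2_1$ while
$\operatorname{mean}\{\chi^2_i\} \Rightarrow \chi^2_L / L$ independently,
so $T \Rightarrow F(1, L)$. For a realistic $L$ of 10–50 the difference
matters: in our null simulations the $\chi^2_1$ referral rejects at
0.069–0.075 at nominal 0.05 for $L = 10$ (anti-conservative, driven by
denominator noise), while the $F(1, L)$ referral is uniformly conservative
at oligoset $J$ (0.040–0.048) and approaches the nominal level as $J$
grows, because the finite-$J$ chi-squares are lighter-tailed than their
limits (capped at $J$). The test results and experiment drivers therefore
use the $F(1, L)$ reference as the large-sample comparator; it reproduces
the qualitative behaviour expected of a large-sample test in this regime —
valid but conservative, and dominated by the permutation test. This was a
genuinely open design choice and the $F(1, L)$ resolution is our own.

## The synthetic-data generator

`simulateDataset()` composes the full data-generating model, and its
defaults *are* the study conditions of the package's simulation claims:

* **Hidden strata.** Five equal-weight strata. The candidate marker's
  allele frequency rises 0.2 → 0.6 across strata while the baseline disease
  risk rises 0.02 → 0.10 — opposed gradients chosen to confound frequency
  with risk, the configuration stratification bias feeds on. Null-marker
  frequencies are Uniform(0.1, 0.9) per (marker, stratum) and are redrawn
  for every simulated dataset: the marker panel is part of the
  data-generating process, not a fixed nuisance. These stratum parameters
  are this package's own stand-ins; the literature the design emulates does
  not print exact values.
* **Disease model.** A per-allele multiplicative odds model at the
  candidate under a rare-disease approximation: within a stratum of
  frequency $p$, case genotypes are $\mathrm{Binom}(2,\, p\psi/(p\psi+1-p))$
  and the case stratum distribution is tilted by
  $w_s r_s (1 - p_s + \psi p_s)^2$. $\psi = 1$ is the null.
* **Matching.** Each control matches its case's stratum with probability
  $1 - \delta$ and is a random population draw with probability $\delta$;
  $\delta \in \{0.1, 0.3, 0.5\}$ spans good to poor matching in the study
  grids.
* **Pooling.** Matched sets are allocated uniformly to the $J$ pooling
  sets (an empty pool triggers a logged re-draw); a pool's true allele
  fraction is its allele-copy count over $2 \times$ size.
* **Measurement.** Unequal allelic amplification distorts a true fraction
  $p$ to $p' = \kappa p / (\kappa p + 1 - p)$, with one
  $\kappa \sim \mathrm{Uniform}(1, 2)$ per *marker* (a marker's assay
  measures all its pools). Noise is logit-normal:
  $\mathrm{logit}(p_{obs}) \sim N(\mathrm{logit}(p'), \tau^2)$ with
  $\tau = \sigma / (p'(1-p'))$, the delta-method calibration that makes the
  SD of the measured frequency $\approx \sigma$ on the frequency scale, so
  $\sigma \in \{0.01, 0.05\}$ is directly comparable to allele-frequency
  differences. Reading "measurement error $\sigma$" on the frequency scale
  rather than the logit scale is a documented interpretation; the two only
  diverge materially far from $p = 0.5$. $\sigma = 0$ returns $p'$ exactly,
  and a monomorphic pool (0 or 1) is returned unchanged with a warning.

What the generator does *not* emulate: linkage disequilibrium among markers
(null markers are assumed unlinked), unequal DNA amounts within a pool,
pool-construction errors, and sequencing-based pool genotyping. Passing
tests therefore certify the statistical machinery under the stated model,
not robustness to those real-data artefacts.

## Experiment drivers, seeds and problem sizes

`runType1Grid()` / `runPowerGrid()` simulate a scenario grid and report
rejection rates with binomial Monte-Carlo standard errors
$\sqrt{r(1-r)/n}$; rejection is $p \le \alpha$ under the default tie rule,
and both the permutation and large-sample p-values are computed on the same
replicates so comparisons are paired. All randomness flows from one master
seed: the master seed yields per-scenario seeds, each scenario seed yields
per-replicate seeds (`deriveSeeds()`), and each replicate seeds its own
model draw, dataset and permutations — grids are reproducible to the bit
from a single integer.

The package's own calibration claims use 5000 replicates of 500
permutations at the baseline scenario ($n = 900$, $m = 1$, $J = 10$,
$L = 10$, $\delta = 0.1$, $\sigma = 0.01$), and the power-ordering checks
use 600 replicates of 250 permutations per cell — sizes chosen so the whole
suite runs on a laptop in a few minutes while keeping Monte-Carlo standard
errors near $3 \times 10^{-3}$ for size and $2 \times 10^{-2}$ for power.
Note that the exact sign-flip distribution has at most $2^{J-1}$ distinct
points, so the smallest attainable p-value is $2^{1-J}$: rejecting at level
$\alpha$ at all requires $2^{J-1} > 1/\alpha$ (J of at least 6 for
$\alpha = 0.05$ and at least 9 for $\alpha = 0.005$) — one reason the
oligoset design point starts near $J = 10$, and why the drivers' own checks
use $J \ge 8$. Two discreteness effects at $B = 500$ are worth knowing. At
$\alpha = 0.005$ the add-one rule can only reject on
$p \in \{1/501, 2/501\}$, and Monte-Carlo sign draws occasionally reproduce
the identity (or global-flip) pattern — an expected once per 500 draws at
$J = 10$ — which ties with $T_{obs}$ and counts against rejection, so the
true rejection rate sits near 0.002–0.003, at the conservative edge of the
nominal 0.005. This is a property of the permutation test at small $B$,
not a defect; at the study's own $B = 10000$ the effect is negligible.

For power orderings the per-allele odds ratio is fixed at $\psi = 1.15$,
chosen once (by a pilot at the baseline scenario) to give mid-range power
so that orderings across $J$, $m$, $\sigma$, $L$ and $\delta$ are exercised
away from the 0/1 boundaries. Absolute power levels are not a claim of
this package — they depend on the unpublished stratum parameters above —
only the orderings and the size are.

## Numerical and degenerate-input choices

* All-zero marker row: $\chi^2 = 0$ (see above); all null rows zero: error.
* A permutation pattern that zeroes the null mean gives $T = \infty$ when
  the candidate survives (counts as extreme) and $T = 0$ when everything
  vanishes; both are measure-zero events for continuous data.
* `exhaustiveTest()` refuses $J > 20$ ($2^J$ blow-up guard).
* Pool tables are validated on ingestion: frequencies in $[0,1]$ with the
  offending cell named, the full marker × pool-set grid present, duplicates
  rejected; the candidate marker is stored first and flagged in
  `rowData()`.
* Reports print 6 significant digits; TSV files keep full precision.

## Known limitations

The comparator is an approximation to large-sample theory whose exact
reference distribution for this design is not published; we chose
$F(1, L)$ on asymptotic grounds and verified only its qualitative
behaviour. Stratum parameters for the simulations are stand-ins, so
absolute power figures should not be read off the grids. The generator's
binomial sampling assumes Hardy–Weinberg within strata and perfectly equal
DNA contributions within pools.
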