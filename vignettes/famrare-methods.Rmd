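---
title: "Family-based designs and score tests for rare-variant association: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Family-based designs and score tests for rare-variant association: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`famrare` implements a simulation and analysis toolkit for comparing
family-based study designs — parent–child trios, affected sib-pairs (ASPs)
and "enriched" trios (one case kept from an ASP) — when testing groups of
rare variants for disease association. This vignette is the package's own
account of the models, the numerical choices, and the limits of what its
simulations demonstrate.

## The disease model

Genotypes are minor-allele counts $g_i \in \{0,1,2\}$ at $m$ biallelic
variants, assumed independent (no linkage disequilibrium) with
Hardy–Weinberg frequencies determined by each variant's minor-allele
frequency (MAF) $q_i$. A subject's affection probability follows a logistic
penetrance model
$$
P(\text{affected} \mid G) = \operatorname{expit}\!\Big(\operatorname{logit}(c) + \sum_i \beta_i g_i\Big),
$$
where $c$ is the background chance of affection for a subject with no minor
alleles and $e^{\beta_i}$ is the per-allele odds ratio of variant $i$
($\beta_i = 0$ for non-causal variants). `population_prevalence()` computes
the exact expectation of this penetrance over Hardy–Weinberg genotypes by
convolving binomial allele-count distributions over groups of variants that
share $(q, \beta)$.

A note on the default parameterisation: with the package defaults (10
variants, MAF 0.5%, background risk 1%, 4 causal variants at OR 2.0) the
model-implied prevalence is about 1.04%. Reports of comparable simulation
settings have quoted a prevalence near 1.21% for the same nominal
parameters; the discrepancy cannot be resolved from the printed parameter
values, so the package documents the exact model-implied figure and never
uses quoted prevalences as correctness checks.

## Ascertained-family simulation: the exact tilted sampler

The study conditions ascertain families on affection — one affected child
per trio, two per ASP. Naive rejection sampling costs $O(1/\text{prevalence})$
per trio and $O(1/\text{prevalence}^2)$ per ASP, prohibitive at 1%
prevalence. `simulate_families()` therefore draws from the exact ascertained
distribution directly, using the fact that affection depends on the family
only through the offspring genotypes:

1. the joint offspring genotype distribution at *causal* variants —
   marginalised over parents (for sib-pairs this marginal couples the two
   sibs) and tilted by the penetrance of each affected child — is computed
   by a forward–backward dynamic program over the per-child causal burden;
2. non-causal offspring genotypes are drawn from their untilted marginals
   (ascertainment cannot shift them);
3. parents are drawn from their exact conditional distribution given the
   offspring genotypes, a $9 \times$(child-state) table per distinct MAF.

Burden states are stored as integer minor-allele counts per group of causal
variants sharing an effect size, so the backward pass matches forward
states exactly with no floating-point key comparisons and no truncation of
rare parental configurations; the sampler is exact for any mixture of
effect sizes whose state space stays modest (it aborts with a clear message
and `method = "rejection"` remains available otherwise). Naive rejection
sampling is retained both as a validation oracle — the test suite compares
the two samplers' joint (parents, child) law by a chi-square goodness-of-fit
test at $n = 10^5$ — and as a fallback for high-prevalence models.

Enriched trios are simulated as ASPs with one affected sibling discarded,
which is their definition; unrelated controls are Hardy–Weinberg subjects
screened to be unaffected by default (at 1% prevalence screening is almost
immaterial, and a flag provides unscreened population controls). The number
of unrelated controls defaults to the number of cases; the equal-arm choice
matches the case–control tests being benchmarked.

## Transmission counts and the five score tests

For each trio and variant, $B$ counts minor alleles transmitted to the
affected offspring by *heterozygous* parents, $C$ the major alleles so
transmitted, and $X = B - C$ is the transmission-disequilibrium
contribution. The counting rule $B = g_{\text{child}} - \#\{\text{homozygous-minor
parents}\}$ requires no phase information. ASPs are treated as two
independent trios sharing parents (no prior linkage hypothesis).

From the $n \times m$ matrix $X$, the score vector is $U = \sum_i X_i$ and
its covariance estimate is $V = \sum_i (X_i - \bar X)(X_i - \bar X)^\top$.
The five tests are functionals of $(U, V)$:

* **UminP** — $\max_j U_j^2/V_{jj}$, with the asymptotic p-value from the
  multivariate-normal rectangle probability under the joint null law of $U$
  (via `mvtnorm`), and a sign-flip Monte-Carlo alternative;
* **score** — $U^\top V^- U$ with a pseudo-inverse, $\chi^2$ on the
  numerical rank of $V$;
* **SSU** — $U^\top U$, null distribution $\sum_j \lambda_j \chi^2_1$ with
  $\lambda_j$ the eigenvalues of $V$;
* **SSUw** — $\sum_j U_j^2 / V_{jj}$, eigenvalues of the correlation-like
  rescaling of $V$;
* **sum** — $(\mathbf 1^\top U)^2 / (\mathbf 1^\top V \mathbf 1)$, one df;
  powerful when effects are homogeneous, cancels under opposite-direction
  effects.

The multiple-test-corrected single-SNP TDT is also provided: per-variant
$(b-c)^2/(b+c)$ with a Bonferroni-corrected minimum p over informative
variants.

Two conventions deserve a note. First, $V$ is the *uncentred-for-Bessel*
sum of outer products of centred rows (no $n/(n-1)$ factor); this is the
standard score-test form and keeps the sum, score and SSUw statistics
scale-consistent — an implementer preferring the $n-1$ convention can
rescale $V$, which changes p-values negligibly at the sample sizes studied.
Second, variants with $V_{jj} = 0$ (no informative transmissions) are
dropped from UminP, SSUw and Bonferroni counts: they carry no information
and retaining them creates 0/0.

The same five tests apply unchanged to case–control data through
`cc_score_components()`, which computes the null logistic score
$U = G^\top(y - \bar y)$ and
$V = \bar y (1-\bar y)\sum_i (g_i - \bar g)(g_i - \bar g)^\top$.

## Case–control transformations of family data

Two transformations make family data accessible to case–control tests:

* **PCC (pseudo-case–control)** — each affected offspring is a case, and
  one pseudo-control per offspring is built from the two untransmitted
  parental alleles, so $g_{\text{case}} + g_{\text{pseudo}} =
  g_{\text{father}} + g_{\text{mother}}$ identically (the package tests this
  identity on every simulated family). Only this one of the three possible
  pseudo-controls is generated, matching the unmatched case–control design
  the downstream tests assume. The column sums of $X$ equal the
  case-minus-pseudo-control allele-count contrast, which is why family and
  PCC analyses of the same data have nearly identical power.
* **UCC (unrelated-case–control)** — affected offspring plus unrelated
  population controls; parental genotypes are discarded.

When ASP families contribute two sibling cases, the case–control sampling
assumptions fail. `cluster_related()` sums minor-allele counts of related
cases into one composite case, and sums controls in blocks of the same
sizes. Unrelated controls carry no natural family match, so blocks are
formed in input order; any exchangeable grouping gives the same null
distribution, and the input-order choice keeps the operation deterministic.
Clustering is applied by default to the five score tests on ASP-derived UCC
data (where it restores type-I error), while single-SNP association,
C-alpha, SKAT and KBAC are left unclustered on that roster — their inflated
error rates there are part of the phenomenon the package reproduces.

## The rare-variant battery

* **C-alpha** compares the observed variance of the case/control split of
  each variant's minor-allele copies to its binomial expectation; the
  analytic reference is a one-tailed standard normal. At MAF 0.5% the
  normal approximation is unreliable, so a permutation version
  (`calpha_permutation()`) is used in the study rosters.
* **SKAT** is the variance-component score $Q = (y-\bar y)^\top G W G^\top
  (y-\bar y)$ with $W = \mathrm{diag}(w_j^2)$ and $w_j$ the Beta$(1,25)$
  density at the observed MAF (combined sample); its null distribution is
  the eigenvalue mixture of the projected kernel. With unit weights
  ($a_1 = a_2 = 1$), $Q = U^\top U$ *exactly* and SKAT coincides with SSU —
  an identity the test suite asserts to machine precision.
* **KBAC** counts distinct non-null multi-variant genotypes; class $i$ with
  $n_i^A$ case and $n_i^U$ control carriers is weighted by the cumulative
  hypergeometric probability of at most $n_i^A$ case carriers, and the
  statistic is $\sum_i k_i (n_i^A/n^A - n_i^U/n^U)$, one-sided in the risk
  direction, calibrated by label permutation. The hypergeometric-kernel
  definition follows the original KBAC formulation; the genotype-class table
  is hashed once and only case counts are re-tallied per permutation.

Permutation p-values use the add-one estimator $(1 + \#\{T^{(b)} \ge
T_{\text{obs}}\})/(B+1)$ with ties counted as exceedances, which is valid
(conservative) at any budget.

## The mixture-of-chi-squares evaluator

SSU, SSUw and SKAT need $P(\sum_j \lambda_j \chi^2_1 > t)$.
`mixture_chisq_pvalue()` inverts the characteristic function exactly in
Imhof's sine-integral form. The integrand oscillates with asymptotic
half-period $2\pi/t$, which defeats generic adaptive quadrature over
$(0,\infty)$; the package integrates chunk-by-chunk over half-periods,
summing a head of 12 chunks directly and Euler-accelerating the alternating
tail (iterated averaging of partial sums), after rescaling by
$\lambda_{\max}$ for numerical balance. The test suite checks the evaluator
against plain chi-square quantiles, a $10^6$-draw Monte-Carlo oracle, and a
$\chi^2_3$ far-tail value exact to eight digits. Eigenvalues below
$10^{-10}\lambda_{\max}$ are dropped; if the inversion fails or lands below
its $\sim 10^{-12}$ noise floor, the Liu–Tang–Zhang moment-matching
approximation takes over (a coarse but monotone fallback whose error is a
few $10^{-3}$ at moderate quantiles).

## Replication engine and reproducibility

`scenario_config()` bundles a scenario; `run_replicate()` simulates one
family sample, builds family/PCC/UCC data *from the same families* —
mirroring the choices available for a real data set — and runs the
roster. Replicate $r$ of a run with master seed $s$ uses a substream seed
derived deterministically from $(s, r)$, so any replicate can be reproduced
in isolation and results do not depend on execution order. Rejection is
declared at $p < \alpha$ strictly; a permutation p-value exactly equal to
$\alpha$ counts as a non-rejection, matching the conservativeness of the
add-one estimator.

`estimate_power()` reports per-test rejection proportions with binomial
Monte-Carlo standard errors; `calibrate_or()` bisects a shared odds ratio
(on the log scale) until the most powerful test reaches a target power,
which is how the baseline effect sizes (OR 2.00 for trios, 1.72 for ASPs,
1.54 for enriched trios, each targeting roughly 90% power for the best
test) were originally chosen. `scenario_battery()` pre-registers the
systematic sweeps: causal-variant count 1–10, total variant count, OR
sweeps for one and four causal variants, protective-variant replacement,
±20% effect-size fluctuation, two-population stratification
(stratum parameters must be supplied by the user), and case subsets of
100–1100.

### Problem sizes

The headline reproduction (`reproduce_headline_results()`, also the
substance of `scripts/acceptance.R`) uses 1000 replicates for closed-form
tests and 300 replicates × 1000 permutations for C-alpha-P and KBAC; at
these budgets one full run completes in a few minutes on a single core. The
unit-test suite uses smaller configurations (hundreds of families,
$10^4$–$10^5$ draws for distributional oracles) chosen so each property is
tested at 3-standard-error resolution.

## What the simulations do and do not show

The generator emulates exactly the stated study conditions: independent
variants, Hardy–Weinberg parents, Mendelian transmission, logistic
penetrance, ascertainment on affected offspring, and (optionally) discrete
population strata. Real sequence data differ in ways the simulations do not
probe: linkage disequilibrium between variants, site-frequency spectra with
many singletons, genotyping error and missingness, covariates, admixture
rather than discrete strata, and quantitative traits. Conclusions about the
*relative* behaviour of tests and designs (e.g. that enrichment helps
case–control but not transmission tests, or that unclustered sib-pair cases
inflate case–control type-I error) are the quantities the package is built
to reproduce; absolute power numbers should not be read as predictions for
any particular study.

Known limitations: pseudo-controls are genotype-level (no haplotype-level
pseudo-controls), no conditional-logistic matched analysis, no
covariate-adjusted SKAT or SKAT-O, extended pedigrees beyond two affected
siblings are out of scope, and the exact sampler's state space grows with
the number of *distinct* causal effect sizes (the rejection sampler covers
the rest).
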