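---
title: "Models and methods: detection limits and lung-enrichment tests for replicate OTU counts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: detection limits and lung-enrichment tests for replicate OTU counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(balenrich)
```

## The problem

Bronchoalveolar lavage (BAL) fluid collected through a single bronchoscope
contains an unknown admixture of upper-respiratory-tract bacteria —
carried on the instrument through the oropharynx, or present in the lung
transiently by microaspiration. An OTU observed in BAL but not in a paired
oral wash (OW) is therefore not automatically a lung resident: rare
lineages are sampled stochastically, and two replicate extractions of the
*same* fluid already disagree about which rare OTUs are present at all.
`balenrich` treats this as two coupled statistical questions:

1. **Detection** — how abundant must an OTU be for its presence to be a
   reproducible observation at a given sequencing depth?
2. **Enrichment** — which OTUs are more abundant in BAL than a shared
   BAL+OW model of sampling noise can explain, in the lung direction only?

## The model and its assumptions

A replicate count vector of K OTUs with depth N is modeled as
multinomial with a proportion vector that itself varies between
replicates according to a Dirichlet distribution — jointly, a
Dirichlet-multinomial with concentrations $a_1,\dots,a_K$,
$A=\sum_i a_i$. The count of one OTU is then marginally beta-binomial,

$$P(x \mid N, a, b) = \binom{N}{x}\frac{B(x+a,\,N-x+b)}{B(a,b)},
\qquad a = a_i,\; b = A - a_i,$$

with mean proportion $p = a/(a+b)$ and over-dispersion
$\theta = (a+b+1)^{-1}$. The model's key assumptions:

- one common $\theta$ across the OTUs of a comparison (the joint
  Dirichlet-multinomial forces this);
- replicates are exchangeable draws (no extraction-order or batch
  structure);
- counts are on the simplex: only relative abundances are modeled, never
  absolute load.

Typical values from replicate re-extraction experiments of airway fluids:
$\theta \approx 0.003$ (median), with an observed range of roughly
0.0002–0.0325; the package uses 0.003 as its default reporting value and
exposes 0.03 as the worst case.

## Estimating the over-dispersion

**Method of moments** (`estimate_theta_mom`). Each read is treated as one
categorical observation. For OTU $i$ with per-replicate proportions
$p_{si}$, depths $n_s$, pooled proportion $\bar p_i$, $r$ replicates:

$$\mathrm{MSP}_i = \frac{\sum_s n_s (p_{si}-\bar p_i)^2}{r-1},\quad
\mathrm{MSG}_i = \frac{\sum_s n_s p_{si}(1-p_{si})}{\sum_s n_s - r},\quad
\hat\theta = \frac{\sum_i (\mathrm{MSP}_i-\mathrm{MSG}_i)}
{\sum_i \left(\mathrm{MSP}_i+(n_c-1)\mathrm{MSG}_i\right)},$$

with $n_c$ the usual effective sample size for unequal depths. This is
the canonical pooled moment estimator for Dirichlet-multinomial data;
among the variants in the moment-estimation literature we chose the
pooled (sum-over-OTUs) form because it is the standard one for unequal
totals and is nearly unbiased already at 3 replicates in our recovery
simulations. Negative estimates are sampling noise for a variance-ratio
parameter and truncate to 0. The standard error is a delete-one jackknife
over OTU columns — assumption-light, and directly testable against the
spread of repeated simulations.

**Maximum likelihood** (`fit_dm_mle`). The full concentration vector is
optimized (L-BFGS-B on log-concentrations), initialized at the pooled
observed proportions scaled by $A = (1-\hat\theta_{\mathrm{MoM}})/
\hat\theta_{\mathrm{MoM}}$ (floored at $A=10$, capped at $A=10^9$ when
the moment estimate truncates to zero). Convergence is declared at a
relative log-likelihood change of $10^{-8}$, with at most 500 iterations;
exceeding them raises an error carrying the best-so-far parameters. We
optimize the full vector rather than a (proportions, $\theta$)
factorization: the optimum is identical and the full-vector problem is
smooth and unconstrained in log space.

A property worth knowing: like every dispersion MLE that estimates the
per-OTU means from the same data, $\hat\theta_{\mathrm{MLE}}$ is biased
low by a factor of roughly $(S-1)/S$ with $S$ exchangeable samples —
about −34% at $S=3$ and −17% at $S=6$ in our simulations. This is not an
optimizer artifact. In this package's workflows the MLE is only ever
fitted to the *combined* BAL+OW observations of a comparison (2 samples
pairwise, 6 pooled), where its role is to build a null distribution, and
the resulting conservatism is in the direction the test already embraces.
The recovery studies in the test suite therefore evaluate the moment
estimator on one fluid's 3 replicates (how it is used for reporting
$\theta$) and the MLE on the combined 6 replicates (how it is used for
testing).

## Detection limits

The probability that an OTU of proportion $p$ yields a nonzero count at
depth $N$ is $1 - B(a, b+N)/B(a,b)$ with $a = p(a+b)$,
$a+b = (1-\theta)/\theta$; at $\theta=0$ it reduces to the binomial
closed form $1-(1-p)^N$, which the implementation uses directly. The
*critical proportion* inverts this at a target confidence (default 0.95).
Because detection probability is strictly increasing in $p$, the solver
is plain bisection on $p \in (10^{-12}, 1-10^{-12})$ to $10^{-9}$ on the
proportion — unconditionally convergent, and fast enough that nothing
cleverer is warranted. At $\theta = 0.003$ the critical proportion is
0.98% at depth 500 and 0.32% at depth 5000; at the worst case
$\theta = 0.03$, 3.3% and 1.8%.

The critical *count* $N \cdot p_{\mathrm{crit}}(N)$ is, to a very good
approximation, quadratic in $N$: over the default grid of 100–10,000 in
steps of 100 (chosen to span typical per-sample depths; configurable) a
degree-2 least-squares fit reaches $R^2 = 0.9995$, and a cubic improves
it by less than $10^{-3}$, so `fit_critical_count_curve` reports the
next-degree delta alongside the fit rather than pretending the degree is
a free parameter worth tuning.

## The single-sided outlier tests

**Pairwise** (`pairwise_outlier_test`). The two count vectors are treated
as two observations of one Dirichlet-multinomial and fitted by maximum
likelihood. For each OTU the marginal $BB(a_i, A-a_i)$ at the BAL depth
is the null; the p-value is the inclusive upper tail
$P(X \ge x_{\mathrm{obs}})$. Three deliberate choices:

- *One-sided, BAL direction only.* Lung residence predicts enrichment in
  BAL; depletion is not evidence of anything.
- *The tested OTU stays in the null fit.* A genuinely enriched OTU
  inflates $\hat\theta$ and thereby its own null spread — the test is
  conservative by construction, which our null calibration simulations
  confirm (observed level below nominal at $\alpha = 0.05$).
- *Inclusive tails.* For discrete counts, $P(X \ge x)$ with ties counted
  keeps the p-value valid (never anti-conservative).

Fold changes are reported as the ratio of observed proportions; with a
zero OW proportion the fold is `Inf` — no pseudocount is invented,
because significance is carried by the p-value, not the fold. Calls are
labeled in three tiers (not significant / significant unadjusted /
significant after FDR), with Benjamini–Hochberg adjustment across the
OTUs of one comparison at FDR 5% by default.

**Pooled replicates** (`replicate_outlier_test`). All BAL and OW
replicates enter one fit; the statistic is the *unweighted* arithmetic
mean of per-BAL-replicate proportions (depth-robust; pooling counts would
silently weight deep replicates). The null is Monte-Carlo: each trial
redraws one count per BAL replicate at its observed depth from the
marginal beta-binomial, and the p-value is
$(1+\#\{\text{trial} \ge \text{obs}\})/(1+n_{\mathrm{trials}})$ — the
add-one correction keeps p-values positive and valid, and floors them at
$1/(n_{\mathrm{trials}}+1)$ ($1/10001 < 0.0001$ at the default 10,000
trials; written reports render the floor as `<0.0001`). Only the BAL
replicates are simulated: the statistic involves nothing else, and OW
information enters through the joint fit. Each OTU draws from its own
substream derived deterministically from the master seed, so results are
bit-reproducible and independent of OTU iteration order; a seed is
mandatory. BH adjustment is applied within one subject's analysis — each
subject is its own family of hypotheses.

`compare_pairwise_vs_replicate` runs all $R_{\mathrm{BAL}} \times
R_{\mathrm{OW}}$ pairwise tests alongside the pooled test and tallies
per-OTU call counts. Its typical lesson, reproduced in the test suite: a
strongly enriched OTU is called everywhere; marginal OTUs are called in
scattered pairwise comparisons that replication fails to substantiate.

## The synthetic-data generator

`synthetic_design`/`generate_paired_dataset` emulate the paired-replicate
study design: per-fluid Dirichlet draw then multinomial draw (exact
compounding — marginals are beta-binomial by construction), defaults of
three replicates per fluid at depth 5000 and $\theta = 0.003$. The
baseline community is a geometric rank-abundance over 100 OTUs with the
top OTU near 0.25 — dominance resembling oropharyngeal profiles with a
long rare tail, without copying any real sample.

Planted enrichment is *fold-preserving*: a planted OTU's BAL proportion
is exactly `fold * baseline` and the remaining OTUs are renormalized
into the leftover mass. We chose this over dividing the whole perturbed
vector by its sum because it keeps the planted fold change identical to
the expected ratio of BAL to OW proportions — the quantity the outlier
tests report — so truth tables and test output are directly comparable
(e.g. a baseline-0.0014 OTU planted at fold 580 has expected BAL
proportion 0.81).

What the generator does **not** emulate: sequencing error, chimeras and
denoising artifacts; taxonomy (labels are opaque); depth variation within
a fluid (configurable but defaulted equal); correlated OTU dynamics
beyond the compositional constraint; and contamination from instruments
or reagents. Passing tests on synthetic data therefore establish that the
statistics behave as designed *under the model*, not that the model
captures every failure mode of real airway samples — the conservatism
margins observed in calibration are expected to narrow on data with
structured (non-exchangeable) replicate variation.

One practical consequence quantified by the generator: for an OTU at
baseline proportion 0.001 with $\theta = 0.003$ at depth 5000, the
Dirichlet component alone gives the per-replicate proportion a standard
deviation of $\sqrt{q(1-q)\theta} \approx 0.0017$ — larger than the mean.
Fold-change *estimates* for rare OTUs are therefore intrinsically noisy
(roughly 100% relative error even with 3 replicates), while *calls* are
stable; the test suite accordingly checks rare-OTU fold recovery as a
ratio of proportions aggregated over repeated simulated datasets, and
checks calls on single datasets.

## Numerical choices

- All probability arithmetic is in log space (log-gamma/log-beta); no
  factorials are evaluated at depths up to $10^4$.
- Differences like $\log\Gamma(A+N)-\log\Gamma(A)$ cancel catastrophically
  for huge $A$ (the near-multinomial limit); above $A = 10^7$ they are
  computed as ascending sums $\sum_{j=0}^{N-1}\log(A+j)$ (and
  $\sum 1/(A+j)$ for digamma differences), which is exact at these depths.
- The optimizer box-bounds log-concentrations in
  $[\log 10^{-10}, \log 10^{10}]$ — far outside any data-supported value,
  purely to keep the search in the numerically trustworthy region.
- $\theta = 0$ inputs are handled by closed forms (detection) or an
  internal total concentration of $10^{12}$ (beta-binomial), which is
  binomial to within $10^{-6}$ in probability at depth 1000.
- Degenerate inputs: all-zero OTU columns are dropped before fitting
  (they contribute nothing to the likelihood); zero counts in *some*
  replicates are retained — they carry exactly the axis-abutting signal
  the concordance analysis is about; a single replicate cannot identify
  $\theta$ and errors out.

## Problem sizes in the shipped studies

The test suite's simulation studies use 100-OTU communities at depth
5000: 200 same-distribution pairs for pairwise calibration, 60 repeats
per $\theta \in \{0.0002, 0.003, 0.0325\}$ for estimator recovery, one
full 3×3-replicate analysis plus 100 generator draws for planted-OTU
recovery, and 10,000-trial Monte-Carlo nulls where p-value floors are
asserted. These sizes give Monte-Carlo standard errors comfortably inside
the tolerances they are tested against while keeping the whole suite in
the tens of seconds.

## Known limitations

- A single shared $\theta$ per comparison: OTU-specific dispersion (e.g.
  amplification bias affecting particular taxa) is absorbed into the
  common estimate, diluting power for well-behaved OTUs.
- The pairwise test fitted to exactly two samples estimates $\theta$ from
  one degree of freedom per OTU; it is serviceable because of pooling
  across OTUs, but intervals on $\theta$ from pairwise fits are wide.
- No zero-inflation: an OTU systematically absent from one fluid for
  biological reasons is modeled as merely rare.
- No phylogenetic or taxonomic pooling; every OTU is tested marginally.
- Compositional effects: a single massively enriched OTU depresses every
  other proportion in BAL; the one-sided test is insensitive to this by
  design, but fold changes of non-enriched OTUs shift accordingly.
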