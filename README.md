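# balenrich

Statistical tools for deciding which bacterial lineages in a
bronchoalveolar lavage (BAL) sample are genuinely enriched in the lung,
rather than carried in from the upper respiratory tract. Sampling the lung
with a bronchoscope drags the instrument through the oropharynx, so BAL
16S rRNA gene surveys are substantially admixed with oral bacteria;
simply listing OTUs "present in BAL but not in the oral wash (OW)" is
misleading because rare lineages come and go stochastically between
replicate extractions of the *same* fluid. `balenrich` is written for
microbiome researchers and pulmonary-translational groups analyzing paired
BAL/OW OTU count tables with replicate DNA extractions.

## The model

Replicate OTU count vectors from one fluid are modeled jointly by a
Dirichlet-multinomial distribution with concentration vector
(a<sub>1</sub>, ..., a<sub>K</sub>), total A = Σ a<sub>i</sub>. The count
of a single OTU across N reads is then marginally beta-binomial,

P(x | N, a, b) = C(N, x) B(x + a, N − x + b) / B(a, b),

with a = a<sub>i</sub>, b = A − a<sub>i</sub>. The shapes control the
expected proportion p = a/(a+b) and the over-dispersion
θ = (a + b + 1)<sup>−1</sup>: θ = 0 is plain multinomial resampling,
larger θ means replicate extractions disagree more. On top of this model
the package provides:

- **Over-dispersion estimation** — the pooled (Weir–Hill-style) method of
  moments across OTUs (`estimate_theta_mom()`, with jackknife standard
  errors) and full maximum likelihood by numerical optimization
  (`fit_dm_mle()`).
- **Detection limits** — the probability that an OTU of proportion p is
  observed at all at depth N (`detection_probability()`), and the
  *critical proportion* at which that probability reaches 95%
  (`critical_proportion()`, `detection_curve()`), plus a polynomial fit of
  the critical count against depth (`fit_critical_count_curve()`).
- **Single-sided outlier tests** — for one BAL vs one OW sample, the
  marginal beta-binomial under the joint fit is the null and the one-sided
  p-value is the inclusive upper tail at the observed BAL count
  (`pairwise_outlier_test()`); for pooled replicates, the statistic is the
  mean per-replicate BAL proportion with a 10,000-trial Monte-Carlo null
  (`replicate_outlier_test()`), and `compare_pairwise_vs_replicate()`
  tallies how often pairwise comparisons would have called each OTU.
  Both control the false discovery rate at 5% by Benjamini–Hochberg.
- **Synthetic data** — seed-deterministic paired BAL/OW generators with
  known truth (`synthetic_design()`, `generate_paired_dataset()`,
  `run_recovery_suite()`), so every statistical claim is testable.

## Worked example

Simulate one subject — three BAL and three OW replicate extractions at
depth 5000, over-dispersion θ = 0.003, with one rare OTU (baseline
0.1%) planted 250-fold enriched in the lung — and analyze it:

```r
library(balenrich)

design <- synthetic_design(n_otus = 100, theta = 0.003,
                           enriched_otus = 20, fold_changes = 250, seed = 42)
d <- generate_paired_dataset(design)

estimate_theta_mom(d$ow)
#> Over-dispersion estimate (method of moments): theta = 0.002373
#>   jackknife SE = 0.000739 (over 24 OTUs)
#>   3 replicates, depths 5000, 5000, 5000

res <- compare_pairwise_vs_replicate(d$bal, d$ow, n_trials = 10000, seed = 42)
res[res$significant_fdr, c("otu_id", "bal_proportion", "ow_proportion",
                           "fold_change", "p_value", "q_value",
                           "n_pairwise_fdr", "n_pairwise_raw")]
#>    otu_id bal_proportion ow_proportion fold_change p_value q_value
#> 1 OTU_020          0.255        0.0024         106   1e-04  0.0029
#>   n_pairwise_fdr n_pairwise_raw
#> 1              9              9
```

The planted OTU is the only FDR-significant call: its mean BAL proportion
(25.5%) is ~106× its mean OW proportion in this draw, its Monte-Carlo
p-value sits at the floor 1/10001 (rendered `<0.0001` in written reports),
and it is called in all nine pairwise BAL×OW comparisons both with and
without FDR adjustment. The estimated θ = 0.0024 ± 0.0007 recovers the
planted 0.003.

Detection limits for planning sequencing depth:

```r
detection_curve(theta = 0.003, depths = c(500L, 1000L, 2000L, 5000L, 10000L))
#>   depth critical_proportion critical_count
#> 1   500             0.00978           4.89
#> 2  1000             0.00648           6.48
#> 3  2000             0.00462           9.24
#> 4  5000             0.00324          16.22
#> 5 10000             0.00262          26.21
```

At 500 reads an OTU must reach ~1% of the community to be seen in 95% of
replicate extractions; at 5000 reads, ~0.3%. OTUs below the critical
proportion cannot be distinguished from stochastic sampling noise, so a
"BAL-only" lineage below this line is not evidence of lung residence.

A command-line interface wrapping the same functions is installed at
`exec/balenrich` (subcommands `simulate`, `estimate-theta`,
`detect-limit`, `pairwise`, `replicate`, `compare`).

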