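# rhythmnet

Detection of circadian (24-hour) rhythmic genes from replicated bulk
RNA-seq time courses, and a test of whether cycling genes' peak times are
*organized* on a gene regulatory network.

The package is aimed at analyses of the following design: two independent
time-course experiments (V1, V2) each run under two conditions (e.g.
constant 18°C vs 25°C ambient temperature), with fat-body- or other
tissue-level TPM expression matrices sampled every few hours across the
day. It answers three questions:

1. **Which genes cycle, per condition?** Harmonic (cosinor) regression
   `y = β₀ + β₁cos(ωt) + β₂sin(ωt)`, `ω = 2π/24`, per gene and
   experiment, with an F test against the intercept-only model. A gene
   is a *consensus cycler* when `p < 0.1` in **both** experiments and
   the two phase estimates agree to within 3 h on the circle. The
   criterion's null is analytic: a non-cycling gene passes with
   probability `0.1² × 6/24 = 0.0025`, so the expected false-positive
   count and FDR come for free (`expected_false_positives()`,
   `fdr_estimate()`, `fdr_threshold_sweep()`).
2. **How are the phases distributed?** Circular statistics in ZT hours:
   circular means, signed/absolute circular phase differences, the
   Watson–Wheeler uniform-scores two-sample test, the
   Jammalamadaka–SenGupta circular correlation, an exact binomial sign
   test for a phase advance, and two-component von Mises mixture fitting
   to locate bimodal phase peaks.
3. **Are phases organized on the network?** On the largest connected
   component of a gene interaction graph, the median absolute phase
   difference `|Δφ|` of cycler pairs is profiled against their geodesic
   distance (`phase_distance_profile()`): a positive slope means nearby
   genes peak at similar times. Significance per distance comes from a
   permutation null that re-places the cycler set uniformly over the
   network 5000 times (`permutation_null()`), with degree-bias and
   localization control tests alongside.

A synthetic-data module (`sim_config()`, `simulate_study()`,
`simulate_network()`) generates the full study design with known ground
truth — cycling fractions, amplitudes, bimodal phase models, the V1/V2
sampling schemes, and phase-assortative networks — and drives the test
suite.

## Worked example

Simulate a 2000-gene study (4% / 6% of genes cycling at 18°C / 25°C),
run the whole pipeline, and summarize:

```r
library(rhythmnet)

cfg <- run_config(
  sim = sim_config(n_genes = 2000, frac_cycling_18 = 0.04,
                   frac_cycling_25 = 0.06, frac_shared = 0.3, seed = 20),
  net_sim = net_sim_config(n_nodes = 300,
                           graph_params = list(nei = 1, p = 0.02),
                           per_edge_phase_step = 0.6,
                           placement_noise_sd = 0.5, seed = 21),
  n_perm = 1000, seed = 20)

bundle <- run_pipeline(cfg)
report_summary(bundle)
#> rhythm detection summary
#>   genes after expression filter: 1904
#>   consensus cyclers: 76 (18C), 117 (25C), 23 common
#>   expected false positives: 4.76 (FDR 6.3% / 4.1%)
#>   18C profile slope: 0.503 h/step (p = 6.09e-06, df = 4)
#>   25C profile slope: 0.508 h/step (p = 1.5e-06, df = 4)
```

Reading this: 1904 of 2000 simulated genes pass the median-TPM > 5
expression filter; 76 and 117 genes pass the dual-experiment criterion at
the two temperatures (the truth contains 80 and 120 cyclers, so power is
high), of which `1904 × 0.0025 ≈ 4.8` are expected to be false calls —
an FDR of about 6% and 4%. The simulated networks place cyclers
assortatively with a 0.6 h-per-hop phase drift; the recovered profile
slopes (≈ 0.5 h/step, attenuated by placement noise and graph shortcuts)
are strongly significant.

The per-distance profile against its permutation null:

```r
bundle$network[["18C"]]$null
#> permutation null (relocate), 1000 permutations
#>  distance n_pairs median_dphi null_q025 null_q975 p_two_sided
#>         1      75   0.6850168  2.658132  7.705300 0.001998002
#>         2      79   1.1889559  2.667309  7.682421 0.001998002
#>         3      81   1.7276403  2.860823  7.563249 0.001998002
#>         4      84   2.2582449  3.046170  7.548958 0.011988012
#>         5      87   2.5970304  3.022830  7.447219 0.017982018
#>         6      91   3.2544512  2.936428  7.504718 0.097902098
```

Immediate network neighbours differ by a median 0.7 h — far below the
2.7 h lower null quantile — and the median difference grows steadily with
distance, the signature of network phase organization.

Real data enter through `read_expression()` (TSV matrix + CSV sample
sheet), `filter_genes()`, and `load_network()` (two-column edge list);
`run_config()` accepts file paths in place of simulator configs.

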