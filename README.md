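# netoverlap

Resting-state fMRI networks estimated as *weighted* spatial maps (rather than
hard parcellations) assign many cortical locations to more than one network.
`netoverlap` is an R package for scientists who work with such decompositions
(e.g. probabilistic functional modes or spatial ICA) and want to answer two
questions:

1. **How much do an individual's networks overlap in space?**
2. **What mechanism explains a given two-network overlap region?** Three
   candidate mechanisms are adjudicated: *spatial mixing* (fine interleaving of
   vertices that each belong to one network), *temporal switching* (the region
   changes allegiance over time), and *coupling* (the region carries a
   combination of both networks' signals at every TR).

## What the package computes

Given `K` signed mode maps over `V` grayordinate-like vertices and `V x T`
vertex timeseries per run:

- **Mode matching and selection** — the Hungarian algorithm pairs modes across
  decompositions by maximizing total spatial correlation (cost `1 - r`); modes
  are retained when both the median test-retest and median group-individual
  correlation reach 0.7, and flagged missing in a subject when both fall below
  0.2. Stability measures compare matched maps, netmat edges, and
  overlap-matrix edges (`K(K-1)/2` lower-triangle entries).
- **Spatial overlap** — the threshold-free `K x K` overlap matrix of pairwise
  map correlations, Fisher-z averaged across subjects
  (`tanh(mean(atanh r))`), and binarized overlap count maps (threshold 1 by
  default) weighted by cortical vertex area, with area totals at 2/3/4/5+
  overlapping networks.
- **Two-network vertex assignment** — for a pair `(i, j)`, a vertex is
  N1-unique when `w_i >= 1`, `w_j < 0.1`, and the summed (positive-part)
  weight of the other `K - 2` modes is `< 0.1`; symmetrically N2-unique;
  Overlap when both pair weights pass the threshold; otherwise excluded. A
  3 x 3 robustness grid `{0.75, 1, 1.25} x {0.02, 0.1, 0.5}` is built in, and
  pairs are kept when >= 25 overlap vertices occur in at least half of the
  subjects. Standardized (mean 0, sd 1 per run) N1/N2/Overlap summary
  timeseries are extracted by label-wise averaging.
- **Eight semi-simulated overlap timeseries** — reconstructions of the
  overlap series from the N1/N2 data under each hypothesis: block switching
  at 50/25/10 TRs, per-TR max switching, linear additive coupling
  `z(N1 + N2)`, nonlinear multiplicative coupling
  `z(max(N1,0) * max(N2,0))`, and random / interdigitated spatial mixtures
  built from raw unique-vertex timeseries.
- **Model comparison** — Pearson correlation of each variant with the original
  overlap series (aggregated as medians, with paired t-tests on Fisher-z
  values between adjacent ranks), normalized Fourier power spectra, and a GLM
  suite scored by adjusted `R^2 = 1 - (1 - R^2)(n - 1)/(n - p - 1)`:
  sliding-window switching fits (`O_w = b N1_w` or `b N2_w`, window 10, step
  1, best-of-two per window, averaged), linear / combined / interaction-only
  coupling fits, and per-vertex mixture fits averaged over the overlap region.
- **Synthetic ground truth** — `simulate_dataset()` plants unique and overlap
  territories with known map weights and generates vertex timeseries under a
  chosen mechanism from smoothed (low-frequency) latent network series, so
  the full pipeline can be validated by *mechanism recovery*.

## Worked example

Simulate a small cohort whose overlap region is additively coupled, analyze
it, and rank the hypotheses:

```r
library(netoverlap)

cfg <- synth_config(n_vertices = 300, n_modes = 6, n_runs = 2,
                    n_timepoints = 300, mechanism = "coupling_additive",
                    noise_sd = 0.3, unique_region_size = 25,
                    overlap_region_size = 20)
cohort <- simulate_cohort(cfg, n_subjects = 5, seed = 11)
res <- withr::with_seed(11, analyze_cohort(cohort))
rk <- rank_hypotheses(res$corr,
                      dplyr::filter(res$glm, model != "coupling_combined"))
rk
#> <hypothesis_ranking>
#>   correlation winner: linear_add (median r = 0.996)
#>   GLM winner:         coupling_linear (median adj R2 = 0.992)

rk$correlation$medians
#> # A tibble: 8 × 4
#>   variant      median     n  rank
#>   <chr>         <dbl> <int> <int>
#> 1 linear_add    0.996    10     1
#> 2 mix_random    0.991    10     2
#> 3 max_switch    0.860    10     3
#> 4 switch_50     0.730    10     4
#> 5 switch_10     0.725    10     5
#> 6 switch_25     0.709    10     6
#> 7 mix_interdig  0.675    10     7
#> 8 nonlin_mult   0.581    10     8

rk$correlation$tests[1, ]
#> # A tibble: 1 × 5
#>   higher     lower      statistic      p.value    df
#>   <chr>      <chr>          <dbl>        <dbl> <dbl>
#> 1 linear_add mix_random      19.5 0.0000000116     9
```

Both comparison routes identify the planted mechanism: the linear additive
reconstruction tracks the true overlap series best (median r = 0.996 across
the 10 subject-runs, significantly above the runner-up by a paired t-test on
z-transformed correlations), and the linear coupling GLM achieves the best
median adjusted R² (0.992). The random-mixture variant is the expected
runner-up — averaging half-N1/half-N2 vertices approximates the additive sum —
which is exactly why the GLM route is consulted alongside the correlations.

`run_experiment(experiment_config(...))` wraps the same chain with staged
artifacts, and `mechanism_recovery()` tabulates generating mechanism against
winning hypothesis across mechanisms.

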