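---
title: "Quantifying and explaining overlapping resting-state networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying and explaining overlapping resting-state networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netoverlap)
```

## The problem

Weighted decompositions of resting-state fMRI — probabilistic functional
modes, spatial ICA and relatives — describe each network as a signed map over
grayordinates together with a timecourse. Unlike hard parcellations, these
maps overlap: many vertices carry substantial weight on two or more networks.
`netoverlap` treats that overlap as an object of study. It quantifies it
(overlap matrices, count maps) and asks *why* a given two-network overlap
region exists, by comparing three mechanistic accounts:

- **Spatial mixing** — the region is a fine interleaving of vertices that
  each belong to a single network; stationary decomposition blurs them into
  apparent overlap.
- **Temporal switching** — the region's vertices change network allegiance
  over the run; time-averaged estimation shows both networks.
- **Coupling** — the region genuinely integrates both networks' signals at
  every TR, additively or multiplicatively.

The adjudication strategy is deliberately "semi-simulated": the overlap
region's observed mean timeseries `O` is compared with reconstructions built
only from the *non-overlap* signals (`N1`, `N2`, or the raw unique-region
vertex timeseries) under each hypothesis. A correlation route and a GLM route
run in parallel; their verdicts are reported side by side and never forced
into one, because they weigh different things (the GLM estimates free
amplitude coefficients and is immune to block-phase mismatches, while the
direct correlation is parameter-free).

## Vertex assignment and summary extraction

For a mode pair `(i, j)` a vertex is uniquely associated with network 1 when
`w_i >= net_weight_thr`, `w_j < excl_thr`, and the summed weight of the other
`K - 2` modes is `< excl_thr`; symmetrically for network 2; it is overlap
when both pair weights reach the threshold and the remaining-mode sum stays
below the exclusion value; everything else is excluded. Defaults are
`net_weight_thr = 1` and `excl_thr = 0.1`, with a built-in 3 × 3 robustness
grid `{0.75, 1, 1.25} × {0.02, 0.1, 0.5}`. The thresholds are in map-weight
units, applied to the maps exactly as estimated. An absolute threshold of 1
is conservative for typical mode-weight distributions; users whose maps live
on a different scale should re-derive a percentile-matched value — the
package deliberately defaults to the absolute number rather than a
percentile, so that the rule is transparent and portable.

Two decisions here were genuinely open:

- **The exclusion sum uses positive parts** (`positive_part_sum = TRUE`).
  Negative weights do not constitute network membership, and a signed sum
  would let a strong negative weight on one bystander mode cancel a strong
  positive weight on another, admitting vertices that clearly carry a third
  network. The signed variant is available as a configuration flag.
- **"At least half of the subjects"** in pair selection is `ceiling(0.5 * S)`
  qualifying subjects with >= 25 overlap vertices, which reproduces the
  natural reading for both odd and even cohort sizes.

Summary timeseries (`N1`, `N2`, `O`) are label-wise vertex means,
standardized to mean 0 and sd 1 *within each run*. Standardization throughout
the package divides by the population standard deviation (`n`, not `n - 1`):
the choice is immaterial to every correlation and every `R^2`, and it makes
`sum(z^2) = n` exact, which the GLM code exploits.

## The eight semi-simulated overlap timeseries

From the standardized summaries: block switching at 50, 25 and 10 TRs (the
series starts with the first block of `N1`, then the second block of `N2`,
each block keeping its own time indices; trailing partial blocks are kept),
per-TR max switching (elementwise max of the standardized summaries), linear
additive coupling (`N1 + N2`), and nonlinear multiplicative coupling (the
product after clamping each standardized summary at zero). From raw vertex
data: the random mixture (half the overlap vertices get a random N1-unique
donor with replacement — network 1 takes the extra vertex when the count is
odd — the other half a random N2-unique donor; donors are averaged) and the
interdigitation mixture (each overlap vertex takes the donor network with the
higher map weight, ties to network 1, and that network's unique vertex
nearest in flat vertex index, ties to the lower index). Every output is
standardized.

Numerical edge cases are flagged, not fudged: a zero-variance sum or product
(e.g. exactly anti-correlated summaries, or clamped supports that never
intersect) raises a typed condition that `semisim_bundle()` converts into a
recorded flag, and the variant is simply absent from that run's comparison.
Note the clamping happens on the *standardized* series — an all-negative raw
summary still produces a usable interaction after standardization, which is
the behaviour you want when summaries are z-scored per run anyway.

## The GLM suite and adjusted R²

All fits use demeaned, variance-normalized variables and no intercept.
`R^2 = 1 - SS_res / sum(y^2)`, and model complexity is penalized with the
conventional adjustment `1 - (1 - R^2)(n - 1)/(n - p - 1)`, counting the
absorbed mean as the intercept degree of freedom.

- **Switching**: two single-regressor models (`O_w = b1 N1_w`,
  `O_w = b2 N2_w`) per sliding window of 10 TRs, step 1; the better adjusted
  `R^2` per window is recorded and averaged across the `T - 10 + 1` windows.
  Windows reuse the globally standardized series: per-window re-scaling would
  change the model class and silently absorb switching structure. Windows
  with a zero-variance response or regressor are skipped and counted. The
  best-of-two-per-window maximum is an upward-biased statistic under pure
  noise; the package reports it as defined and leaves the bias question to
  the model comparison, where all candidates face the same data.
- **Coupling**: linear (`O = b1 N1 + b2 N2`), combined (adding the
  interaction), and interaction-only models, where the interaction is the
  zero-clamped product of the standardized summaries, itself standardized
  before fitting so that coefficients are comparable. Because the combined
  model nests the linear one, it tracks it closely by construction; it is
  reported in full but excluded when the pipeline names a single *winning
  mechanism*, since "linear plus a nonlinear term" does not name a different
  mechanism than "linear".
- **Mixture**: a separate two-regressor GLM per overlap vertex, averaged
  across vertices. Zero-variance vertex series are skipped with a count.

Collinear regressors abort the fit with the condition number in the error
message rather than silently dropping a column.

Cohort aggregation uses medians across (pair × subject × run) observations,
and paired two-sided t-tests between adjacent ranks — on Fisher-z values for
correlations, on raw adjusted `R^2` for GLMs — with the (pair, subject, run)
observation as the pairing unit. The switching statistic is likewise
summarized across runs by its median: windows straddling a switch boundary
are intrinsically poorly fit by either single-alliance model, so individual
runs fluctuate with the accident of boundary placement while the cohort
median is stable.

## Mode matching, selection and overlap summaries

Matching minimizes the total assignment cost `1 - r` over the
network-to-network spatial correlation matrix with an `O(K^3)`
shortest-augmenting-path Hungarian solver implemented in the package. The
solver scans columns in a fixed order with strict inequalities, so results
are deterministic across platforms; exact ties between distinct optimal
assignments (measure zero for continuous inputs) resolve to the solver's
fixed scan order. Zero-variance maps correlate as 0 (with a warning) so the
cost matrix stays finite. Matched correlations are *not* Fisher-transformed
inside the matching — the transform is monotone, so it cannot change the
optimum — and negative matched correlations are kept with their sign;
sign-flipping modes is a substantive modelling step the package does not take
silently.

Mode selection retains modes whose median test-retest and median
group-individual correlations both reach 0.7 (a conventional lowest
acceptable reliability); a subject's mode is flagged missing when both of its
correlations fall below 0.2, with non-finite values counting as below.

The overlap matrix is the `K × K` Pearson matrix between mode maps across
vertices; group averaging happens in Fisher-z space with `|r|` clipped at
`1 - 1e-12` before `atanh` so that perfect correlations average finitely.
Count maps binarize at the weight threshold, count modes per vertex, and
aggregate vertex areas at levels 2, 3, 4 and 5+ (levels 0 and 1 are retained
internally).

## The synthetic-data generator

`synth_config()` defines the study conditions. Latent network timeseries are
Gaussian white noise convolved with a circular boxcar of `smooth_len` TRs
(default 7) and standardized; at the default TR of 0.72 s this puts the
kernel's first spectral null near 0.2 Hz and most power below 0.1 Hz, i.e.
the slow autocorrelated character of hemodynamic signals, without an explicit
HRF model. The smoothing width is a free choice — real summary spectra are
not pinned down sharply enough to dictate one — and is surfaced in the
configuration for exactly that reason. A `latent_corr` parameter mixes a
shared component into all latents when correlated networks are wanted;
the default is 0.

Maps plant each mode's unique territory at `weight_high = 1.5` (comfortably
above the binarization threshold of 1) and the designated pair's shared
territory on both modes, over a uniform(-0.005, 0.005) background — small
enough that the bystander-mode exclusion sum cannot trip the default 0.1
threshold on territory vertices. For the interdigitated-mixing mechanism the
generating network of each overlap vertex carries `weight_high + 0.25`, so
the weight-argmax donor rule in the interdigitation reconstruction reflects
the planted alternation; with exactly equal weights the tie-break to network
1 would make that mechanism unrecoverable by construction. Vertex areas
default to 1 mm² so the area-weighted count map is exercised.

Vertex data follow the mechanism exactly: unique-region vertices carry their
latent; overlap vertices carry the planted half/half copies (random or
alternating by index, network 1 taking the odd vertex), the block schedule
(starting with network 1, trailing partial block kept — matching the
semi-simulation's phase so that noise-free switching recovery is exact by
design), the standardized sum, or the standardized clamped product; additive
Gaussian noise of `noise_sd` (in units of the standardized signal) is applied
everywhere. All randomness flows from the single seed in the configuration:
identical seeds give bit-identical datasets.

What the generator does *not* emulate — and what passing recovery tests
therefore cannot certify about real data: hemodynamic convolution and its
lags, physiological and motion noise structure, spatial autocorrelation of
noise, subcortical structures, surface geometry, and overlap among more than
two networks at once. Mechanism recovery on this generator shows the
*analysis chain* is correct and sensitive under realistic noise levels, not
that real overlap regions are simple.

## Problem sizes and validation

The package validates itself at desk scale: recovery cohorts of 20 subjects ×
4 runs with `V = 500`, `K = 12`, `T = 500` (TR 0.72 s), unique regions of 30
vertices, overlap regions of 25 (the pair-selection minimum), and noise sd
0.3 for the noisy cohorts — 25 seeded cohorts for the coupling-recovery rate.
Unit oracles are independent re-implementations: exhaustive permutation
search for the Hungarian solver, explicit normal equations for the GLM, hand
computations for toys. The delimited dataset format round-trips bit-exactly
(`%.17g`); CIFTI-2 input/output is not provided in this build, and
`write_dataset(format = "cifti")` says so rather than approximating.

## Known limitations

- Winners are argmaxes of medians; when two variants are statistically
  indistinguishable the ranking still orders them, and the paired tests are
  the honest summary to read alongside.
- Block-switching reconstructions are not phase-aligned to the data; with
  real data a genuine switching region whose schedule is out of phase with
  the reconstruction will depress the correlation route (the GLM route is
  unaffected by design). Recovery tests therefore use phase-matched
  schedules.
- The sliding-window switching score has no analytic null here; a permutation
  null is easy to build from the package's pieces but is not asserted as a
  test.
- More-than-two-network overlap, lagged or deconvolved couplings, and
  re-estimating modes are out of scope.
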