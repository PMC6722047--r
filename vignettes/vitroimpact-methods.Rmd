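---
title: "Methods: spectral CBF analysis, NPA/BIF scoring and paired endpoint statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spectral CBF analysis, NPA/BIF scoring and paired endpoint statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vitroimpact)
```

This vignette documents the models and procedures the package implements,
the tunable parameters and their defaults, the design choices made where the
methodology was genuinely open, what the synthetic-data generators do and do
not emulate, and the package's known limitations.

# Ciliary beat frequency from video

## Model

A high-speed greyscale recording of beating ciliated epithelium (standard
acquisition: 512 frames at 100 fps, 640×480 px, 8-bit) is treated as a field
of per-pixel intensity time series. A beating pixel oscillates at the local
ciliary beat frequency; slow movement of mucus above the culture adds a
strong sub-2.5 Hz component, and the sensor adds broadband noise. The
analysis is:

1. **Pixel subsampling** on a regular grid, steps 1–8 per axis (step 8/8
   gives the standard 1/64 sampling ratio).
2. **Per-pixel spectrum**: the trace is mean-centered (removing the DC
   intensity level) and its one-sided periodogram power spectral density is
   computed by FFT on the grid `k·fps/N`, `k = 0..⌊N/2⌋`, restricted to
   0–`min(50, fps/2)` Hz, then smoothed with a P-spline and clipped at 0.
3. **Movie spectrum**: the per-frequency *median* over pixel spectra —
   robust to saturated and non-beating pixels — smoothed again with a
   P-spline.
4. **Peak extraction**: the dominant frequency is the argmax of the movie
   spectrum inside the physiological band (default 2.5–25 Hz; the floor
   excludes mucus drift, the ceiling high-frequency noise in damaged
   cultures). The peak band is the maximal interval around the dominant
   frequency over which power decreases strictly moving away from the peak;
   the weighted frequency is the power-weighted mean frequency over the peak
   band.

## Numerical choices

* **Periodogram normalization.** `power[k] = |DFT_k|²/N²`, doubled at
  interior bins, so the one-sided spectrum sums exactly to the population
  variance of the centered trace (Parseval). The tests pin this identity to
  1e-9. Any fixed normalization leaves argmax and weighted means unchanged;
  this one makes the Parseval check exact.
* **P-spline.** Cubic B-spline basis, one knot per grid bin, second-order
  difference penalty, fixed λ = 1, negative fitted values clipped to 0; all
  settings overridable via `smooth_params` (per-pixel and movie-level
  smoothers share settings unless overridden). The knot spacing matters: a
  basis two grid bins wide (support ≈ 1.6 Hz at the standard 0.195 Hz grid)
  smears a strong 1.5 Hz mucus peak past the 2.5 Hz floor over the two
  smoothing passes, at which point the drift steals the argmax from the
  beat. One knot per bin keeps the smoother bandwidth comfortably below the
  guard band while still suppressing bin-level noise; the
  smoothing-neutrality test (a 5× isolated peak moves at most one bin)
  passes under either setting, the drift-rejection test only under the
  narrow one.
* **Peak band rule.** Strict decrease required; a plateau (relative
  tolerance 1e-12) or a zero-power bin terminates the band. Zero power
  cannot "decrease further", and including trailing zero bins would change
  the reported band without affecting the weighted mean (zero weight).
* **Ties.** Argmax ties resolve to the lowest frequency; ties are
  measure-zero on real spectra.
* **Degenerate inputs.** A spectrum with no positive power in the band
  returns a flagged `no_peak` result with `NA` frequencies rather than an
  error: a constant (dead) movie is a legitimate observation.
* fps other than 100 and N other than 512 are supported; the 0–50 Hz cap
  becomes `min(50, fps/2)`.

# Network perturbation amplitude

## Model

A causal network model is a signed two-layer graph: a functional **backbone**
(directed signed cause–effect edges among biological entities) and a signed
**downstream** layer linking backbone nodes to measurable genes. Given a
contrast (per-gene log2 fold-change `β_g` with standard error `se_g`), the
differential node values `f` minimize

```
E(f) = Σ_{(x,y,s) ∈ backbone} (f_x − s·f_y)² + Σ_{(x,g,s) ∈ downstream} (f_x − s·β_g)²
```

— node values should follow the signed causal relations while matching the
signed gene evidence. `E` is a strictly convex quadratic whenever every
backbone connected component carries at least one measured gene (otherwise
the fit is refused, naming the unsupported component); the minimizer solves
the signed-graph-Laplacian system `(L + W) f = S β` and is linear in `β`.

The **NPA score** is the gene-support-weighted mean square
`Σ_x w_x f_x² / Σ_x w_x` with `w_x` the number of downstream genes of `x`;
node contributions `c_x = w_x f_x² / Σ w_x` decompose the score exactly.
Consequences verified by tests: `β ≡ 0 ⇒ score = 0`; `score(cβ) = c²·score(β)`
(in particular sign-flip invariance); the fit matches brute-force numerical
minimization of `E` on all small fixtures.

The exact quadratic form used in the original methodology is published in
its own methods literature rather than restated in exposure studies; the
objective above is this package's concrete instantiation, chosen to
reproduce every property the downstream analyses rely on (directional
fitting linear in `β`, a nonnegative amplitude, an exact leading-node
decomposition).

## Uncertainty and companion statistics

* **Confidence interval / p_exp** (`npa_uncertainty`): parametric Monte
  Carlo, `β̃_g ~ Normal(β_g, se_g²)`, refit and rescore; CI = 2.5/97.5
  percentiles. `p_exp` compares the observed score against null draws
  `Normal(0, se_g²)` with the add-one estimator `(1 + #{null ≥ obs})/(1 + n)`
  (never exactly zero).
* **O statistic**: permute the assignment of `β` values to downstream gene
  slots, network fixed — is the score specific to *which* genes sit where?
* **K statistic**: rewire the backbone by shuffling the endpoint multiset
  and re-pairing (edge count and degree sequence preserved, signs reshuffled
  with the edges), downstream layer fixed — is the score specific to the
  causal structure? Rewired graphs are constrained to remain *valid*
  backbones (no self-loops, no parallel edges): allowing parallel edges
  would place the permutation null partly outside the model class and makes
  p_K measurably conservative under the null. Backbones with fewer than two
  edges report `p_K = NA`.
* A network is called **significant** when all three p values are below
  0.05. No multiplicity adjustment is applied across networks (per-network
  calls at 0.05); users comparing many networks should adjust externally.
* K is powered against perturbations that the causal structure itself
  predicts: a backbone-**coherent** signal (node values sign-consistent
  along edges, `planted_perturbation(coherent = TRUE)`) yields small p_K,
  while an incoherent random-subset perturbation is detected by p_exp and
  p_O but not necessarily by K — the structure carries no information about
  it. This is expected behavior, not a power defect.

Defaults: `n_draws = n_perm = 500`; every stochastic operation takes an
explicit seed. Duplicate genes under several backbone nodes are allowed
(each edge contributes its own term). Genes missing from a contrast are
dropped with a message; a node losing more than half its gene support is
flagged in the output.

## Leading nodes and NPA modules

Leading nodes are the minimal prefix of the contribution-sorted nodes
(ties lexicographic) covering 80% of the score (threshold configurable).
The NPA module is the connected backbone subgraph maximizing total node
score, where leading nodes score their contribution and all others pay a
penalty (default: the median non-leading contribution) — a low node is
included only as a bridge worth its cost. Search is exhaustive over
connected subsets up to 15 backbone nodes (tests pin agreement with an
independent enumeration oracle) and greedy (best-frontier growth, best
prefix kept) above.

## Biological impact factor

Each network's scores are rescaled by that network's maximum across the
contrast set (networks scoring zero everywhere drop out), so no single
network dominates. Family aggregates are means of rescaled member scores,
the BIF of a contrast is the mean of its family aggregates, the relative BIF
normalizes to the maximum contrast (marked REF = 100%, exactly one per set),
and family shares express each family's percentage of the contrast's
aggregate total (summing to 100 where defined). The rescaling step is one
reading of "hierarchically structured aggregation"; it makes REF exact and
shares comparable across families, and is documented here because the
aggregation weighting (networks vs sub-networks vs families) is not fully
pinned down by the source methodology.

# Paired endpoint statistics

* **Per-gene contrasts** (`paired_contrast`): within-run differences
  `d_r = exposed_r − air_r`, `log2fc = mean(d)`, `se = sd(d)/√n`,
  two-sided t with `n−1` df, BH-FDR across genes. The run blocking makes the
  analysis exactly invariant to run-level offsets shared by both arms
  (tested). Zero-variance genes get `p = 1` and a flag — dropping them would
  silently change the BH denominator. An ordinary (unmoderated) paired t is
  used: at the 9-run scale of the emulated design with synthetic data it
  reproduces the blocking structure exactly, and no moderation formulas are
  part of the methodology being implemented; `bh_adjust` wraps the standard
  step-up adjustment.
* **DEGs**: FDR < 0.05 (flag-adjustable), split by fold-change sign.
* **Mediators** (`mediator_foldchanges`): fold-change = ratio of geometric
  means (exposed/air), paired t on log concentrations. Nonpositive readings
  are floored at half the analyte's smallest positive value (configurable)
  and flagged; an all-floored analyte is flagged below-detection. Handling
  of above-curve readings is left to upstream quantification.
* **Histopathology** (`histo_distribution`): percent of samples per ordinal
  severity level per (finding, group); rows sum to 100; a (finding, group)
  with no samples reports NA ("not applicable"), never 0%.

# Synthetic data: what it emulates and what it does not

* `gen_beat_movie`: beating pixels share one frequency but carry i.i.d.
  uniform phases — per-pixel spectra identical in expectation yet
  desynchronized, the regime in which the median-over-pixels step is
  meaningful. Non-beating pixels (fraction configurable) carry only drift +
  noise, emulating field-of-view heterogeneity. The coherent sub-2.5 Hz
  drift emulates mucus movement. *Not* emulated: cilia hydrodynamics,
  optical point-spread, metachronal waves, frequency drift over time.
* `gen_contrast`: `β_g = s·f0_x + Normal(0, noise_sd)`; `se_g` is reported
  as the true noise sd, keeping the uncertainty calibration exact by
  construction. Real contrasts carry estimated, gene-dependent standard
  errors and correlated noise; passing calibration here shows the machinery
  is correct, not that real-data p values are exact.
* `planted_perturbation` defaults to a fixed planted magnitude of 2 on a
  random 30% of nodes (gene-level `β` at 10× its standard error — a strong,
  clearly detectable perturbation). Equal planted effect sizes keep
  leading-node recall well defined: contributions scale as `f0²`, so under
  strongly heterogeneous magnitudes the cumulative-80% leading-node
  definition necessarily drops the weakest true nodes no matter how good the
  fit is. `coherent = TRUE` instead propagates sign-consistent values along
  the backbone (all nodes perturbed), the regime the K statistic is powered
  against.
* `gen_null_matrix`: 9-run paired design with shared run offsets and no
  treatment effect, for type-I-error control; `gen_mediator_panel`:
  log-normal concentrations with planted log2 effects.
* All generators are byte-deterministic given their seed and write exactly
  the file formats the analysis functions read (round-trip tested).

# Problem sizes used in tests

The test and acceptance fixtures use 32×32-pixel movies (512 frames,
subsampling step 2 → 256 pixel series) rather than full 640×480 frames: the
spectral pipeline is identical per pixel and the median is already stable at
a few hundred desynchronized pixels, so the smaller field exercises every
code path while keeping the 40-movie recovery battery fast. Null
calibrations use 500 replicate datasets at 200 permutations/draws each, and
the DEG null control 200 datasets of 2000 genes × 9 runs.

# Known limitations

* The NPA objective, CI construction, and O/K definitions are this package's
  instantiations of a methodology whose exact equations are published
  elsewhere; scores are comparable within this package, not numerically
  against other implementations.
* The greedy NPA-module search above 15 backbone nodes is a heuristic; it is
  exact on all enumerable fixtures but carries no optimality guarantee.
* The paired t is unmoderated; with very few runs and many genes,
  empirical-Bayes variance moderation (as in standard microarray pipelines)
  would gain power.
* BH-FDR is not idempotent in general (re-adjusting an adjusted vector can
  change it when ties are created); the tests assert the true properties —
  oracle equality, monotonicity, `adj ≥ p`, cap at 1.
* TIFF I/O is 8/16-bit greyscale only; RGB recordings are rejected rather
  than converted.
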