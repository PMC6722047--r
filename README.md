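# vitroimpact

Systems-toxicology scoring of in vitro aerosol-exposure experiments on 3D
organotypic airway cultures. The package implements the computational core of
a comparative exposure study — e.g. e-cigarette aerosol versus cigarette
smoke on reconstituted human buccal and small-airway epithelium — as a
reusable, fully tested pipeline:

* **Ciliary beat frequency (CBF)** from high-speed video: per-pixel
  periodogram power spectral densities of mean-centered intensity traces,
  penalized-B-spline (P-spline) smoothing, a robust per-frequency median
  across pixels, and dominant/weighted frequency extraction inside the
  physiological 2.5–25 Hz band (the 2.5 Hz floor rejects slow mucus drift,
  the 25 Hz ceiling high-frequency noise).
* **Network perturbation amplitude (NPA)** scoring of transcriptomic
  contrasts on signed two-layer causal network models: differential backbone
  node values are fitted by least squares so that they best satisfy the
  signed causal relations while matching the signed gene-level log2
  fold-changes, giving the score
  `NPA = Σ_x w_x f_x² / Σ_x w_x` (`w_x` = genes under node `x`) with an
  exact additive node decomposition, a Monte Carlo confidence interval, an
  experimental-variation p value, the O/K permutation companion statistics
  (gene-assignment and backbone-structure specificity), leading nodes, and
  maximum-score connected NPA-module subgraphs.
* **Biological impact factor (BIF)**: per-network scores rescaled by each
  network's maximum over the contrast set, aggregated into family means and
  a single impact number per contrast, normalized to the maximum contrast
  (marked `REF = 100%`) with family percentage shares.
* **Paired endpoint statistics**: per-gene exposed-vs-air paired t contrasts
  blocked by exposure run, Benjamini–Hochberg FDR with DEG counting
  (FDR < 0.05), geometric-mean fold-changes of secreted inflammatory
  mediators with paired tests on log concentrations, and percent
  distributions of ordinal histopathology scores.
* **Synthetic-data generators** reproducing the statistical structure of
  every input — beat movies with known frequency, mucus drift and noise;
  causal networks with planted (optionally backbone-coherent) perturbations;
  blocked null expression designs; mediator panels — so the entire pipeline
  is testable without any study data.

## Worked example

```r
library(vitroimpact)

## --- CBF: recover a planted 8.0078 Hz beat under drift and noise ---------
mv  <- gen_beat_movie(f_beat = 8.0078125, fps = 100, n_frames = 512,
                      height = 32, width = 32, amplitude = 30, noise_sd = 10,
                      drift_amplitude = 10, seed = 5)
cbf(mv, step_row = 2, step_col = 2)
#> cbf_result: dominant 8.008 Hz (power 115.2), peak band [7.227, 8.789] Hz, weighted 8.008 Hz

## --- NPA: score a coherent planted perturbation on a 20-node model -------
net <- gen_network(20, "scale-free", genes_per_node = 10, seed = 7)
pl  <- planted_perturbation(net, coherent = TRUE, noise_sd = 0.2)
ct  <- gen_contrast(net, pl, seed = 7)
npa(net, ct, n_draws = 500, n_perm = 500, seed = 7)
#> npa: network 'synthetic' (synthetic)
#>   score 4.144  [4.037, 4.252]
#>   p_exp 0.001996  p_O 0.001996  p_K 0.001996  -> significant
#>   leading nodes: N18, N19, N07, N17, N02, N10, ...

## --- BIF: aggregate scores across contrasts ------------------------------
compute_bif(data.frame(contrast = c("CS_24h", "EC_24h"),
                       network = "necroptosis", family = "cell fate",
                       score = c(4.144, 1.036)))
#> bif_result:
#>  contrast  bif relative_bif_pct is_ref
#>    CS_24h 1.00              100   TRUE
#>    EC_24h 0.25               25  FALSE
```

The dominant frequency is the argmax of the smoothed movie-median spectrum
inside 2.5–25 Hz (here exactly the planted beat, one FFT bin = 0.195 Hz);
the NPA score is significant because all three companion p values
(experimental variation, O, K) fall below 0.05; the relative BIF expresses
each contrast as a percentage of the strongest one.

A thin CLI over the same functions lives at `inst/cli/vitroimpact.R`
(`cbf`, `npa`, `bif`, `dge`, `mediators`, `histo`, `simulate` subcommands).

## Scope

Gene-level log2 expression matrices are taken as input (array preprocessing
and normalization are upstream concerns), network models are treated as
opaque signed graphs with string node labels, and instrument-side steps
(aerosol generation, particle sizing, Luminex curve fitting, pathology
scoring) are out of scope. See `vignettes/vitroimpact-methods.Rmd` for the
model details, parameter choices and known limitations.
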