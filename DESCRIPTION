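Package: vitroimpact
Title: Systems Toxicology Scoring of In Vitro Aerosol Exposures
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis pipeline for organotypic airway-culture exposure
    studies: ciliary beat frequency extraction from high-speed video by
    periodogram spectral analysis with penalized B-spline smoothing,
    network perturbation amplitude (NPA) scoring of transcriptomic
    contrasts on signed two-layer causal network models with permutation
    companion statistics and biological impact factor (BIF) aggregation,
    paired exposed-versus-air differential statistics with
    Benjamini-Hochberg FDR control, and synthetic-data generators that
    reproduce the statistical structure of each input so the whole
    pipeline is testable without raw study data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    splines,
    stats,
    tiff,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
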