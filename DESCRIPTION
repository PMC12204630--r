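Package: crpspike
Title: Canonical Response Parameterization of Extracellular Spike Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for parameterizing single-unit action potentials from
    extracellular microelectrode recordings, as acquired during deep brain
    stimulation surgery. Implements threshold detection and template-match
    spike sorting, empirical discovery of the significant spike window and
    canonical unit shape by projection profiling, per-spike scaling weights
    and quality metrics, resolution of overlapping spikes by serial
    subtraction and re-sorting, a normalized spike-shape similarity metric
    with agglomerative clustering, cardiac pulse-modulation fitting of
    per-spike amplitudes, and spike-removed local field potential isolation
    with spectral comparison. Includes a synthetic recording generator with
    known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
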