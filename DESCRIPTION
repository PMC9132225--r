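Package: medplast
Title: Multielectrode-Array Synaptic Plasticity Analysis
Version: 0.9.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis pipeline for 8x8 planar multielectrode-array (MED64-style)
    field-potential recordings of synaptic plasticity in cortical slices.
    Extracts fEPSP slope and amplitude per channel and sweep, classifies
    activated and stable channels, applies slice-level quality control,
    normalizes responses to baseline, quantifies long-term potentiation and
    depression from the last-10-minute window, computes paired-pulse ratios,
    detects recruited (unsilenced) and silenced channels, builds layer-resolved
    spatial maps, and runs the standard group comparisons (Welch t-test,
    two-way ANOVA with Sidak or Tukey post-hoc tests). Ships a synthetic
    slice-recording generator with condition presets so the whole pipeline is
    exercisable and testable without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    data.table,
    jsonlite,
    emmeans
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
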