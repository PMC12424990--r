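Package: slicepasef
Title: Design, Evaluation and In Silico Simulation of Slice-PASEF and
    dia-PASEF Acquisition Schemes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A desk-scale toolkit for data-independent acquisition (DIA)
    method development on trapped-ion-mobility (TIMS) time-of-flight
    instruments. Represents and synthesizes peptide precursor ion clouds in
    m/z x ion-mobility space, designs Slice-PASEF (1-, 2- and 4-frame) and
    reference dia-PASEF isolation-window schemes over them, computes
    analytic figures of merit (MS/MS duty cycle, cycle time, intensity
    coverage, points per chromatographic peak), simulates acquisition in
    silico into streams of boundary-annotated frame spectra, and implements
    an ion-mobility-aware fragment matching and quantification engine
    (frame candidacy against per-peak isolation boundaries, multi-frame
    best-peak fragment intensities, frame-repeat merging, extracted ion
    chromatograms, coefficient-of-variation summaries).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    data.table,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
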