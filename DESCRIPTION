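Package: aromatch
Title: Semi-Automated GC-MS Aroma Profiling and Whisky Classification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A semi-automated pipeline for rapid aroma characterization from
    GC-MS chromatograms: Biller-Biemann style peak deconvolution, linear
    retention index calibration against an n-alkane series (van den Dool and
    Kratz), library-based compound identification through a combined
    mass-spectral cosine / retention-index score with a +/-30 index-unit
    window, blank subtraction, internal-standard relative quantification, and
    statistical classification of two-class sample sets (e.g. Scotch versus
    American whisky) from analytical and rapid-sensory (RATA/CATA) data via
    repeated-subsampling linear discriminant analysis. Includes a fully
    seeded synthetic-data generator (model-whisky chromatograms, alkane
    reference runs, blanks, spectral libraries with decoys, and two-class
    sensory panels) that provides ground truth for every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    utils,
    tools,
    pracma,
    jsonlite
Suggests:
    mzR,
    MASS,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
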