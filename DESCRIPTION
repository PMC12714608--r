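Package: crbdia
Title: Multi-Gradient DIA Metabolomics Deconvolution and Sensory-Guided
    Feature Discovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for sensory-guided nontargeted metabolite discovery by
    liquid chromatography high-resolution mass spectrometry with
    data-independent acquisition (DIA). Implements chromatographic
    retention behavior (CRB) deconvolution, which links SWATH fragments to
    their precursor ions by requiring that fragment retention times track
    the precursor across a systematic series of nine LC gradients, plus
    the surrounding workflow: a ground-truthed synthetic data generator
    (linear-solvent-strength retention physics, DIA scan simulation,
    sensory-panel scores), untargeted MS1 feature detection, targeted
    re-quantification of pooled-QC features in single-gradient sample
    runs, sensory-panel outlier screening and PCA/k-means sample grouping,
    Welch-t differential feature selection with accumulated ion
    chromatograms, spectral-library dot-product annotation with
    standard-based level-1 confirmation, and single-point
    standard-addition quantification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    readr,
    jsonlite,
    yaml,
    mzR,
    stats,
    utils
Suggests:
    mclust,
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
VignetteBuilder: knitr
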