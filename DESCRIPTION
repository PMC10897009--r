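Package: strokemri
Title: Multiparametric MRI Quantification for Experimental Stroke
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Longitudinal multiparametric MRI quantification for rodent models
    of transient focal cerebral ischemia. Computes apparent diffusion
    coefficient (ADC), T2 and serial R1 relaxometry maps, dynamic
    susceptibility contrast (DSC) perfusion maps (CBF, CBV, MTT) by
    block-circulant SVD deconvolution, blood-brain-barrier permeability (Ki)
    by a reference-region generalized Patlak plot, and cerebrovascular
    reactivity (CVR) from hypercapnic-challenge BOLD series. Lesion-core
    region-of-interest analytics derive acute and final lesion masks, mirrored
    contralateral homologues, relative regional perfusion indices, and
    hemispheric lesion volumes. A digital rat-brain phantom generates every
    input modality with known ground truth so each processing stage is
    verifiable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    RNifti,
    jsonlite,
    yaml,
    pracma,
    tibble,
    dplyr,
    tidyr,
    generics,
    ggplot2,
    rlang
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
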