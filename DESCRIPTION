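Package: nigrascan
Title: Neuromelanin- and Iron-Sensitive MRI Quantification of the Substantia Nigra and Locus Coeruleus
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Threshold-based segmentation and contrast quantification of the
    substantia nigra and locus coeruleus on neuromelanin-sensitive MRI,
    two-point R2* relaxometry from dual-echo gradient-echo magnitudes, ROI
    sampling of susceptibility maps, and the cohort statistics used to relate
    these measures to striatal dopamine-transporter binding: Mann-Whitney group
    comparisons, FDR-corrected Spearman correlation batteries, ROC analysis
    with exact Clopper-Pearson intervals, intraclass correlation reliability,
    and least-squares prediction of DAT binding. A synthetic phantom and
    cohort generator with known ground truth drives testing and validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports: methods, stats, utils, tools, RNifti, yaml, jsonlite
Suggests: testthat (>= 3.0.0), pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
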