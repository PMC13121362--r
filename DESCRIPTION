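Package: fetquant
Title: Quantitative [18F]FET PET/MRI Analysis for IDH-Mutant Glioma
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Background-referenced tumour segmentation and uptake metrics for
    amino-acid PET of diffuse glioma: mean contralateral background estimation,
    1.6-fold threshold segmentation, TBR_max/TBR_mean and PET-RANO positivity,
    Dice overlap between PET volumes and MRI lesion masks, dynamic
    time-activity-curve classification (increasing/stable/decreasing) with
    minimal time-to-peak (TTP_min), a cohort statistics layer (chi-square,
    Fisher, Mann-Whitney U, Kruskal-Wallis, Cohen's kappa, median/range
    summaries), and synthetic phantom/cohort generators with known ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    RNifti,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
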