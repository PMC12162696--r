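Package: aindex
Title: Voxel-Wise Asymmetry-Index Quantification of Cerebral Hypometabolism
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantifies hemispheric asymmetry of brain FDG-PET uptake in
    unilateral ischemic cerebrovascular disease. Converts PET activity
    volumes to standardized uptake value ratio (SUVR) maps against a pons
    reference, optionally applies Van-Cittert partial-volume correction,
    computes two voxel-wise asymmetry indices (contralateral-normalized AI1
    and bilateral-mean-normalized AI2) after excluding infarcted voxels and
    their mirror partners, and measures hypometabolic volume and percentage
    per lobe and hemisphere with a 10 percent threshold. Includes a
    synthetic brain-phantom generator with geometric ground truth, a
    cohort-level statistical layer (paired t-tests, Bland-Altman agreement,
    Spearman correlation with NIHSS and mRS scores, follow-up change), and
    an end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    RNifti,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'volio.R'
    'blur.R'
    'phantom.R'
    'prep.R'
    'asym.R'
    'cohort_stats.R'
    'pipeline.R'
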