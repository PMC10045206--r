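Package: pcatomics
Title: Pericoronary Adipose Tissue Radiomics from Coronary CT Angiography
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An end-to-end pipeline relating pericoronary adipose tissue
    (PCAT) radiomics on coronary CT angiography to vessel-level
    vulnerable-plaque labels. Segments PCAT as a peri-vessel annulus of
    radial width equal to the vessel diameter intersected with the adipose
    Hounsfield window (-190 to -30 HU), extracts a 1356-value radiomic
    signature per vessel (shape, first-order and five texture families at
    three gray-level discretizations, aggregated across slices by min, max,
    mean and standard deviation), reduces it by correlation pruning,
    univariate cross-validated AUC screening, minimum-redundancy
    maximum-relevance selection and coefficient-based recursive elimination,
    and evaluates the final logistic model by repeated stratified three-fold
    cross-validation. Includes a synthetic straightened-vessel CT phantom
    generator with controllable adipose attenuation and texture effects for
    calibration and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    RNifti,
    pROC
Config/testthat/edition: 3
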