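Package: octskin
Title: Skin Thickness and Attenuation Coefficient Estimation from OCT Volumes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies photodamage-related changes in skin from volumetric
    optical coherence tomography (OCT) data. Provides a layered-skin phantom
    generator with known ground truth, readers and writers for multi-page TIFF
    volumes with JSON sidecars, A-scan block averaging and edge trimming,
    reference-based intensity calibration, peak-based segmentation of the skin
    surface, dermal-epidermal junction and dermis-muscle boundary, per-A-scan
    attenuation coefficient estimation by linear fits of log intensity under a
    single-scattering Lambert-Beer model, and the longitudinal group-comparison
    plan (IQR outlier filtering, one-way ANOVA gate, Mann-Whitney U follow-ups)
    used to compare control and UV-irradiated groups over time.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    tiff,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
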