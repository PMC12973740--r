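Package: mandifrac
Title: Trabecular Texture and Radiomorphometric Analysis of Panoramic Radiographs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Box-counting fractal dimension and gliding-box lacunarity of
    skeletonized trabecular bone patterns from panoramic radiograph regions
    of interest, together with the Rudolph-White preprocessing chain
    (Gaussian background removal, thresholding, morphological cleaning,
    inversion, thinning), mandibular cortical width (MCW) and panoramic
    mandibular index (PMI) from landmark geometry, and the nonparametric
    three-group statistical layer (Kruskal-Wallis, Dunn-Bonferroni post hoc,
    rank eta-squared, Cohen's f, ANOVA-approximation power, age/sex
    covariate regression). Includes synthetic phantom and cohort generators
    with known ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, grDevices, jsonlite, tiff, png
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
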