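Package: invacast
Title: Prioritising Potentially New Invasive Plants Under Climate Change
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for prioritising potentially new invasive
    plant species under climate change. Combines presence-background
    maximum-entropy habitat-suitability modelling (projected onto baseline
    and future climates), dual-threshold habitat classification (least
    training presence and sensitivity-specificity sum maximization),
    habitat-area change metrics on geodesic cell areas, a criterion-based
    invasiveness risk score with category bands, and a two-axis
    prioritisation that ranks species by risk category and projected gain
    in suitable high-risk habitat. Includes derivation of the 19 standard
    bioclimatic variables from monthly climatologies, Pearson/VIF
    collinearity filtering, ESRI ASCII raster input/output, and a
    virtual-species simulator so every stage can be exercised against
    known ground truth without external downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports: stats, utils, graphics, grDevices, yaml
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
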