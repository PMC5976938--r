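Package: cartiqmap
Title: Quantitative MRI Relaxometry and Depth-Dependent Composition
    Modelling of Articular Cartilage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A reproducible pipeline for comparing quantitative MRI (qMRI)
    relaxation maps of articular cartilage with a depth-dependent
    computational model of tissue composition. Provides a synthetic
    osteochondral phantom with known ground truth, pixel-wise least-squares
    fitting of mono-exponential (T2*, T1rho) and magnitude inversion-recovery
    (T1) signal models with adjusted R-squared quality control, normalized
    cartilage depth and zonal/regional segmentation on curved samples, a
    calibrated depth-dependent volume-fraction and collagen fiber orientation
    model after the Benninghoff arcade, and pixel-wise Spearman correlation,
    curve-fit and non-parametric group-comparison statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
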