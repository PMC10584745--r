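Package: ctfriqa
Title: Full-Reference Image Quality Assessment Benchmarking for CT Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to benchmark full-reference image quality assessment
    (FR-IQA) methods on computed tomography (CT) images. Provides CT
    window/level display conversion and background cropping, a Gaussian
    noise and blur distortion grid generator, from-scratch implementations
    of nine FR-IQA metrics (PSNR, SSIM, MS-SSIM, IW-SSIM, FSIM, IFC, VIF,
    NQM, VSNR), a synthetic CT phantom generator with a simulated
    double-stimulus continuous quality scale (DSCQS) observer panel,
    intraclass correlation analysis of rater agreement, and a performance
    evaluation harness (five-parameter logistic nonlinearity correction,
    PLCC, SROCC, RMSE, and one-tailed residual F-test significance
    matrices).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    png,
    EBImage,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
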