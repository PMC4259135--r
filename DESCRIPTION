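Package: ivuspmd
Title: Coronary Plaque Boundary Detection in IVUS Images with a
    Modified Perona-Malik Diffusion Filter
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects the luminal and adventitial plaque boundaries in
    intravascular ultrasound (IVUS) B-mode images.  The pipeline resamples
    the cross-sectional image into polar coordinates, reduces speckle noise
    with an anisotropic Perona-Malik diffusion filter whose per-direction
    strengths are tuned to preserve the near-horizontal plaque boundaries,
    localises boundary candidates with a weighted linear-discriminant image
    separability statistic, and reconstructs smooth periodic boundary
    curves by Takagi-Sugeno fuzzy inference with linear consequents fitted
    by weighted least squares.  A synthetic polar IVUS phantom generator
    with known ground-truth boundaries supports end-to-end validation, and
    an 'ivus-pmd' command-line script exposes every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    png,
    tiff,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
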