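Package: chromatrace
Title: Video-Based Colorimetric Reaction Monitoring and Mixing Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts videos (or directories of still frames) of
    color-changing chemical and biochemical processes into time-resolved
    kinetic data. Computes per-region-of-interest color traces in RGB, HSV
    and CIE-L*a*b* space, CIE76 Delta E against a reference frame, and the
    RGB sum response; detects reaction onset and plateau end-points; fits
    pseudo-first- and second-order rate laws; estimates mutual information
    between color traces and sparse offline measurements; and quantifies
    spatial mixing with an interfacial-perimeter (Contact) metric and
    gray-level co-occurrence matrix (GLCM) texture features. Includes
    seedable synthetic-video generators (uniform reactions, stirred dye
    mixing, multi-well plates) so every analysis stage is testable without
    recorded footage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    farver,
    optparse,
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
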