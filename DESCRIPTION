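Package: palmvein
Title: Contact-Free Palm-Vein Recognition from Whole-Palm NIR Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A whole-palm, contact-free palm-vein verification pipeline for
    near-infrared (NIR) hand images. Segments the full palm (fingers included,
    wrist excluded) with Otsu thresholding, enhances vein texture with a
    hierarchical difference-of-Gaussians plus histogram-equalization scheme,
    extracts scale-invariant keypoints with RootSIFT (Hellinger-kernel)
    descriptors, matches them with Lowe's ratio test, and removes mismatches
    with a two-stage filter: centroid-relative neighborhood consistency
    followed by uniform local-binary-pattern histogram comparison. Surviving
    match counts are turned into verification scores and FAR/FRR/EER reports.
    Includes a seeded synthetic NIR vein-image generator with ground-truth
    transforms so every stage is testable without external data, and a
    command-line interface for enhancement, matching, batch evaluation and
    fixture generation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tools,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
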