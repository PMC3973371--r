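Package: frictionpads
Title: Contact Mechanics and Scaling Analysis of Fibrillar Insect Friction Pads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how fibrillar 'friction pads' (the acantha-covered
    euplantulae of stick insects) build real contact area under normal load.
    Provides a Greenwood-Williamson-style forward simulator of a conical fibril
    bed under a curved pad (tip-to-side contact transition, shear biasing),
    a synthetic contact-image generator with ground truth, ImageJ-style particle
    quantification (segmentation, moment-equivalent ellipses, convex-hull
    projected area, sampled density, optical boundary error), the hierarchical
    contact-area decomposition A_R = A_A * N_A * A_Ac with random-intercept
    power-law fits (marginal and conditional R^2), and a suite of friction-law
    models (Amonton and adhesion-extended fits, constant shear stress, contact
    growth rate, JKR adhesive sphere) for comparing friction pads with soft
    adhesives and rigid materials.
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
    grDevices,
    jsonlite,
    lme4,
    mgcv,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    EBImage
Suggests:
    nlme,
    png,
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
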