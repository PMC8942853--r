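Package: avimorph
Title: Inertial Characteristics, Pitch Stability and Evolutionary Analysis of
    Morphing Bird Wings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Models a flying bird as a composite of simple geometric solids to
    compute its centre of gravity and moment-of-inertia tensor across the elbow
    and wrist range of motion. Derives longitudinal static-stability metrics
    (standard-mean-chord quarter chord, neutral point, static margin) and a
    proportional pitch-agility metric per wing configuration, converts
    motion-capture marker data to joint angles and range-of-motion convex
    hulls, and fits Brownian-motion and Ornstein-Uhlenbeck models of trait
    evolution on a phylogeny with AICc comparison, Monte-Carlo likelihood-ratio
    model selection, phylogenetic least-squares allometry, joint-angle
    effect-size models, and a centre-of-gravity error bootstrap. Includes
    seeded generators for synthetic specimens, marker traces, trees and traits
    so the full pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    car,
    dplyr,
    generics,
    ggplot2,
    grDevices,
    jsonlite,
    mgcv,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    nlme,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
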