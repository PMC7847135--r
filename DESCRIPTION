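Package: spotmorph
Title: Quantitative Analysis of Dorsal Spot Patterns in Triatomine Bugs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An image-analysis pipeline for discriminating Triatoma dimidiata
    haplogroups from the light spot pattern of the dorsal abdomen. Standardizes
    dorsal photographs into a common geometric frame, segments the light spots,
    numbers them by the central/lateral convention, and measures relative areas,
    Feret diameters and angles, and aspect ratios. Downstream tools provide
    per-group spot-frequency heat maps, nonparametric group comparisons
    (Kruskal-Wallis), forward-stepwise linear discriminant analysis with Wilks'
    lambda, a multilayer-perceptron classifier with permutation variable
    importance, and a synthetic-specimen generator that emulates the three
    haplogroup archetypes so the whole pipeline is testable without external
    images.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    MASS,
    igraph,
    jsonlite,
    png,
    tiff,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    nnet,
    vegan,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
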