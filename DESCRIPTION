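Package: fibrilmorph
Title: Morphometry of Collagen Fibril Networks in Grayscale Micrographs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the organization of fibrillar networks (such as
    extracellular collagen fibrils imaged by scanning electron microscopy)
    from grayscale raster images. A Canny edge detector followed by
    morphological closing and topology-preserving thinning reduces each
    image to a one-pixel-wide skeleton; the skeleton is decomposed into a
    graph of endpoints, junctions and line segments; and two structural
    statistics are computed from the segments: the bending ratio
    (mean-squared end-to-end distance over mean-squared contour length)
    and the persistence length of a planar worm-like chain, estimated
    either from the end-to-end scaling law or from the tangent-angle
    correlation. A synthetic worm-like-chain fibril-image generator
    provides ground truth so every stage can be validated by parameter
    recovery, and nonparametric group comparisons (Mann-Whitney, one-way
    ANOVA with Bonferroni post hoc tests) compare conditions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    igraph,
    jsonlite,
    minpack.lm,
    png,
    stats,
    tiff,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
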