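Package: arborfract
Title: Fractal Morphometry of 3D Neuron Dendritic Arbors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for quantifying the fractal geometry of three-dimensional
    neuron reconstructions. Reads SWC morphologies, decomposes arbors into
    soma-to-tip branches, and estimates branch fractal dimensions by two
    independent methods: a Richardson coastline (divider) analysis using
    spherical-shell rulers marched along the branch, and a tortuosity
    scaling analysis over all branch sub-paths. Whole-arbor complexity is
    measured by 3D box counting. An angle-multiplier distortion model
    rescales weave and fork angles while preserving segment lengths, and
    connectivity/cost metrics (view-averaged expanded profile area,
    dendrite surface area and volume, convex-hull bounding area and
    volume) support analysis of how arbors balance connectivity against
    material and operating costs. A synthetic morphology generator
    (correlated-random-walk branches, CA1-like basal arbors, H-trees of
    known dimension) makes the whole pipeline testable without
    experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
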