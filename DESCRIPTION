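Package: lifelab
Title: A Game of Life Laboratory for Developmental and Epigenetic Modelling
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: A sparse, topology-aware Conway Game of Life engine with the
    birth/survival rules made explicit, readers and writers for the standard
    RLE and plaintext pattern formats, a classifier for the emergent-form
    taxonomy (still lifes, oscillators with period, spaceships with
    displacement, die-outs), an experiment harness for random-soup free
    evolution, stabilization detection, mover escapes and pattern collisions
    with per-generation census records, a box-counting fractal dimension
    estimator, and a linear stability analyzer for m-morphogen
    reaction-diffusion dynamics on a ring of cells producing the
    stationary/oscillatory by wavelength-class typology.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
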