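Package: phynetdraw
Title: Layout, Optimization and Image Capture of Rooted Phylogenetic Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Algorithms for drawing rooted phylogenetic networks in combining
    and transfer views, as cladograms or phylograms, in linear or circular
    style. Coordinates are assigned on a backbone tree obtained by rerouting
    reticulations below their lowest stable ancestor; child orders are
    optimized to minimize the total reticulate displacement of reticulate
    edges, exhaustively for small nodes and by simulated annealing otherwise.
    Includes an extended-Newick reader/writer supporting transfer-acceptor
    ('##') notation, a random network simulator, SVG and raster renderers,
    and a skeletonization-based pipeline that captures network topology from
    published figures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    EBImage,
    Rcpp,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
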