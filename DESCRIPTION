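Package: dorasim
Title: Grid-Based Overlap Resolution for Individual-Based Models of
    Microbial Growth
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Individual-based simulation of microbial colonies and biofilms
    with a discretized, grid-based algorithm for resolving spatial overlaps
    between circular cells.  Cells are rasterized onto an occupancy grid,
    surplus occupancy is redistributed by an iterative diffusion-like process
    while a four-layer motion tensor records the directional displacements,
    and the accumulated displacements are translated back into per-cell
    movement vectors.  A kd-tree relaxation shover is included as the
    pairwise comparator, together with a minimal individual-based model
    (Monod growth and division, forward-time central-space substrate
    diffusion, colony and biofilm scenarios), overlap and morphology
    metrics, a packing fixture generator, and a scenario runner with a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE, load = "source")
RoxygenNote: 7.3.3
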