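Package: fibrilforge
Title: Atomistic Assembly of Crosslinked Collagen Fibrils
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds atomistic models of crosslinked collagen fibrils from a
    triple-helix template: crystal-symmetry expansion of the unit cell within a
    contact distance, van der Waals clash filtering, Bravais-lattice
    layer-by-layer optimization that adds crosslinkable molecules at fibril
    boundaries, lysine-derived crosslink engineering (type mixing and random
    replacement with lysine), Gly-X-Y-aware sequence threading onto the
    template backbone, fibril assembly to a target length with neutral terminal
    caps, and structural quality metrics (D-band periodicity by 1-D K-means,
    quadrant nearest-neighbor lateral spacing, end connectivity, radial packing
    density). Deterministic synthetic fixture generators make the whole
    pipeline testable without external structure downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
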