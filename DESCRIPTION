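Package: fibercliq
Title: Fast Whole-Brain Tractography Streamline Clustering with
    Orientation-Invariant Distances and Maximal-Clique Merging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Clusters whole-brain diffusion-MRI tractograms of streamline
    fibers resampled to 21 equidistant points. Implements a four-stage
    pipeline: per-position 3D point clustering with Lloyd's k-means under
    random, farthest-first (maximin) k-means++ or retraction-modified
    initialization; grouping of fibers by identical point-cluster membership
    keys; reassignment of small preliminary clusters to their nearest large
    cluster under the minimum direct-flip distance with a per-point pruning
    cascade; and final merging of candidate clusters via maximal-clique
    enumeration (pivoting Bron-Kerbosch with degeneracy ordering) on
    per-group centroid graphs. Ships orientation-invariant fiber metrics,
    Davies-Bouldin quality evaluation, a ground-truth-labelled synthetic
    tractogram generator, TRK/bundles/array file I/O, tidy broom-style
    accessors and ggplot2 visualisation.
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
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    igraph,
    mclust,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
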