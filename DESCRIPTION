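Package: orbipool
Title: Group-Orbit Pooling Models of Simple and Complex Cells
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Models of early visual-cortex representation learning in which
    simple cells acquire weights by unsupervised (Hebbian-family) learning on
    stimuli structured into orbits of a finite orthogonal group, and complex
    cells pool simple cells whose weights form a group orbit. Provides exact
    finite-group constructors (cyclic and dihedral permutation groups, planar
    rotations, polar-grid patch rotations), orbit-structured synthetic
    stimulus generators, threshold-indexed complex-cell signatures that
    realize the empirical-CDF maximal invariant, orthogonality-constrained
    response maximization on the Stiefel manifold, the iterated
    maximal-response wiring rule for complex-cell aggregation, and
    invariance/selectivity metrics including finite-threshold Hoeffding
    coverage analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
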