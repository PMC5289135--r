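Package: conformap
Title: Kernel Maps, Clustering and Consistency Screening for Molecular
    Conformer Databases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for navigating databases of molecular conformers.
    Computes rotation-invariant atomic-environment descriptors (SOAP power
    spectra) and combines them into the regularized-entropy-match (REMatch)
    structure kernel and its induced kernel distance.  Provides sketch-map
    nonlinear two-dimensional embedding with automatic switching-distance
    selection, farthest-point-sampling landmark selection and out-of-sample
    projection; agglomerative clustering under the root-mean-square linkage
    with representative structures and cluster spreads; and automated
    outlier detection and structure/property consistency screening against
    a scalar property such as energy.  Includes a synthetic torsional-basin
    conformer generator so every stage of the pipeline can be exercised and
    tested without external data, plus command-line entry points for the
    full workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    pracma
Suggests:
    testthat (>= 3.0.0),
    ape,
    mclust,
    vegan,
    optparse,
    withr
Config/testthat/edition: 3
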