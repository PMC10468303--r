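Package: rougheye
Title: Automated Quantification of Drosophila Rough-Eye Degeneration and
    Downstream Genetic Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies ommatidial degeneration in Drosophila compound-eye
    micrographs and carries the measurements through the genetics that a
    natural-variation screen needs. Images are preprocessed with a white
    top-hat transform, a region of interest is selected by centroid-distance
    pruning and confidence-ellipse fitting, individual ommatidia are
    segmented as 8-connected pixel clusters, and 16 geometric trait metrics
    (means and dispersions of nearest-neighbour distance, eccentricity,
    area, perimeter and radius statistics) are aggregated per image.
    Downstream tools fit the per-trait mixed model (group and batch fixed,
    line random) by REML to obtain line BLUPs and broad-sense heritability
    with parametric-bootstrap confidence intervals, run a covariate-adjusted
    per-variant linear association scan on homozygous inbred-line genotypes
    with Tracy-Widom selection of principal-component covariates and
    Benjamini-Hochberg correction, map hits to annotated genes, and test a
    candidate gene set for enrichment of disease-associated human orthologs
    by permutation. A synthetic-data module generates degenerating
    ommatidial-lattice images, replicated line phenotypes, structured
    genotype panels and ortholog tables with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    lme4,
    igraph,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    optparse
Config/testthat/edition: 3
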