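Package: satellitome
Title: Comparative Analysis of Satellite DNA Libraries from Short Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for comparative satellitome analysis in groups of related
    species: rotation- and strand-aware comparison of satellite DNA monomers,
    similarity-tier classification into sequence variants, intraspecific
    superfamilies and interspecific groups, Kimura 2-parameter divergence and
    divergence-binned abundance landscapes estimated by masking short reads
    against monomer catalogs, a paired-end Tandem Structure Index, single-copy
    gene normalization with hierarchical clustering of the resulting abundance
    matrix, and decomposition of monomers into duplicated subrepeats and
    higher-order repeat structure. Includes a synthetic-data generator that
    evolves satellite libraries on a species tree under the library hypothesis
    and emits genomes, paired-end reads and full ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    Biostrings,
    BiocGenerics,
    igraph,
    ape,
    jsonlite,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
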