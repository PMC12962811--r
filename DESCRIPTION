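Package: paleoquartet
Title: Quantifying the Phylogenetic Information of Small Ancient-Protein Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing how much phylogenetic information small sets
    of proteins carry about closely related taxa. Provides a multispecies
    coalescent simulator with a simple codon substitution process that
    generates protein panels with known ground-truth gene trees (incomplete
    lineage sorting and archaic introgression included), Shannon-entropy and
    site-rate conservation scoring of protein and DNA alignments, exhaustive
    maximum-likelihood quartet gene-tree inference with bootstrap support and
    polytomy collapsing, an iterative protein-subsampling concatenation
    analysis that tracks topology frequencies and informative-site counts as
    loci accumulate, and overlap/frequency analysis of archaic-introgressed
    haplotype segments against gene intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
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
    yaml
Suggests:
    bio3d,
    optparse,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
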