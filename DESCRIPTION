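Package: duplexmut
Title: Duplex Sequencing Mutation Burden, Spectra, and microDNA Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-consensus analysis of targeted duplex-sequencing variant
    calls from paired somatic and germline (blood and sperm) samples. Implements
    the rare-variant filtering ladder (clonal collapse, exclusion of single
    nucleotide variants over clonal multi-nucleotide variants or near indel
    boundaries, intra-cohort contamination removal, variant allele frequency
    gating), depth-normalized mutation-frequency and substitution-subtype
    statistics, trinucleotide (SBS96) spectra with likelihood-ratio spectrum
    comparison and cosine similarity to reference signatures, and detection and
    classification of putative extrachromosomal circular DNA (microDNA) versus
    chromosomal tandem duplications from junction-supporting read-pair
    geometry. A synthetic-cohort generator with ground-truth labels makes the
    whole pipeline testable without raw sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    withr,
    stats,
    utils,
    Biostrings,
    BiocGenerics,
    rtracklayer,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
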