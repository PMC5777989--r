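Package: homeoprot
Title: Allele-Specific Proteogenomics for Allopolyploid Crops
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects and quantifies homeolog-specific gene products in
    allopolyploid crops by integrating proteomics with transcriptomics.
    Builds cultivar-specific protein databases from reference coding
    sequences plus RNA-seq variant calls (codon-ambiguous residues written
    as X), calls cultivar-specific peptides carrying single amino acid
    polymorphisms (SAAPs) by cross-database matching with codon-level
    resolution from allele depths, tests homeolog expression bias in
    triploid ABB genotypes against the 2/3 dosage expectation by exact
    binomial testing with Benjamini-Hochberg adjustment, selects
    cultivar-specific peptide ions by sparse PLS-DA combined with
    Kruskal-Wallis testing, and performs Fisher-exact GO enrichment.
    Includes a seeded synthetic allotriploid data generator so the whole
    pipeline is testable without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vcfR,
    yaml
Suggests:
    jsonlite,
    mixOmics,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
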