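Package: simmgeval
Title: Concordance of 16S-Derived Simulated Metagenomes with Shotgun Multiomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Evaluates how faithfully simulated metagenomes predicted from 16S
    rRNA amplicons (PICRUSt2-style output) reproduce the functional repertoire
    of empirically sequenced metagenomes and metatranscriptomes. Provides
    readers for HUMAnN2/PICRUSt2-style tab-delimited KO/EC/pathway abundance
    tables (including taxon-stratified rows), an NSTI-based ASV discard rule,
    a lineage-text prokaryote filter, three-way presence/absence set
    decomposition with Sorensen-Dice percent similarity, curated gene-set
    prevalence statistics (antimicrobial resistance KOs, fiber-degrading
    CAZy enzymes, short-chain fatty acid pathways), Jaccard/PCoA/PERMANOVA
    beta-diversity comparison, genus-level functional contribution analysis,
    and a synthetic-study generator with planted, recoverable structure so the
    whole pipeline is testable without sequence data.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    vegan,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
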