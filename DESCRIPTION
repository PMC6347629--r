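Package: neoivs
Title: Neoantigen Discovery and Memory T-Cell Clonotype Tracking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computational companion to in vitro stimulation (IVS) screens
    for neoantigen-reactive memory T cells. Implements ensemble
    somatic-variant consensus filtering with COSMIC rescue, mutant 25-mer
    neoepitope and indel neo-ORF extraction from transcript cDNA, tandem
    minigene (TMG) assembly with restriction-site-free nucleotide
    back-translation, TCR-beta clonotype tracking across sorted T-cell
    subsets with productive-clonality statistics, and a ground-truthed
    synthetic-data generator so the whole pipeline is testable offline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
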