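Package: taxplorer
Title: Molecular Reference Databases and Taxonomy Exploration from
    Nucleotide Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Retrieves nucleotide-record data and metadata from an NCBI-style
    e-utilities endpoint through a pluggable (and offline-testable) transport,
    standardizes record taxonomy to the six main ranks (phylum, class, order,
    family, genus, species) against a local taxdump-dialect taxonomy store
    with ancestor-name fallback for incompletely ranked taxa, and emits
    molecular reference databases (multi-FASTA, accession-to-taxonomy TSV
    consumable by taxonomy-assignment platforms, gene-frequency tables) plus
    interactive exploration outputs (per-rank scatter series, sunburst
    hierarchies, world-map point arrays) exported as standalone HTML with
    machine-recoverable embedded data. Includes a synthetic-fixture generator
    for taxonomies and record corpora so the whole pipeline runs and is
    testable without network access.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    grDevices,
    graphics,
    stats,
    tools,
    utils
Suggests:
    Biostrings,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
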