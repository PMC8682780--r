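Package: chromacontact
Title: Differential Enrichment and Contact-Region Mapping for Chromatin Proteomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for silica-bead chromatin-enrichment
    proteomics. Reads MaxQuant-style protein-group and peptide tables,
    applies decoy/contaminant filters, assembles SILAC forward/reverse
    log-ratios or label-free intensity matrices, and performs group-wise
    quantile normalization, rule-based missing-value imputation and an
    empirical-Bayes moderated t-test with Benjamini-Hochberg adjustment
    and two-tier significance calls. Maps crosslinked-fraction enriched
    peptides to protein domains and intrinsically disordered regions,
    merges overlapping annotation matches into consensus regions, ranks
    domain types and computes amino-acid composition enrichment.
    Classifies enriched proteins by gene-ontology keywords (known
    DNA/chromatin binders, nuclear, unexpected; RNA-binding proteins),
    computes abundance-weighted category summaries, chromatin-to-proteome
    iBAQ ratio classes, Fisher's-exact dataset comparisons and
    fold-change correlations. Includes a seeded synthetic-data generator
    (proteomes, in-silico tryptic digestion, quantification tables with
    planted ground truth) so every stage is testable without deposited
    mass-spectrometry data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Biostrings,
    limma,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
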