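Package: mirpipe
Title: Plant Small-RNA miRNA Discovery and Degradome Target Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A two-library (e.g. male versus female) plant small-RNA sequencing
    analysis pipeline: adapter trimming and read cleanup, collapsing to unique
    sRNA tags with TPM normalisation, conserved miRNA assignment against a
    miRBase-style mature set, novel miRNA discovery from transcript-mapped reads
    via stem-loop folding with MFE/MFEI criteria and miRNA* annotation,
    count-based differential expression (Fisher's exact and chi-square tests
    with BH adjustment), and degradome (PARE) cleavage-target identification
    with category 0-4 classification. Includes a thermodynamic nearest-neighbor
    RNA secondary-structure folder and a ground-truth synthetic data generator
    so the whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
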