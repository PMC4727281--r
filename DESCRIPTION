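Package: editcoevo
Title: Chloroplast C-to-U RNA Editing Sites and Coevolution of Their PPR
    Specificity Factors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the comparative analysis of C-to-U RNA editing in
    plant chloroplast coding sequences. Predicts editing sites in a query
    CDS by codon restoration against a panel of reference editomes with
    configurable support thresholds, assigns standardized editing-site
    labels (gene + "eU" + CDS position + amino-acid change), maps
    orthologous sites across species into editing-state matrices and
    three-way editome partitions, counts minimum independent losses of
    editing sites and their nuclear PPR specificity factors on a rooted
    cladogram under a loss-only (Dollo) model, reports site-factor
    co-loss concordance, and scores pentatricopeptide-repeat (PPR) arrays
    against their RNA targets under the proposed P/S-repeat recognition
    code for positions 6 and 1'. Synthetic-data generators with known
    ground truth make every stage testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    Biostrings,
    ape,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
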