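Package: tcrcs
Title: Chemical Complementarity Scoring of TCR CDR3 Repertoires Against Candidate Antigens
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Sliding-window chemical complementarity scoring between T-cell
    receptor CDR3 amino-acid sequences and candidate antigen sequences
    (electrostatic and combined electrostatic-hydropathy modes), per-case
    score aggregation and percentile dichotomization, survival association
    via univariate Cox proportional hazards and Kaplan-Meier/log-rank
    analysis (including antigen-expression-stratified reanalysis),
    immune-gene-panel Pearson correlation with Bonferroni control, and
    per-residue epitope mapping of high-scoring alignments. Includes a
    synthetic-data generator producing CDR3 repertoires, right-censored
    survival outcomes and expression matrices with known ground truth, so
    every pipeline stage is testable without controlled-access data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    seqinr,
    stats,
    survival,
    tools,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
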