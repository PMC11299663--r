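#!/usr/bin/env Rscript
# Stage 2: complementarity scoring.
#
# Scores every case's pooled TRA+TRB CDR3s against the full synthetic
# antigen and against its 220-239 sub-peptide, in both electrostatic and
# combo (electrostatic + hydropathy) modes, and splits the cohort at the
# median of the maximal score. One TSV per (antigen, mode) lands under
# results/scores/.

library(tcrcs)

in_dir <- file.path("results", "synthetic_cohort")
if (!dir.exists(in_dir)) stop("run analysis/01_simulate_cohort.R first")
out_dir <- file.path("results", "scores")
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

records <- read_cdr3_table(file.path(in_dir, "cdr3.tsv"))
full <- read_antigen_fasta(file.path(in_dir, "antigen.fasta"))[1, ]
rp <- extract_subpeptide(full, 220, 239)

for (ant in list(full, rp)) {
  for (mode in c("electrostatic", "combo")) {
    sc <- score_cases(records, ant, mode = mode)
    f <- file.path(out_dir, sprintf("%s__%s__scores.tsv", ant$antigen_id, mode))
    write_tsv_with_header(sc, f)
    part <- dichotomize(sc, 50)
    cat(sprintf("%-30s %-13s  max CS median %.2f (range %.2f-%.2f); upper/lower split %d/%d\n",
                ant$antigen_id, mode, stats::median(sc$max_cs),
                min(sc$max_cs), max(sc$max_cs),
                length(part$upper), length(part$lower)))
  }
}
cat("score tables written to", out_dir, "\n")
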