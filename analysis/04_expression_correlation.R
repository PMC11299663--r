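#!/usr/bin/env Rscript
# Stage 4: immune-panel correlation.
#
# Pearson correlation of every panel gene's expression with the per-case
# maximal electrostatic score against the full antigen, Bonferroni
# control at the family size actually tested, the coefficient histogram,
# and a Kaplan-Meier median-split check that the top-correlated gene is
# itself a survival marker. Outputs under results/correlation/.

library(tcrcs)

in_dir <- file.path("results", "synthetic_cohort")
sc_file <- file.path("results", "scores",
                     "synthetic_antigen__electrostatic__scores.tsv")
if (!file.exists(sc_file)) stop("run analysis/02_score_repertoires.R first")
out_dir <- file.path("results", "correlation")
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

scores <- utils::read.delim(sc_file, comment.char = "#",
                            stringsAsFactors = FALSE)
expr <- read_expression_matrix(file.path(in_dir, "expression.tsv"))
clinical <- read_clinical_table(file.path(in_dir, "clinical.tsv"))

tab <- correlate_panel(expr, scores, alpha = 0.05)
write_tsv_with_header(as.data.frame(tab),
                      file.path(out_dir, "panel_correlations.tsv"))
cat(sprintf("tested %d genes; Bonferroni threshold p < %.3g; %d significant\n",
            attr(tab, "m_tests"), attr(tab, "threshold"),
            sum(tab$significant_after_bonferroni)))
cat("top of the table (descending r):\n")
print(utils::head(tab[, c("gene", "pearson_r", "p",
                          "significant_after_bonferroni")], 5),
      row.names = FALSE)

h <- coefficient_histogram(tab, file = file.path(out_dir,
                                                 "coefficient_histogram.pdf"))
write_tsv_with_header(h, file.path(out_dir, "coefficient_histogram.tsv"))

top_gene <- tab$gene[1]
km <- expression_median_split_km(expr, top_gene, clinical)
cat(sprintf("median-split KM on %s: n = %d/%d, log-rank p = %.3g, HR = %.3f\n",
            top_gene, km$n_upper, km$n_lower, km$p, km$hr))
cat("correlation outputs written to", out_dir, "\n")
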