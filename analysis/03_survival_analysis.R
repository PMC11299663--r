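#!/usr/bin/env Rscript
# Stage 3: survival association.
#
# For each (antigen, mode) score table: the univariate Cox fit of overall
# survival on the continuous per-SD score, the Kaplan-Meier / log-rank
# comparison of the upper vs lower median-split groups, and the
# antigen-expression-stratified reanalysis (upper 25% vs lower 75% of the
# first panel gene, standing in for antigen-gene expression). Emits a
# forest table and rendering under results/survival/.

library(tcrcs)

in_dir <- file.path("results", "synthetic_cohort")
sc_dir <- file.path("results", "scores")
if (!dir.exists(sc_dir)) stop("run analysis/02_score_repertoires.R first")
out_dir <- file.path("results", "survival")
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

clinical <- read_clinical_table(file.path(in_dir, "clinical.tsv"))
expr <- read_expression_matrix(file.path(in_dir, "expression.tsv"))
strat_gene <- rownames(expr)[1]
strat_vals <- stats::setNames(as.numeric(expr[strat_gene, ]), colnames(expr))

fits <- list()
for (f in sort(list.files(sc_dir, pattern = "__scores\\.tsv$"))) {
  tag <- sub("__scores\\.tsv$", "", f)
  sc <- utils::read.delim(file.path(sc_dir, f), comment.char = "#",
                          stringsAsFactors = FALSE)
  cox <- cox_univariate(sc, clinical)
  fits[[tag]] <- cox
  km <- km_logrank(dichotomize(sc, 50), clinical)
  cat(sprintf("%s\n  Cox: HR = %.3f (95%% CI %.3f-%.3f), p = %.3g\n",
              tag, cox$hr, cox$ci_low, cox$ci_high, cox$p))
  cat(sprintf("  KM median split: n = %d/%d, log-rank p = %.3g, HR = %.3f\n",
              km$n_upper, km$n_lower, km$p, km$hr))
  strat <- expression_stratified_cox(sc, clinical, strat_vals, 75)
  for (side in c("upper", "lower")) {
    r <- strat[[side]]
    if (isTRUE(r$not_evaluable)) {
      cat(sprintf("  %s %s stratum (n = %d): not evaluable (%s)\n",
                  strat_gene, side, strat[[paste0("n_", side)]], r$reason))
    } else {
      cat(sprintf("  %s %s stratum (n = %d): HR = %.3f, p = %.3g\n",
                  strat_gene, side, r$n, r$hr, r$p))
    }
  }
  write_tsv_with_header(km$curves,
                        file.path(out_dir, paste0(tag, "__km_curves.tsv")))
}

ft <- forest_table(fits)
write_tsv_with_header(ft, file.path(out_dir, "forest_table.tsv"))
plot_forest(ft, file = file.path(out_dir, "forest_plot.pdf"))
cat("forest table and plot written to", out_dir, "\n")
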