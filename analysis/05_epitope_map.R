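#!/usr/bin/env Rscript
# Stage 5: epitope mapping.
#
# Accumulates, over every CDR3 whose sliding-window electrostatic score
# reaches 3.0, a count on each antigen residue inside that CDR3's best
# window, then reports the peak regions. On the synthetic cohort the
# count histogram should peak inside the planted acidic block at
# 220-239. Outputs under results/epitope/.

library(tcrcs)

in_dir <- file.path("results", "synthetic_cohort")
if (!dir.exists(in_dir)) stop("run analysis/01_simulate_cohort.R first")
out_dir <- file.path("results", "epitope")
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

records <- read_cdr3_table(file.path(in_dir, "cdr3.tsv"))
ant <- read_antigen_fasta(file.path(in_dir, "antigen.fasta"))[1, ]
truth <- read_truth(file.path(in_dir, "truth.json"))

for (mode in c("electrostatic", "combo")) {
  em <- build_epitope_map(records, ant, mode = mode, threshold = 3.0)
  write_epitope_map(em, ant$sequence,
                    file.path(out_dir, sprintf("epitope_map__%s.tsv", mode)))
  peaks <- peak_regions(em, 0.5)
  cat(sprintf("%s: %d qualifying CDR3-window pairs; count peak at position %s\n",
              mode, em$n_pairs, ifelse(is.na(em$peak), "none", em$peak)))
  if (nrow(peaks) > 0) {
    cat("  peak regions (>= half of max count): ",
        paste(sprintf("%d-%d", peaks$start, peaks$end), collapse = ", "),
        "\n", sep = "")
  }
  in_block <- !is.na(em$peak) && em$peak >= truth$planted_interval[1] &&
    em$peak <= truth$planted_interval[2]
  cat(sprintf("  peak inside planted block %d-%d: %s\n",
              truth$planted_interval[1], truth$planted_interval[2],
              ifelse(in_block, "yes", "no")))

  grDevices::pdf(file.path(out_dir, sprintf("epitope_map__%s.pdf", mode)),
                 width = 8, height = 3.5)
  graphics::plot(seq_along(em$counts), em$counts, type = "h",
                 xlab = "antigen residue position", ylab = "count",
                 main = sprintf("Epitope map (%s, CS >= %g)", mode,
                                em$threshold))
  graphics::rect(truth$planted_interval[1], 0, truth$planted_interval[2],
                 max(em$counts), border = NA,
                 col = grDevices::adjustcolor("red", 0.15))
  grDevices::dev.off()
}
cat("epitope maps written to", out_dir, "\n")
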