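# tcrcs — chemical complementarity scoring of TCR CDR3 repertoires

`tcrcs` asks whether the T-cell receptors resident in a tumor are
chemically matched to a candidate tumor antigen, and whether that match
predicts outcome. It is built for immuno-oncology analysts who already have
per-case CDR3 amino-acid tables (TRA + TRB), a candidate antigen sequence
(e.g. full-length renalase-1 or its RP220 peptide, residues 220–239),
clinical follow-up, and optionally a gene-expression matrix — and who want
a reproducible, tested version of the whole in-silico chain: score →
survival → correlation → epitope map.

## The score

For a CDR3 `c` placed at offset `o` inside antigen `a`, the electrostatic
complementarity score is

    CS(o) = Σ_i Σ_{j : |j−(i+o)| ≤ 1}  w(|j−(i+o)|) · ( −q(c_i) · q(a_j) )

with direct-pair weight `w(0) = 1`, diagonal weight `w(1) = 0.5`, and
charges D = E = −1, K = R = +1, H = +0.1. Opposite charges directly across
score +1 (attraction = complementarity), like charges −1. "Combo" mode adds
`λ Σ w · h(c_i) · h(a_j)` on a mean-centered, unit-interval Kyte–Doolittle
hydropathy scale (λ = 1). The sliding window shifts the CDR3 one residue at
a time across the antigen and keeps the maximal CS; a case's score is the
maximum over its pooled TRA + TRB CDR3s. Downstream, cases are median-split
for Kaplan–Meier / log-rank analysis, the continuous score enters a
univariate Cox model (HR per SD of score; HR < 1 = higher complementarity,
lower death hazard), panel genes are Pearson-correlated with the scores
under Bonferroni control, and CDR3s with CS ≥ 3.0 vote on the antigen
residues inside their best window to build the epitope map.

## Worked example

Everything below is runnable without any data download — the package ships
a synthetic-data generator whose cohorts carry known ground truth.

```r
library(tcrcs)

alignment_cs("KK", "DD", 0)$cs
#> [1] 3                  # two direct +1 pairs, two diagonal +0.5 pairs

h <- sliding_max_cs("CASSKRKF", "GGDDEDGGGGSGGGG")
h$cs; h$offset
#> [1] 4                  # best window is antigen residues 1-8
#> [1] 0

cfg  <- sim_config(n_cases = 60, seed = 42)   # true log HR -0.3 per SD of CS
reps <- simulate_repertoires(cfg)
ant  <- simulate_antigen(cfg)                 # acidic block planted at 220-239
sc   <- score_cases(reps, ant)
cl   <- simulate_survival(sc, cfg)

cox_univariate(sc, cl)
#> Cox PH (univariate, per SD of score): HR = 0.817, 95% CI (0.591, 1.130),
#>   p = 0.222, n = 60 (39 events)

km_logrank(dichotomize(sc, 50), cl)
#> Kaplan-Meier: upper n = 30, lower n = 30; log-rank chisq = 1.751,
#>   p = 0.186; HR (upper vs lower) = 0.644

em <- build_epitope_map(reps, ant, threshold = 3)
em
#> Epitope map of synthetic_antigen (electrostatic mode, CS >= 3):
#>   500 contributing pairs, peak at position 227
peak_regions(em)
#>   start end
#> 1   220 236
```

The fitted HR sits below 1 (the generative direction of effect), and the
epitope-map peak falls inside the planted 220–239 block. At n = 60 the Cox
CI still crosses 1 — the estimator's calibration at n = 500 is what the
acceptance script measures.

## The analysis workflow

`analysis/` holds numbered drivers that run the complete study on a
simulated cohort and write tables under `results/`:

```sh
Rscript analysis/01_simulate_cohort.R       # inputs + truth.json
Rscript analysis/02_score_repertoires.R     # CS tables, both modes, full antigen + 220-239 peptide
Rscript analysis/03_survival_analysis.R     # Cox, KM, expression-stratified Cox, forest plot
Rscript analysis/04_expression_correlation.R# panel correlations, histogram, top-gene KM
Rscript analysis/05_epitope_map.R           # per-residue count maps + peak regions
```

Real data drops in by replacing the files under `results/synthetic_cohort/`
(CDR3 TSV: `case_id`, `chain`, `cdr3_aa`; clinical TSV: `case_id`,
`os_days`, `os_event`; expression TSV: genes × cases; antigen FASTA), or by
calling `run_full_analysis(run_config(...))` directly.

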