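---
title: "Chemical complementarity scoring of TCR CDR3 repertoires: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chemical complementarity scoring of TCR CDR3 repertoires: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tcrcs)
```

## The question the pipeline answers

Tumor-resident T cells carry receptors whose third complementarity-determining
region (CDR3) dominates antigen contact. If a candidate tumor antigen — here,
a secreted protein such as renalase-1 and its RP220 signaling-module peptide
(residues 220–239) — is actually recognized by the infiltrating repertoire,
then patients whose CDR3s are chemically *complementary* to that antigen's
amino-acid sequence should, on average, mount a better anti-tumor response.
The pipeline operationalizes that idea as four linked analyses:

1. **Scoring** — a sliding-window chemical complementarity score (CS)
   between each CDR3 and the antigen, aggregated to one number per case.
2. **Survival** — association of the per-case score with overall survival
   (univariate Cox; Kaplan–Meier on the median split).
3. **Expression correlation** — Pearson correlation of an immune-signature
   gene panel with the case scores, under Bonferroni control, plus an
   expression-stratified reanalysis of the survival association.
4. **Epitope mapping** — localization of the antigen regions that
   high-scoring CDR3s repeatedly align to.

The package consumes already-extracted CDR3 amino-acid tables (TSV), antigen
FASTA, clinical TSV and an expression TSV. Recovering V(D)J recombination
reads from sequencing files is explicitly out of scope, as are MHC binding
prediction, structural docking and germline annotation.

## The complementarity score

Residues are characterized by two property scales, both configurable and
serializable to two-column TSV:

* **Charge**: D = E = −1, K = R = +1, H = +0.1, all other residues 0.
  Histidine is only weakly basic at physiological pH; the +0.1 default makes
  it a minor contributor rather than a full charge, and `default_charge_table(h_charge = )`
  exposes the choice. There is deliberately no pKa/pH-dependent model.
* **Hydropathy**: the Kyte–Doolittle index rescaled to [0, 1]
  (Uversky normalization, `(KD + 4.5)/9`) and then mean-centered over the 20
  residues. Centering makes the hydropathy term of a random sequence pair
  average zero, mirroring the electrostatic term's null behavior; without it,
  every alignment of typical sequences would carry a positive hydropathy
  offset that grows with length. Both the raw scale and the centering flag
  are exposed.

For a CDR3 $c_{1..m}$ placed at offset $o$ inside an antigen $a_{1..n}$, the
electrostatic score is

$$
\mathrm{CS}(o) \;=\; \sum_{i=1}^{m}\;\sum_{\substack{j \,:\, |j-(i+o)|\le 1}}
w_{|j-(i+o)|}\,\bigl(-\,q(c_i)\,q(a_j)\bigr),
\qquad w_0 = 1,\; w_1 = 0.5 .
$$

Opposite charges directly across contribute +1 (attraction is
complementarity), like charges −1, and diagonally adjacent pairs half of
that; pairs further apart contribute nothing. The weights are this
package's convention — the qualitative rule is that off-diagonal
contributions decrease — and both are settable in `scoring_params()`.
**Combo** mode adds $\lambda \sum w\,h(c_i)h(a_j)$ with $\lambda = 1$ by
default: a like-with-like hydrophobicity reward on the same neighbor
stencil. Whether a hydropathy term should reward similarity or
complementarity is genuinely open; the product form (similarity) is flagged
as a convention and can be neutralized with $\lambda = 0$.

The **sliding window** evaluates CS at every one-residue shift that keeps
the shorter sequence fully inside the longer (no overhangs, so scores are
comparable across offsets) and retains the maximum; ties go to the smallest
offset. When a CDR3 is longer than the antigen — possible against the
20-residue RP220 peptide with CDR3s up to 24 residues — the roles swap and
the reported window is the whole antigen. Scores are *not* length-normalized
by default because the epitope-mapping threshold (CS ≥ 3.0) is an absolute
value; a per-length variant exists behind `scoring_params(normalize = TRUE)`.

Internally coordinates are 0-based half-open; every user-facing table is
1-based inclusive, which is why the 220–239 sub-peptide has length 20
(`extract_subpeptide`).

Per case, `score_cases()` pools TRA and TRB CDR3s and keeps the maximum of
the per-CDR3 sliding maxima. CDR3s with ambiguity codes, unknown chains or
fewer than 5 residues are dropped with a logged warning rather than scored.
`dichotomize()` splits cases at a type-7 sample quantile of the score
(default the median); ties at the cut go to the lower group, a deterministic
rule that the degenerate all-equal input turns into "everything lower" plus
a warning flag.

## Survival model

`cox_univariate()` fits $h(t\mid x) = h_0(t)\,e^{\beta x}$ by partial
likelihood with Efron tie handling; $x$ is the per-case maximal CS, z-scored
by default so the hazard ratio reads *per SD of score* (the raw scale is an
option). Confidence intervals and p-values are Wald on $\log \mathrm{HR}$.
HR < 1 means higher complementarity associates with lower death hazard.
Degenerate inputs fail loudly: all-censored data ("no events"), constant
scores ("zero variance"), or fewer than 10 joined cases. All joins between
scores, clinical and expression tables are strict inner joins on `case_id`
with a logged count of dropped cases.

`km_logrank()` produces product-limit curves, the two-sample log-rank test,
and a between-group HR from a Cox fit on the group indicator (whose
convergence warning is suppressed for perfectly separated toy groups, where
the log-rank statistic remains well defined). `expression_stratified_cox()`
re-runs the Cox fit within the upper 100−p% and lower p% of an expression
variable (default p = 75, i.e. upper quartile vs the rest), flagging a
stratum below 10 cases as not evaluable instead of erroring the whole run.
Whether the "right" Cox covariate is the continuous score or the percentile
group is unresolved upstream; both are available and the continuous score is
the default.

## Panel correlation

`correlate_panel()` computes per-gene Pearson r against the case scores on
raw expression values (a `log2(x+1)` switch exists but is off: no transform
is assumed), with pairwise-complete deletion and per-row n. The Bonferroni
family size *m* is the number of tests actually performed in the run — not
a nominal panel size — and is reported alongside the threshold, because a
printed threshold whose denominator cannot be reconstructed is not a
reproducible quantity. Zero-variance genes yield `NaN` rows, flagged
not-significant, and do not count toward *m*.

## Epitope mapping

`build_epitope_map()` scans each CDR3 along the antigen; if its sliding
maximum reaches the threshold (default CS ≥ 3.0), each antigen residue in
that CDR3's *best* window gains a count of 1. Only the best window
contributes by default, consistent with the retained-maximum scoring rule;
counting all windows at or above threshold is available behind a flag, and
the choice is documented as a convention since either reading is defensible.
The invariant $\sum \text{counts} = \sum \text{qualifying window lengths}$
is exact and tested. `peak_regions()` reports maximal runs of positions at
or above half the maximal count, in 1-based inclusive coordinates.

## What the synthetic cohort emulates

The generator (`sim_config()` + `simulate_*`) is first-class, tested code,
because every estimator in the pipeline is validated against its generative
twin:

* **Repertoires** — per case, 5–15 CDR3s of 8–24 residues; residues drawn
  from a background distribution (uniform by default; a human-proteome-like
  table is optional) except that with per-case probability
  $e_c \sim U(0, 0.3)$ a residue is replaced by K or R. The per-case tilt is
  what makes true case-level complementarity vary; setting
  `charge_enrichment = 0` removes all between-case structure.
* **Antigen** — a 342-residue random protein (the length of renalase-1)
  with a synthetic acidic 20-mer planted at 220–239 (80% D/E), i.e. a block
  complementary to basic CDR3s at the RP220 coordinates. The block is a
  constructed stand-in, not the real protein sequence.
* **Survival** — exponential event times with rate
  $h_0 e^{\beta z}$, $z$ the z-scored case score, $\beta = -0.3$ per SD,
  $h_0 = 10^{-3}/\mathrm{day}$ (median survival near two years);
  independent uniform censoring on $[0, \tau]$ with $\tau$ solved
  numerically so the expected censored fraction hits the 30% target. The
  exponential was chosen over Weibull for this closed-form calibration.
* **Expression** — per gene, $\rho z + \sqrt{1-\rho^2}\,\varepsilon$
  mapped affinely to a nonnegative RSEM-like scale (mean 500, SD 100,
  floored at zero — the floor is unreachable in practice at these sizes),
  so the population correlation with the score is exactly $\rho$
  (default 0.4 across a 51-gene panel).

Every generator reseeds from `seed` plus a fixed per-operation increment,
so outputs are reproducible and independent of call order.
`make_fixture_bundle()` writes the four input files plus a versioned
`truth.json` holding $\beta$, the per-gene $\rho$, and the planted interval.

What the generator does **not** emulate: V(D)J recombination statistics,
clonal abundance, germline-encoded CDR3 motifs, expression count noise
(negative binomial), or correlated gene-gene structure. Passing tests
therefore demonstrate that the estimators recover the parameters of this
generative model — not that any particular real cohort satisfies it.

## Verification strategy and problem sizes

The test suite checks the scoring engine against an independent brute-force
enumerator (explicit loops over offsets and residue pairs, with its own
copies of the property scales) on 1,000 random instances, plus exact
algebraic properties: symmetry for equal-length pairs, the charge-neutral
null, the ±3 sign-flip pair, combo ≡ electrostatic at $\lambda = 0$, and
the exact +$w_0$ effect of an isolated opposite-charge substitution.
Estimation checks run at the sizes where their tolerances are meaningful:
Cox recovery on cohorts of n = 500 over 200 survival replicates (mean
absolute bias below 0.03, CI coverage within [0.91, 0.98], null coverage
≥ 93/100), correlation recovery at n = 400 with 100 genes (≥ 95% of genes
within ±0.1 of the planted 0.4; ≤ 2 Bonferroni false positives across 20
null panels), and planted-epitope recovery over 100 cohorts (count argmax
inside 220–239 in ≥ 95). The end-to-end run is checked to byte-reproduce
all tabular outputs; the configuration hash stamped into output headers
deliberately excludes the output directory so runs into different
directories compare equal. `scripts/acceptance.R` recomputes all of these
quantities from scratch on fresh seeds, at 300 oracle instances and 100
Cox replicates — sizes chosen so the whole script stays a sub-minute
smoke run while the larger-sample versions live in the test suite.

## Known limitations

* The neighbor weights, the hydropathy scale, and the similarity-form
  hydropathy term are documented conventions; other published variants of
  chemical complementarity scoring may weight a wider stencil or score
  partial overhangs, and absolute CS values are not comparable across
  conventions (the CS ≥ 3.0 epitope threshold is tied to this one).
* The survival module is univariate by design: no multivariate adjustment,
  competing risks, interval censoring or proportionality diagnostics.
* Pearson correlation on raw RSEM-like values is sensitive to heavy tails;
  the `log2` option mitigates but the default mirrors the plain-values
  analysis.
* Case-level aggregation by the maximum ignores repertoire size beyond the
  reported `n_cdr3`; deep repertoires get more draws at a high maximum, a
  bias the dichotomization inherits.
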