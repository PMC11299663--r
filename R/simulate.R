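# Human-proteome-like background amino-acid frequencies (UniProt/Swiss-Prot
# averages, renormalized over the 20 standard residues); optional
# alternative to the uniform default.
AA_FREQ_HUMAN <- c(
  A = 0.0702, C = 0.0230, D = 0.0474, E = 0.0710, F = 0.0365,
  G = 0.0657, H = 0.0263, I = 0.0433, K = 0.0573, L = 0.0996,
  M = 0.0213, N = 0.0359, P = 0.0631, Q = 0.0477, R = 0.0564,
  S = 0.0833, T = 0.0536, V = 0.0597, W = 0.0122, Y = 0.0267
)

#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator. The defaults
#' describe a mid-sized tumor cohort: 100 cases carrying 5-15 CDR3s each
#' of 8-24 residues; per-case repertoires tilted toward basic residues by
#' a propensity drawn uniformly on `[0, charge_enrichment]` so that true
#' case-level complementarity varies; exponential survival whose
#' log-hazard is linear in the z-scored case score with 30% of follow-up
#' censored; and an immune-gene expression panel constructed to correlate
#' with the case score at a target Pearson rho. The default antigen is a
#' 342-residue random protein (the length of renalase-1) carrying a
#' synthetic acidic 20-mer block at positions 220-239 — a planted
#' epitope complementary to basic CDR3s at the coordinates of the RP220
#' signaling module.
#'
#' @param n_cases Number of cases. Default 100.
#' @param cdr3_per_case Integer range (min, max) of CDR3s per case.
#'   Default `c(5, 15)`.
#' @param cdr3_length Integer range of CDR3 lengths; minimum 5.
#'   Default `c(8, 24)`.
#' @param charge_enrichment Upper bound of the per-case propensity to
#'   draw K/R residues in place of background residues; 0 removes all
#'   between-case composition differences. Default 0.3.
#' @param cox_beta True log hazard ratio per SD of the case score.
#'   Default -0.3.
#' @param baseline_hazard Exponential baseline hazard per day. Default
#'   0.001 (median survival just under two years at beta = 0).
#' @param censoring_rate Target fraction of censored cases in `[0, 1)`.
#'   Default 0.3.
#' @param expr_rho Target Pearson correlation between each gene and the
#'   z-scored case score; scalar or length-`n_genes` vector, |rho| < 1.
#'   Default 0.4.
#' @param n_genes Panel size. Default 51.
#' @param antigen_length Length of the simulated antigen. Default 342.
#' @param planted_start,planted_length 1-based start and length of the
#'   planted acidic block. Defaults 220 and 20.
#' @param planted_acidity Probability that a planted-block residue is D
#'   or E (split evenly); the remainder is background. Default 0.8.
#' @param background_freq `"uniform"` (default) or `"human"` background
#'   residue frequencies.
#' @param seed Integer RNG seed; every generator output is fully
#'   reproducible from it.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_cases = 100, cdr3_per_case = c(5, 15),
                       cdr3_length = c(8, 24), charge_enrichment = 0.3,
                       cox_beta = -0.3, baseline_hazard = 0.001,
                       censoring_rate = 0.3, expr_rho = 0.4, n_genes = 51,
                       antigen_length = 342, planted_start = 220,
                       planted_length = 20, planted_acidity = 0.8,
                       background_freq = c("uniform", "human"), seed = 1) {
  background_freq <- match.arg(background_freq)
  cfg <- list(n_cases = as.integer(n_cases),
              cdr3_per_case = as.integer(cdr3_per_case),
              cdr3_length = as.integer(cdr3_length),
              charge_enrichment = charge_enrichment, cox_beta = cox_beta,
              baseline_hazard = baseline_hazard,
              censoring_rate = censoring_rate, expr_rho = expr_rho,
              n_genes = as.integer(n_genes),
              antigen_length = as.integer(antigen_length),
              planted_start = as.integer(planted_start),
              planted_length = as.integer(planted_length),
              planted_acidity = planted_acidity,
              background_freq = background_freq, seed = as.integer(seed))
  stopifnot(cfg$n_cases >= 1,
            length(cfg$cdr3_per_case) == 2, cfg$cdr3_per_case[1] >= 1,
            cfg$cdr3_per_case[1] <= cfg$cdr3_per_case[2],
            length(cfg$cdr3_length) == 2, cfg$cdr3_length[1] >= 5,
            cfg$cdr3_length[1] <= cfg$cdr3_length[2],
            cfg$charge_enrichment >= 0, cfg$charge_enrichment < 1,
            cfg$censoring_rate >= 0, cfg$censoring_rate < 1,
            all(abs(cfg$expr_rho) < 1),
            cfg$n_genes >= 1, cfg$baseline_hazard > 0,
            cfg$antigen_length >= cfg$cdr3_length[1],
            cfg$planted_start >= 1, cfg$planted_length >= 0,
            cfg$planted_start + cfg$planted_length - 1 <= cfg$antigen_length,
            cfg$planted_acidity >= 0, cfg$planted_acidity <= 1)
  structure(cfg, class = "sim_config")
}

# Each generator reseeds from the config with a fixed operation-specific
# increment, so outputs do not depend on call order.
sim_seed <- function(cfg, op_offset) {
  set.seed((cfg$seed + op_offset) %% .Machine$integer.max)
}

background_probs <- function(cfg) {
  if (cfg$background_freq == "human") {
    AA_FREQ_HUMAN[AA_STANDARD] / sum(AA_FREQ_HUMAN)
  } else {
    stats::setNames(rep(1 / 20, 20), AA_STANDARD)
  }
}

#' Simulate per-case CDR3 repertoires
#'
#' Draws, per case, a CDR3 count and per-CDR3 lengths uniformly from the
#' configured ranges. Each residue comes from the background frequency
#' with probability `1 - e_c` and from {K, R} (equal odds) with
#' probability `e_c`, where the per-case basic-residue propensity `e_c`
#' is uniform on `[0, charge_enrichment]`. Cases therefore differ in
#' charged-residue composition, which is what makes true case-level
#' complementarity scores vary. TRA/TRB chain labels are assigned at
#' random with equal probability.
#'
#' @param cfg A [sim_config()].
#' @return Data frame with columns `case_id`, `chain`, `cdr3_aa`.
#' @export
simulate_repertoires <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  sim_seed(cfg, 101L)
  bg <- background_probs(cfg)
  case_ids <- sprintf("case_%04d", seq_len(cfg$n_cases))
  enr <- stats::runif(cfg$n_cases, 0, cfg$charge_enrichment)
  n_cdr3 <- sample(cfg$cdr3_per_case[1]:cfg$cdr3_per_case[2], cfg$n_cases,
                   replace = TRUE)
  rows <- lapply(seq_len(cfg$n_cases), function(i) {
    lens <- sample(cfg$cdr3_length[1]:cfg$cdr3_length[2], n_cdr3[i],
                   replace = TRUE)
    seqs <- vapply(lens, function(L) {
      basic <- stats::runif(L) < enr[i]
      res <- character(L)
      res[basic] <- sample(c("K", "R"), sum(basic), replace = TRUE)
      res[!basic] <- sample(AA_STANDARD, sum(!basic), replace = TRUE,
                            prob = bg)
      paste(res, collapse = "")
    }, character(1))
    data.frame(case_id = case_ids[i],
               chain = sample(c("TRA", "TRB"), n_cdr3[i], replace = TRUE),
               cdr3_aa = seqs, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate an antigen with a planted complementary block
#'
#' A random background protein with, optionally, a contiguous acidic
#' (D/E-rich) block planted at the configured coordinates. The block is a
#' synthetic construct: CDR3s enriched in basic residues score highest
#' against it, so the planted interval is the ground-truth epitope for
#' recovery tests. Set `planted_length = 0` for a fully random antigen.
#'
#' @param cfg A [sim_config()].
#' @return List with `antigen_id`, `sequence`, and the 1-based inclusive
#'   `planted_interval` (NULL when no block is planted).
#' @export
simulate_antigen <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  sim_seed(cfg, 202L)
  bg <- background_probs(cfg)
  res <- sample(AA_STANDARD, cfg$antigen_length, replace = TRUE, prob = bg)
  planted <- NULL
  if (cfg$planted_length > 0L) {
    idx <- cfg$planted_start:(cfg$planted_start + cfg$planted_length - 1L)
    acidic <- stats::runif(length(idx)) < cfg$planted_acidity
    res[idx[acidic]] <- sample(c("D", "E"), sum(acidic), replace = TRUE)
    planted <- c(cfg$planted_start, cfg$planted_start + cfg$planted_length - 1L)
  }
  list(antigen_id = "synthetic_antigen", sequence = paste(res, collapse = ""),
       planted_interval = planted)
}

#' Simulate right-censored survival outcomes from case scores
#'
#' The generative twin of the univariate Cox analysis: event times are
#' exponential with rate `baseline_hazard * exp(cox_beta * z)`, `z` the
#' z-scored per-case maximal score, so the true log hazard ratio per SD
#' of score is exactly `cox_beta`. Censoring times are uniform on
#' `[0, tau]` with `tau` calibrated numerically so the expected censored
#' fraction equals `censoring_rate`; `censoring_rate = 0` yields
#' observed events everywhere.
#'
#' @param scores Case score table ([score_cases()]).
#' @param cfg A [sim_config()].
#' @param value_col Score column. Default `"max_cs"`.
#' @return Data frame with columns `case_id`, `time` (days), `event`.
#' @export
simulate_survival <- function(scores, cfg, value_col = "max_cs") {
  stopifnot(inherits(cfg, "sim_config"), nrow(scores) > 0)
  sim_seed(cfg, 303L)
  x <- scores[[value_col]]
  z <- if (stats::sd(x) > 0) as.numeric(scale(x)) else rep(0, length(x))
  rate <- cfg$baseline_hazard * exp(cfg$cox_beta * z)
  t_event <- stats::rexp(length(rate), rate = rate)
  if (cfg$censoring_rate == 0) {
    return(data.frame(case_id = scores$case_id, time = t_event,
                      event = 1L, stringsAsFactors = FALSE))
  }
  # P(censored | rate, tau) for C ~ U(0, tau): E[e^{-rate * C}]
  p_cens <- function(tau) mean((1 - exp(-rate * tau)) / (rate * tau))
  lo <- 1e-6 / cfg$baseline_hazard
  hi <- 1e6 / cfg$baseline_hazard
  tau <- stats::uniroot(function(t) p_cens(t) - cfg$censoring_rate,
                        c(lo, hi), tol = 1e-8)$root
  c_time <- stats::runif(length(rate), 0, tau)
  data.frame(case_id = scores$case_id,
             time = pmin(t_event, c_time),
             event = as.integer(t_event <= c_time),
             stringsAsFactors = FALSE)
}

#' Simulate an expression panel correlated with case scores
#'
#' Per gene `g` with target correlation `rho_g`, draws
#' `rho_g * z + sqrt(1 - rho_g^2) * eps` (`z` the z-scored case score,
#' `eps` iid standard normal) and maps it affinely onto a nonnegative
#' RSEM-like scale (mean 500, SD 100, floored at 0; the floor is
#' essentially never reached at these sizes). The per-gene sample
#' correlation with the scores converges to `rho_g` as the number of
#' cases grows.
#'
#' @param scores Case score table.
#' @param cfg A [sim_config()]; `expr_rho` is recycled across
#'   `n_genes` genes if scalar.
#' @return Numeric matrix, `n_genes` x cases, gene rownames
#'   `GENE_0001 ...`, case-id colnames. The true rho vector is attached
#'   as attribute `true_rho`.
#' @export
simulate_expression <- function(scores, cfg, value_col = "max_cs") {
  stopifnot(inherits(cfg, "sim_config"), nrow(scores) > 0)
  sim_seed(cfg, 404L)
  x <- scores[[value_col]]
  z <- if (stats::sd(x) > 0) as.numeric(scale(x)) else rep(0, length(x))
  rho <- rep_len(cfg$expr_rho, cfg$n_genes)
  n <- length(z)
  m <- matrix(NA_real_, nrow = cfg$n_genes, ncol = n,
              dimnames = list(sprintf("GENE_%04d", seq_len(cfg$n_genes)),
                              scores$case_id))
  for (g in seq_len(cfg$n_genes)) {
    latent <- rho[g] * z + sqrt(1 - rho[g]^2) * stats::rnorm(n)
    m[g, ] <- pmax(0, 500 + 100 * latent)
  }
  attr(m, "true_rho") <- rho
  m
}

#' Write a complete synthetic input bundle
#'
#' Generates an internally consistent input set for the full pipeline —
#' CDR3 table, antigen FASTA, clinical table, expression matrix — plus a
#' ground-truth file recording the generative parameters (true log hazard
#' ratio, per-gene rho, planted epitope interval), for end-to-end tests.
#' Scores used to generate survival and expression are computed with the
#' given mode and default tables/parameters.
#'
#' @param cfg A [sim_config()].
#' @param dir Output directory (created if needed).
#' @param mode Scoring mode used for the generative case scores.
#' @return Named character vector of the five file paths (`cdr3`,
#'   `antigen`, `clinical`, `expression`, `truth`), invisibly.
#' @export
make_fixture_bundle <- function(cfg, dir, mode = "electrostatic") {
  stopifnot(inherits(cfg, "sim_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create output directory: ", dir,
                             call. = FALSE)
  reps <- simulate_repertoires(cfg)
  ant <- simulate_antigen(cfg)
  scores <- score_cases(reps, ant, mode = mode)
  clinical <- simulate_survival(scores, cfg)
  expr <- simulate_expression(scores, cfg)

  paths <- c(cdr3 = file.path(dir, "cdr3.tsv"),
             antigen = file.path(dir, "antigen.fasta"),
             clinical = file.path(dir, "clinical.tsv"),
             expression = file.path(dir, "expression.tsv"),
             truth = file.path(dir, "truth.json"))
  write_cdr3_table(reps, paths["cdr3"])
  write_antigen_fasta(ant, paths["antigen"])
  write_clinical_table(data.frame(case_id = clinical$case_id,
                                  os_days = clinical$time,
                                  os_event = clinical$event),
                       paths["clinical"])
  write_expression_matrix(expr, paths["expression"])
  truth <- list(schema_version = 1L,
                seed = cfg$seed,
                cox_beta = cfg$cox_beta,
                censoring_rate = cfg$censoring_rate,
                expr_rho = rep_len(cfg$expr_rho, cfg$n_genes),
                planted_interval = ant$planted_interval,
                antigen_id = ant$antigen_id,
                mode = mode,
                n_cases = cfg$n_cases)
  jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(paths)
}

#' Read a fixture ground-truth file
#'
#' @param path `truth.json` written by [make_fixture_bundle()]. Errors if
#'   the schema version is not the one this package writes.
#' @return The truth list.
#' @export
read_truth <- function(path) {
  truth <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(truth$schema_version) || truth$schema_version != 1L) {
    stop("unsupported truth.json schema version: ",
         format(truth$schema_version), call. = FALSE)
  }
  truth
}
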