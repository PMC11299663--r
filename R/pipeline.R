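#' Extract a sub-peptide from an antigen
#'
#' Inclusive 1-based slice, the coordinate convention of peptide
#' nomenclature (a peptide spanning residues 220 to 239 has length 20).
#' The returned antigen id is suffixed with the interval.
#'
#' @param antigen Antigen string or list/row with `antigen_id`,
#'   `sequence`.
#' @param start_1based,end_1based_inclusive Interval bounds, 1-based
#'   inclusive, with `1 <= start <= end <= length`.
#' @return List with `antigen_id` and `sequence` of the slice.
#' @examples
#' rp <- extract_subpeptide(strrep("A", 342), 220, 239)
#' nchar(rp$sequence)  # 20
#' @export
extract_subpeptide <- function(antigen, start_1based, end_1based_inclusive) {
  ant <- as_antigen(antigen)
  n <- nchar(ant$sequence)
  s <- as.integer(start_1based)
  e <- as.integer(end_1based_inclusive)
  if (is.na(s) || is.na(e) || s < 1L || e < s || e > n) {
    stop(sprintf("invalid sub-peptide interval [%s, %s] for antigen of length %d",
                 format(start_1based), format(end_1based_inclusive), n),
         call. = FALSE)
  }
  list(antigen_id = sprintf("%s_%d-%d", ant$antigen_id, s, e),
       sequence = substr(ant$sequence, s, e))
}

#' Pipeline run configuration
#'
#' Paths and parameters of one end-to-end run. Antigens may additionally
#' be analyzed as a sub-peptide (e.g. residues 220-239 of a full-length
#' antigen) by giving `subpeptide`.
#'
#' @param cdr3_file CDR3 TSV path.
#' @param antigen_file Antigen FASTA path (every record is analyzed).
#' @param clinical_file Clinical TSV path.
#' @param expression_file Optional expression TSV path; enables the
#'   correlation stage and expression-stratified survival.
#' @param output_dir Output directory.
#' @param modes Scoring modes to run. Default both.
#' @param subpeptide Optional `c(start, end)` 1-based inclusive interval;
#'   each full antigen is also analyzed restricted to this slice.
#' @param score_percentile Percentile for the score dichotomy. Default 50.
#' @param expression_split_percentile Percentile for expression strata.
#'   Default 75 (upper 25% vs lower 75%).
#' @param stratify_gene Gene symbol whose expression defines the strata
#'   (e.g. the antigen's own gene); default the first gene in the matrix.
#' @param alpha Family-wise significance level for the panel correlation.
#' @param epitope_threshold Minimum score for the epitope map. Default 3.
#' @param panel Optional character vector of panel genes; default all.
#' @param params [scoring_params()].
#' @param tables [aa_tables()].
#' @return List of class `run_config`.
#' @export
run_config <- function(cdr3_file, antigen_file, clinical_file,
                       expression_file = NULL, output_dir,
                       modes = c("electrostatic", "combo"),
                       subpeptide = NULL, score_percentile = 50,
                       expression_split_percentile = 75,
                       stratify_gene = NULL, alpha = 0.05,
                       epitope_threshold = 3.0, panel = NULL,
                       params = scoring_params(), tables = aa_tables()) {
  modes <- match.arg(modes, SCORING_MODES, several.ok = TRUE)
  stopifnot(score_percentile > 0, score_percentile < 100,
            expression_split_percentile > 0,
            expression_split_percentile < 100)
  if (!is.null(subpeptide)) {
    stopifnot(length(subpeptide) == 2, subpeptide[1] >= 1,
              subpeptide[1] <= subpeptide[2])
  }
  structure(list(cdr3_file = cdr3_file, antigen_file = antigen_file,
                 clinical_file = clinical_file,
                 expression_file = expression_file, output_dir = output_dir,
                 modes = modes, subpeptide = subpeptide,
                 score_percentile = score_percentile,
                 expression_split_percentile = expression_split_percentile,
                 stratify_gene = stratify_gene, alpha = alpha,
                 epitope_threshold = epitope_threshold, panel = panel,
                 params = params, tables = tables),
            class = "run_config")
}

# Stable hash of the configuration *excluding* the output directory, so
# two runs into different directories produce byte-identical tables.
config_hash <- function(cfg) {
  h <- cfg[setdiff(names(cfg), "output_dir")]
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(h, tmp, auto_unbox = TRUE, digits = NA, force = TRUE,
                       null = "null")
  unname(tools::md5sum(tmp))
}

output_meta <- function(cfg) {
  c(sprintf("tcrcs %s", as.character(utils::packageVersion("tcrcs"))),
    sprintf("config_hash %s", config_hash(cfg)))
}

# Run one stage, rewriting any error so the failing stage and input are
# identifiable.
with_stage <- function(stage, input, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("stage '%s' failed on %s: %s", stage, input,
                 conditionMessage(e)), call. = FALSE)
  })
}

cox_to_list <- function(r) {
  if (isTRUE(r$not_evaluable)) {
    list(not_evaluable = TRUE, n = r$n, reason = r$reason)
  } else {
    r[c("hr", "ci_low", "ci_high", "p", "beta", "se", "n", "n_events",
        "covariate_scaling")]
  }
}

#' Run the full complementarity analysis
#'
#' Orchestrates every stage on one input bundle: per-antigen, per-mode
#' case scoring; score-percentile dichotomization with Kaplan-Meier /
#' log-rank comparison; univariate Cox association of the continuous
#' score; optionally, expression-stratified Cox reanalysis and the
#' panel correlation with its coefficient histogram; and the epitope map
#' with its peak regions. All tabular outputs are TSV with a comment
#' header carrying the package version and a configuration hash; a
#' machine-readable `summary.json` and human-readable `report.txt`
#' aggregate the statistics. Re-running with identical inputs and
#' configuration byte-reproduces every table.
#'
#' @param cfg A [run_config()].
#' @return The summary list, invisibly. Side effect: files under
#'   `cfg$output_dir`, namespaced as `<antigen>__<mode>__*`.
#' @export
run_full_analysis <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  meta <- output_meta(cfg)

  records <- with_stage("read_cdr3", cfg$cdr3_file,
                        read_cdr3_table(cfg$cdr3_file))
  antigens <- with_stage("read_antigen", cfg$antigen_file,
                         read_antigen_fasta(cfg$antigen_file))
  clinical <- with_stage("read_clinical", cfg$clinical_file,
                         read_clinical_table(cfg$clinical_file))
  expr <- NULL
  if (!is.null(cfg$expression_file)) {
    expr <- with_stage("read_expression", cfg$expression_file,
                       read_expression_matrix(cfg$expression_file))
  }

  ant_list <- lapply(seq_len(nrow(antigens)), function(i) {
    list(antigen_id = antigens$antigen_id[i], sequence = antigens$sequence[i])
  })
  if (!is.null(cfg$subpeptide)) {
    subs <- lapply(ant_list, function(a) {
      with_stage("extract_subpeptide", a$antigen_id,
                 extract_subpeptide(a, cfg$subpeptide[1], cfg$subpeptide[2]))
    })
    ant_list <- c(ant_list, subs)
  }

  summary <- list(package_version = as.character(utils::packageVersion("tcrcs")),
                  config_hash = config_hash(cfg), analyses = list())

  for (ant in ant_list) {
    for (mode in cfg$modes) {
      tag <- paste0(ant$antigen_id, "__", mode)
      scores <- with_stage("score", tag,
                           score_cases(records, ant, mode = mode,
                                       tables = cfg$tables,
                                       params = cfg$params))
      write_tsv_with_header(scores,
                            file.path(cfg$output_dir,
                                      paste0(tag, "__scores.tsv")), meta)

      part <- with_stage("dichotomize", tag,
                         dichotomize(scores, cfg$score_percentile))
      km <- with_stage("survival", paste0(tag, " (KM)"),
                       km_logrank(part, clinical))
      write_tsv_with_header(km$curves,
                            file.path(cfg$output_dir,
                                      paste0(tag, "__km_curves.tsv")), meta)
      cox <- with_stage("survival", paste0(tag, " (Cox)"),
                        cox_univariate(scores, clinical))

      res <- list(antigen_id = ant$antigen_id, mode = mode,
                  n_cases = nrow(scores),
                  cox = cox_to_list(cox),
                  km = list(n_upper = km$n_upper, n_lower = km$n_lower,
                            chisq = km$chisq, p = km$p, hr = km$hr))

      if (!is.null(expr)) {
        strat_gene <- if (is.null(cfg$stratify_gene)) rownames(expr)[1] else cfg$stratify_gene
        if (strat_gene %in% rownames(expr)) {
          ev <- stats::setNames(as.numeric(expr[strat_gene, ]),
                                colnames(expr))
          strat <- with_stage("stratified_survival", tag,
                              expression_stratified_cox(
                                scores, clinical, ev,
                                cfg$expression_split_percentile))
          res$stratified <- list(gene = strat_gene, cut = strat$cut,
                                 n_upper = strat$n_upper,
                                 n_lower = strat$n_lower,
                                 upper = cox_to_list(strat$upper),
                                 lower = cox_to_list(strat$lower))
        }
        ct <- with_stage("correlate", tag,
                         correlate_panel(expr, scores, panel = cfg$panel,
                                         alpha = cfg$alpha))
        write_tsv_with_header(as.data.frame(ct),
                              file.path(cfg$output_dir,
                                        paste0(tag, "__correlations.tsv")),
                              meta)
        res$correlation <- list(m_tests = attr(ct, "m_tests"),
                                threshold = attr(ct, "threshold"),
                                n_significant = sum(ct$significant_after_bonferroni))
      }

      emap <- with_stage("epitope_map", tag,
                         build_epitope_map(records, ant, mode = mode,
                                           threshold = cfg$epitope_threshold,
                                           tables = cfg$tables,
                                           params = cfg$params))
      write_epitope_map(emap, ant$sequence,
                        file.path(cfg$output_dir,
                                  paste0(tag, "__epitope_map.tsv")), meta)
      peaks <- peak_regions(emap)
      res$epitope <- list(n_pairs = emap$n_pairs, peak = emap$peak,
                          peak_regions = peaks)

      summary$analyses[[tag]] <- res
    }
  }

  jsonlite::write_json(summary, file.path(cfg$output_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  writeLines(render_report(summary), file.path(cfg$output_dir, "report.txt"))
  invisible(summary)
}

render_report <- function(summary) {
  lines <- c(sprintf("tcrcs %s  (config %s)", summary$package_version,
                     summary$config_hash), "")
  for (tag in names(summary$analyses)) {
    a <- summary$analyses[[tag]]
    lines <- c(lines, sprintf("== %s ==", tag),
               sprintf("cases scored: %d", a$n_cases))
    if (isTRUE(a$cox$not_evaluable)) {
      lines <- c(lines, sprintf("Cox: not evaluable (%s)", a$cox$reason))
    } else {
      lines <- c(lines, sprintf(
        "Cox (%s): HR = %.3f, 95%% CI (%.3f, %.3f), p = %.3g",
        a$cox$covariate_scaling, a$cox$hr, a$cox$ci_low, a$cox$ci_high,
        a$cox$p))
    }
    lines <- c(lines, sprintf(
      "KM upper/lower split: n = %d / %d, log-rank p = %.3g, HR = %.3f",
      a$km$n_upper, a$km$n_lower, a$km$p, a$km$hr))
    if (!is.null(a$correlation)) {
      lines <- c(lines, sprintf(
        "panel correlation: %d tests, Bonferroni threshold %.3g, %d significant",
        a$correlation$m_tests, a$correlation$threshold,
        a$correlation$n_significant))
    }
    lines <- c(lines, sprintf(
      "epitope map: %d qualifying pairs, peak position %s",
      a$epitope$n_pairs,
      ifelse(is.na(a$epitope$peak), "none", a$epitope$peak)), "")
  }
  lines
}
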