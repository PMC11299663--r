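# Shared readers/writers for the plain-text formats the pipeline consumes:
# tab-delimited tables with optional '#' comment headers, and FASTA
# antigens via seqinr.

#' Write a data frame as TSV with comment-line metadata
#'
#' Tab-delimited, no quoting, no row names; optional `#`-prefixed header
#' lines (e.g. package version and config hash) precede the column
#' header. All package readers skip `#` lines.
#'
#' @param df Data frame.
#' @param path Output path.
#' @param meta Optional character vector of metadata lines (written as
#'   `# <line>`).
#' @export
write_tsv_with_header <- function(df, path, meta = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!is.null(meta)) writeLines(paste0("# ", meta), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#",
                    check.names = FALSE)
}

#' Read / write a CDR3 table
#'
#' TSV with header columns `case_id`, `chain` (TRA/TRB), `cdr3_aa`.
#'
#' @param path File path.
#' @return Data frame with the three columns.
#' @export
read_cdr3_table <- function(path) {
  df <- read_tsv(path)
  need <- c("case_id", "chain", "cdr3_aa")
  if (!all(need %in% names(df))) {
    stop("CDR3 TSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  df[, need]
}

#' @rdname read_cdr3_table
#' @param records Data frame with `case_id`, `chain`, `cdr3_aa`.
#' @param meta Optional `#` header lines.
#' @export
write_cdr3_table <- function(records, path, meta = NULL) {
  write_tsv_with_header(records[, c("case_id", "chain", "cdr3_aa")], path, meta)
}

#' Read / write a clinical table
#'
#' TSV with columns `case_id`, `os_days`, `os_event` (1 = death
#' observed, 0 = censored).
#'
#' @param path File path.
#' @return Data frame with columns `case_id`, `time`, `event` (plus the
#'   original `os_*` columns).
#' @export
read_clinical_table <- function(path) {
  df <- read_tsv(path)
  need <- c("case_id", "os_days", "os_event")
  if (!all(need %in% names(df))) {
    stop("clinical TSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  df$time <- df$os_days
  df$event <- as.integer(df$os_event)
  stopifnot(all(df$time >= 0), all(df$event %in% c(0L, 1L)))
  df
}

#' @rdname read_clinical_table
#' @param clinical Data frame with `case_id`, `os_days`, `os_event`.
#' @param meta Optional `#` header lines.
#' @export
write_clinical_table <- function(clinical, path, meta = NULL) {
  write_tsv_with_header(clinical[, c("case_id", "os_days", "os_event")],
                        path, meta)
}

#' Read / write an expression matrix
#'
#' TSV whose first column (`gene`) holds gene symbols and whose remaining
#' columns are case ids; values are nonnegative RSEM-like quantities.
#'
#' @param path File path.
#' @return Numeric matrix, genes x cases.
#' @export
read_expression_matrix <- function(path) {
  df <- read_tsv(path)
  as_expression_matrix(df)
}

#' @rdname read_expression_matrix
#' @param m Numeric matrix with gene rownames and case-id colnames.
#' @param meta Optional `#` header lines.
#' @export
write_expression_matrix <- function(m, path, meta = NULL) {
  df <- data.frame(gene = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv_with_header(df, path, meta)
}

#' Read antigen sequences from FASTA
#'
#' Each record becomes one antigen; sequences are validated against the
#' 20 standard amino acids.
#'
#' @param path FASTA file path.
#' @return Data frame with columns `antigen_id`, `sequence`.
#' @export
read_antigen_fasta <- function(path) {
  recs <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                             forceDNAtolower = FALSE)
  if (length(recs) == 0L) stop("no sequences in FASTA file: ", path,
                               call. = FALSE)
  data.frame(
    antigen_id = vapply(recs, function(r) attr(r, "name"), character(1)),
    sequence = vapply(seq_along(recs), function(i) {
      validate_sequence(as.character(recs[[i]]),
                        paste0("antigen '", attr(recs[[i]], "name"), "'"))
    }, character(1)),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' @rdname read_antigen_fasta
#' @param antigen List or data frame with `antigen_id` and `sequence`
#'   (one or more rows).
#' @export
write_antigen_fasta <- function(antigen, path) {
  if (!is.data.frame(antigen)) {
    antigen <- data.frame(antigen_id = antigen$antigen_id,
                          sequence = antigen$sequence,
                          stringsAsFactors = FALSE)
  }
  seqinr::write.fasta(as.list(antigen$sequence),
                      names = antigen$antigen_id, file.out = path,
                      as.string = TRUE, nbchar = 60)
  invisible(path)
}
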