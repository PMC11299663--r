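#' Per-residue epitope map from high-scoring CDR3 alignments
#'
#' Scans every CDR3 along the antigen; for each CDR3 whose sliding-window
#' maximal complementarity score meets the threshold, a count of 1 is
#' added to every antigen residue inside that CDR3's best-scoring window.
#' The resulting histogram localizes antigen regions repeatedly targeted
#' by high-complementarity CDR3s (candidate epitopes). By default only
#' the single best window of each qualifying CDR3 contributes (matching
#' the retained-maximum scoring rule); set `best_window_only = FALSE` to
#' count every window at or above the threshold. Tie windows resolve to
#' the smallest offset.
#'
#' @param records CDR3 data frame (`case_id`, `chain`, `cdr3_aa`). TRA
#'   and TRB are pooled unless `chain` is given.
#' @param antigen Antigen string or list with `antigen_id`, `sequence`.
#' @param mode `"electrostatic"` (default) or `"combo"`.
#' @param threshold Minimum qualifying score. Default 3.0. Values <= 0
#'   are allowed but warned: the map degenerates to coverage counting.
#' @param tables,params See [alignment_cs()].
#' @param chain Optional restriction to `"TRA"` or `"TRB"`.
#' @param best_window_only Count only each CDR3's best window (default).
#' @return An object of class `epitope_map`: list with `antigen_id`,
#'   `counts` (integer per residue, index 1 = antigen position 1),
#'   `threshold`, `mode`, `n_pairs` (number of contributing CDR3-window
#'   pairs), and `peak` (1-based position of the maximal count; smallest
#'   on ties; `NA` when the map is all zero).
#' @export
build_epitope_map <- function(records, antigen, mode = "electrostatic",
                              threshold = 3.0, tables = aa_tables(),
                              params = scoring_params(), chain = NULL,
                              best_window_only = TRUE) {
  ant <- as_antigen(antigen)
  mode <- match.arg(mode, SCORING_MODES)
  if (threshold <= 0) {
    warning("threshold <= 0 degenerates the epitope map to coverage counting",
            call. = FALSE)
  }
  records <- clean_cdr3_records(records)
  if (!is.null(chain)) {
    chain <- match.arg(toupper(chain), c("TRA", "TRB"))
    records <- records[records$chain == chain, , drop = FALSE]
  }
  n <- nchar(ant$sequence)
  counts <- integer(n)
  n_pairs <- 0L
  for (cdr3 in records$cdr3_aa) {
    if (best_window_only) {
      h <- sliding_max_cs(cdr3, ant$sequence, mode = mode, tables = tables,
                          params = params)
      if (h$cs >= threshold) {
        idx <- (h$window_start + 1L):h$window_end
        counts[idx] <- counts[idx] + 1L
        n_pairs <- n_pairs + 1L
      }
    } else {
      s <- score_setup(cdr3, ant$sequence, mode, tables, params)
      cs_all <- -cross_terms_all(s$qs, s$qa, params$w0, params$w1)
      if (mode == "combo") {
        cs_all <- cs_all +
          params$lambda * cross_terms_all(s$hs, s$ha, params$w0, params$w1)
      }
      if (params$normalize) cs_all <- cs_all / s$cdr3_len
      for (o in which(cs_all >= threshold) - 1L) {
        idx <- if (s$swapped) seq_len(n) else (o + 1L):(o + s$cdr3_len)
        counts[idx] <- counts[idx] + 1L
        n_pairs <- n_pairs + 1L
      }
    }
  }
  peak <- if (all(counts == 0L)) NA_integer_ else which.max(counts)
  structure(list(antigen_id = ant$antigen_id, counts = counts,
                 threshold = threshold, mode = mode, n_pairs = n_pairs,
                 peak = peak),
            class = "epitope_map")
}

#' @export
print.epitope_map <- function(x, ...) {
  cat(sprintf("Epitope map of %s (%s mode, CS >= %g): %d contributing pairs, peak at position %s\n",
              x$antigen_id, x$mode, x$threshold, x$n_pairs,
              ifelse(is.na(x$peak), "none", x$peak)))
  invisible(x)
}

#' Peak regions of an epitope map
#'
#' Maximal runs of antigen positions whose count reaches a fraction of the
#' map's maximum, reported as 1-based inclusive intervals (so a 20-residue
#' peak spanning antigen positions 220-239 prints as 220-239).
#'
#' @param map An `epitope_map`.
#' @param min_fraction_of_max Positions with
#'   `count >= min_fraction_of_max * max(count)` belong to a peak.
#'   Default 0.5.
#' @return Data frame with columns `start`, `end` (1-based inclusive);
#'   zero rows when the map is all zero.
#' @export
peak_regions <- function(map, min_fraction_of_max = 0.5) {
  stopifnot(inherits(map, "epitope_map"))
  counts <- map$counts
  if (length(counts) == 0L) stop("empty epitope map", call. = FALSE)
  empty <- data.frame(start = integer(0), end = integer(0))
  if (all(counts == 0L)) return(empty)
  cut <- min_fraction_of_max * max(counts)
  in_peak <- counts >= cut & counts > 0
  r <- rle(in_peak)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  if (!any(keep)) return(empty)
  data.frame(start = starts[keep], end = ends[keep])
}

#' Write an epitope map as TSV
#'
#' One row per antigen residue: `position_1based`, `residue`, `count`.
#'
#' @param map An `epitope_map`.
#' @param antigen_sequence The antigen string the map was built from.
#' @param path Output path.
#' @param meta Optional character vector of `#` comment header lines.
#' @export
write_epitope_map <- function(map, antigen_sequence, path, meta = NULL) {
  seqc <- strsplit(validate_sequence(antigen_sequence, "antigen"), "")[[1]]
  stopifnot(length(seqc) == length(map$counts))
  df <- data.frame(position_1based = seq_along(map$counts), residue = seqc,
                   count = map$counts)
  write_tsv_with_header(df, path, meta)
}
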