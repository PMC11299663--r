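#' Scoring parameters
#'
#' Tunable constants of the complementarity score. The neighbor weights
#' set how much a residue pair contributes when directly aligned
#' (`w0`) versus diagonally adjacent (`w1`); pairs further than one
#' position apart contribute nothing. `lambda` weights the hydropathy
#' term added in combo mode. `normalize` divides the score by the CDR3
#' length (off by default: the epitope-mapping threshold is an absolute
#' score).
#'
#' @param w0 Weight of directly aligned pairs. Default 1.
#' @param w1 Weight of diagonally adjacent pairs. Default 0.5.
#' @param lambda Weight of the hydropathy term in combo mode. Default 1.
#' @param normalize Divide the score by the CDR3 length. Default `FALSE`.
#' @return A list of class `scoring_params`.
#' @export
scoring_params <- function(w0 = 1, w1 = 0.5, lambda = 1, normalize = FALSE) {
  stopifnot(is.numeric(w0), is.numeric(w1), is.numeric(lambda),
            is.logical(normalize))
  structure(list(w0 = w0, w1 = w1, lambda = lambda, normalize = normalize),
            class = "scoring_params")
}

SCORING_MODES <- c("electrostatic", "combo")

# Lagged inner product: sum_i x[i] * y[i + k] over indices valid in both
# vectors (1-based). Out-of-range positions contribute zero, which is the
# boundary behavior of the +/-1 neighbor sum at the ends of the antigen.
lag_sum <- function(x, y, k) {
  i <- seq_along(x)
  j <- i + k
  ok <- j >= 1L & j <= length(y)
  sum(x[ok] * y[j[ok]])
}

# Neighbor-weighted cross term at one offset: w0 * direct + w1 * diagonals.
cross_term <- function(x, y, offset, w0, w1) {
  w0 * lag_sum(x, y, offset) +
    w1 * (lag_sum(x, y, offset - 1L) + lag_sum(x, y, offset + 1L))
}

# Neighbor-weighted cross terms for every full-containment offset
# 0 .. length(y) - length(x), via the lagged inner products at lags
# -1 .. n_off + 1 (each lag is shared by up to three offsets).
cross_terms_all <- function(x, y, w0, w1) {
  n_off <- length(y) - length(x)
  lags <- (-1L):(n_off + 1L)
  cc <- vapply(lags, function(k) lag_sum(x, y, k), numeric(1))
  # cc[k + 2] holds lag k
  o <- 0:n_off
  w0 * cc[o + 2L] + w1 * (cc[o + 1L] + cc[o + 3L])
}

# Shared front end: canonicalize, encode, fetch property vectors, decide
# whether the roles must swap (shorter sequence slides within the longer).
score_setup <- function(cdr3, antigen, mode, tables, params) {
  mode <- match.arg(mode, SCORING_MODES)
  stopifnot(inherits(params, "scoring_params"))
  cdr3 <- validate_sequence(cdr3, "CDR3")
  antigen <- validate_sequence(antigen, "antigen")
  ic <- aa_encode(cdr3)
  ia <- aa_encode(antigen)
  swapped <- length(ic) > length(ia)
  if (swapped) { tmp <- ic; ic <- ia; ia <- tmp }
  list(mode = mode, swapped = swapped,
       cdr3_len = nchar(cdr3), antigen_len = nchar(antigen),
       qs = as.numeric(tables$charge)[ic],  qa = as.numeric(tables$charge)[ia],
       hs = as.numeric(tables$hydropathy)[ic],
       ha = as.numeric(tables$hydropathy)[ia])
}

# Assemble one alignment_score record. Antigen window is 0-based half-open;
# when roles are swapped the whole antigen is overlapped.
make_alignment_score <- function(cs, offset, setup) {
  if (setup$swapped) {
    win <- c(0L, setup$antigen_len)
  } else {
    win <- c(offset, offset + setup$cdr3_len)
  }
  structure(list(cs = cs, offset = as.integer(offset),
                 window_start = win[1], window_end = win[2],
                 mode = setup$mode, swapped = setup$swapped),
            class = "alignment_score")
}

#' Complementarity score of one CDR3-antigen alignment
#'
#' Scores the juxtaposition of a CDR3 against the antigen window starting
#' at `offset` (0-based). Every CDR3 residue interacts with the antigen
#' residue directly across (weight `w0`) and with the two diagonal
#' neighbors (weight `w1`). In electrostatic mode each interacting pair
#' contributes the negated product of the residue charges, so opposite
#' charges (attraction, i.e. complementarity) score positive and like
#' charges negative. Combo mode adds `lambda` times the same
#' neighbor-weighted sum of hydropathy products, rewarding
#' hydrophobic-with-hydrophobic pairing.
#'
#' @param cdr3 CDR3 amino-acid string.
#' @param antigen Antigen amino-acid string, at least as long as the CDR3.
#' @param offset 0-based shift placing the CDR3 fully inside the antigen.
#' @param mode `"electrostatic"` or `"combo"`.
#' @param tables Property tables from [aa_tables()].
#' @param params Scoring parameters from [scoring_params()].
#' @return An `alignment_score`: list with `cs`, `offset`, and the
#'   overlapped antigen window `[window_start, window_end)` (0-based,
#'   half-open).
#' @examples
#' alignment_cs("K", "D", 0)$cs            # +1: opposite charges across
#' alignment_cs("KK", "DD", 0)$cs          # +3: two direct + two diagonal pairs
#' @export
alignment_cs <- function(cdr3, antigen, offset, mode = "electrostatic",
                         tables = aa_tables(), params = scoring_params()) {
  s <- score_setup(cdr3, antigen, mode, tables, params)
  offset <- as.integer(offset)
  n_off <- length(s$qa) - length(s$qs)
  if (offset < 0L || offset > n_off) {
    stop(sprintf("offset %d out of range [0, %d]", offset, n_off),
         call. = FALSE)
  }
  cs <- -cross_term(s$qs, s$qa, offset, params$w0, params$w1)
  if (s$mode == "combo") {
    cs <- cs + params$lambda * cross_term(s$hs, s$ha, offset, params$w0, params$w1)
  }
  if (params$normalize) cs <- cs / s$cdr3_len
  make_alignment_score(cs, offset, s)
}

#' Maximal complementarity score over all alignments (sliding window)
#'
#' Evaluates the alignment score at every one-residue shift of the CDR3
#' along the antigen and retains the highest-scoring alignment. Only
#' full-containment offsets are scored (no overhangs). If the CDR3 is
#' longer than the antigen the roles swap and the antigen slides within
#' the CDR3; the reported window is then the whole antigen. Ties across
#' offsets are broken toward the smallest offset.
#'
#' @inheritParams alignment_cs
#' @return The maximal `alignment_score`.
#' @export
sliding_max_cs <- function(cdr3, antigen, mode = "electrostatic",
                           tables = aa_tables(), params = scoring_params()) {
  s <- score_setup(cdr3, antigen, mode, tables, params)
  cs_all <- -cross_terms_all(s$qs, s$qa, params$w0, params$w1)
  if (s$mode == "combo") {
    cs_all <- cs_all +
      params$lambda * cross_terms_all(s$hs, s$ha, params$w0, params$w1)
  }
  if (params$normalize) cs_all <- cs_all / s$cdr3_len
  best <- which.max(cs_all)   # first index on ties -> smallest offset
  make_alignment_score(cs_all[best], best - 1L, s)
}

# Validate and clean a CDR3 record table: canonical sequences, known chain,
# minimum length. Non-scoreable rows are dropped with a single warning.
clean_cdr3_records <- function(records, min_len = 5L) {
  need <- c("case_id", "chain", "cdr3_aa")
  if (!all(need %in% names(records))) {
    stop("CDR3 table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  records$cdr3_aa <- toupper(records$cdr3_aa)
  records$chain <- toupper(records$chain)
  bad_chain <- !records$chain %in% c("TRA", "TRB")
  bad_seq <- !is_standard_aa(records$cdr3_aa)
  too_short <- nchar(records$cdr3_aa) < min_len
  drop <- bad_chain | bad_seq | too_short
  if (any(drop)) {
    warning(sprintf(
      "dropped %d of %d CDR3 records (%d bad chain, %d non-standard residues, %d shorter than %d AA)",
      sum(drop), nrow(records), sum(bad_chain), sum(bad_seq & !bad_chain),
      sum(too_short & !bad_seq & !bad_chain), min_len), call. = FALSE)
  }
  records[!drop, , drop = FALSE]
}

#' Per-case maximal complementarity scores against one antigen
#'
#' For every case, pools its TRA and TRB CDR3s, computes each CDR3's
#' sliding-window maximal score against the antigen, and records the
#' case-level maximum. Records with unknown chains, non-standard residues
#' or fewer than 5 residues are dropped with a warning; cases left with no
#' valid CDR3 are excluded.
#'
#' @param records Data frame with columns `case_id`, `chain` (TRA/TRB),
#'   `cdr3_aa`.
#' @param antigen Either an antigen amino-acid string or a list/row with
#'   `antigen_id` and `sequence`.
#' @param mode `"electrostatic"` or `"combo"`.
#' @param tables,params See [alignment_cs()].
#' @param chain Optional: restrict to `"TRA"` or `"TRB"`; default pools
#'   both.
#' @return A data frame (one row per case) with columns `case_id`,
#'   `antigen_id`, `mode`, `max_cs`, `n_cdr3`, `best_cdr3`,
#'   `best_win_start`, `best_win_end` (window 1-based inclusive). Ties
#'   across a case's CDR3s resolve to the lexicographically smallest
#'   CDR3.
#' @export
score_cases <- function(records, antigen, mode = "electrostatic",
                        tables = aa_tables(), params = scoring_params(),
                        chain = NULL) {
  ant <- as_antigen(antigen)
  mode <- match.arg(mode, SCORING_MODES)
  if (nrow(records) == 0L) stop("empty CDR3 record collection", call. = FALSE)
  records <- clean_cdr3_records(records)
  if (!is.null(chain)) {
    chain <- match.arg(toupper(chain), c("TRA", "TRB"))
    records <- records[records$chain == chain, , drop = FALSE]
  }
  if (nrow(records) == 0L) stop("no valid CDR3 records to score", call. = FALSE)

  # Score each distinct CDR3 once; cases share the lookup.
  uniq <- sort(unique(records$cdr3_aa))
  hits <- lapply(uniq, sliding_max_cs, antigen = ant$sequence, mode = mode,
                 tables = tables, params = params)
  cs_by_seq <- vapply(hits, `[[`, numeric(1), "cs")
  names(hits) <- names(cs_by_seq) <- uniq

  cases <- sort(unique(records$case_id))
  rows <- lapply(cases, function(cid) {
    seqs <- records$cdr3_aa[records$case_id == cid]
    cs <- cs_by_seq[unique(seqs)]
    best_seq <- min(names(cs)[cs == max(cs)])  # lexicographic tie-break
    h <- hits[[best_seq]]
    data.frame(case_id = cid, antigen_id = ant$antigen_id, mode = mode,
               max_cs = h$cs, n_cdr3 = length(seqs), best_cdr3 = best_seq,
               best_win_start = h$window_start + 1L,
               best_win_end = h$window_end,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Split cases into upper and lower percentile groups
#'
#' Cases whose score is strictly above the percentile cut (type-7 sample
#' quantile) go to the upper group; ties at the cut go to the lower group,
#' so the split is deterministic. If all scores are identical every case
#' is "lower" and the result is flagged degenerate.
#'
#' @param scores Case score table from [score_cases()], or any data frame
#'   with `case_id` and a score column.
#' @param percentile Cut percentile in (0, 100). Default 50 (median split).
#' @param value_col Name of the score column. Default `"max_cs"`.
#' @return List with `upper` and `lower` character vectors of case ids,
#'   the numeric `cut`, and a `degenerate` flag.
#' @export
dichotomize <- function(scores, percentile = 50, value_col = "max_cs") {
  stopifnot(percentile > 0, percentile < 100)
  if (nrow(scores) < 2L) stop("need at least 2 cases to dichotomize",
                              call. = FALSE)
  x <- scores[[value_col]]
  cut <- as.numeric(stats::quantile(x, percentile / 100, type = 7, names = FALSE))
  upper <- scores$case_id[x > cut]
  lower <- scores$case_id[x <= cut]
  degenerate <- length(unique(x)) == 1L
  if (degenerate) {
    warning("all scores identical; every case assigned to the lower group",
            call. = FALSE)
  }
  list(upper = upper, lower = lower, cut = cut, degenerate = degenerate)
}

# Coerce the accepted antigen representations to list(antigen_id, sequence).
as_antigen <- function(antigen) {
  if (is.character(antigen) && length(antigen) == 1L) {
    return(list(antigen_id = "antigen",
                sequence = validate_sequence(antigen, "antigen")))
  }
  if ((is.list(antigen) || is.data.frame(antigen)) &&
      all(c("antigen_id", "sequence") %in% names(antigen))) {
    return(list(antigen_id = as.character(antigen$antigen_id)[1],
                sequence = validate_sequence(as.character(antigen$sequence)[1],
                                             "antigen")))
  }
  stop("antigen must be a sequence string or have fields antigen_id and sequence",
       call. = FALSE)
}
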