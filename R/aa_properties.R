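#' @keywords internal
"_PACKAGE"

# The 20 standard amino acids, alphabetical by one-letter code.
AA_STANDARD <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Kyte-Doolittle hydropathy index (J Mol Biol 1982, 157:105-132).
KYTE_DOOLITTLE <- c(
  A =  1.8, C =  2.5, D = -3.5, E = -3.5, F =  2.8,
  G = -0.4, H = -3.2, I =  4.5, K = -3.9, L =  3.8,
  M =  1.9, N = -3.5, P = -1.6, Q = -3.5, R = -4.5,
  S = -0.8, T = -0.7, V =  4.2, W = -0.9, Y = -1.3
)

#' Construct an amino-acid property table
#'
#' A property table maps each of the 20 standard amino acids (one-letter
#' codes) to a single unitless numeric value. Property tables carry a name
#' identifying the scale and are the lookup backing all complementarity
#' scoring.
#'
#' @param values Named numeric vector covering exactly the 20 standard
#'   amino acids.
#' @param name Identifier string for the scale.
#' @return An object of class `aa_property_table`: a named numeric vector
#'   in standard residue order with a `name` attribute.
#' @export
aa_property_table <- function(values, name) {
  if (!is.numeric(values) || is.null(names(values))) {
    stop("'values' must be a named numeric vector", call. = FALSE)
  }
  keys <- toupper(names(values))
  if (!setequal(keys, AA_STANDARD) || length(keys) != 20L) {
    stop("property table must cover exactly the 20 standard amino acids",
         call. = FALSE)
  }
  if (any(!is.finite(values))) {
    stop("property values must all be finite", call. = FALSE)
  }
  out <- as.numeric(values)[match(AA_STANDARD, keys)]
  names(out) <- AA_STANDARD
  structure(out, name = as.character(name)[1], class = "aa_property_table")
}

#' Default residue charge table
#'
#' Signed unitless side-chain charges at physiological pH: aspartate and
#' glutamate -1, lysine and arginine +1, histidine a small positive charge
#' (weakly basic), all other residues 0. The histidine value is
#' configurable; there is no pH-dependent (pKa) model.
#'
#' @param h_charge Charge assigned to histidine. Default `0.1`.
#' @return An `aa_property_table` of charges.
#' @examples
#' q <- default_charge_table()
#' q[["K"]]  # +1
#' q[["D"]]  # -1
#' @export
default_charge_table <- function(h_charge = 0.1) {
  v <- stats::setNames(numeric(20L), AA_STANDARD)
  v[c("D", "E")] <- -1
  v[c("K", "R")] <- 1
  v["H"] <- h_charge
  aa_property_table(v, name = "charge_default")
}

#' Default residue hydropathy table
#'
#' The Kyte-Doolittle hydropathy index rescaled to the unit interval
#' (Uversky normalization, `(KD + 4.5) / 9`), then mean-centered over the
#' 20 standard residues so the hydropathy term of a random sequence pair
#' scores near zero, matching the behavior of the electrostatic term.
#'
#' @param center If `TRUE` (default) subtract the 20-residue mean so the
#'   scale averages exactly zero.
#' @return An `aa_property_table` of hydropathy values.
#' @export
default_hydropathy_table <- function(center = TRUE) {
  v <- (KYTE_DOOLITTLE + 4.5) / 9
  if (center) v <- v - mean(v)
  aa_property_table(v, name = if (center) "uversky_kd_centered" else "uversky_kd")
}

#' Bundle the property tables used by the scoring engine
#'
#' @param charge Charge `aa_property_table`.
#' @param hydropathy Hydropathy `aa_property_table`.
#' @return A list with elements `charge` and `hydropathy`.
#' @export
aa_tables <- function(charge = default_charge_table(),
                      hydropathy = default_hydropathy_table()) {
  stopifnot(inherits(charge, "aa_property_table"),
            inherits(hydropathy, "aa_property_table"))
  list(charge = charge, hydropathy = hydropathy)
}

#' Validate and canonicalize an amino-acid sequence
#'
#' Uppercases the input and rejects any character outside the 20 standard
#' one-letter codes (ambiguity codes `X`/`B`/`Z`, stops `*`, gaps), naming
#' the first offending position. Sequences containing non-standard codes
#' are not scoreable and should be dropped upstream.
#'
#' @param seq A single amino-acid string.
#' @param what Label used in error messages (e.g. `"CDR3"`).
#' @return The canonical (uppercase) sequence string.
#' @export
validate_sequence <- function(seq, what = "sequence") {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq)) {
    stop(what, " must be a single character string", call. = FALSE)
  }
  if (nchar(seq) == 0L) {
    stop(what, " is empty", call. = FALSE)
  }
  up <- toupper(seq)
  chars <- strsplit(up, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% AA_STANDARD)
  if (length(bad) > 0L) {
    stop(sprintf("%s contains non-standard residue '%s' at position %d",
                 what, chars[bad[1]], bad[1]), call. = FALSE)
  }
  up
}

# TRUE for sequences made only of the 20 standard codes (after uppercasing);
# vectorized, used to drop unscoreable CDR3s with a warning.
is_standard_aa <- function(seqs) {
  vapply(strsplit(toupper(seqs), "", fixed = TRUE),
         function(ch) length(ch) > 0L && all(ch %in% AA_STANDARD),
         logical(1))
}

# Integer-encode a canonical sequence against AA_STANDARD (1..20).
aa_encode <- function(seq) {
  match(strsplit(seq, "", fixed = TRUE)[[1]], AA_STANDARD)
}

#' Write a property table to a two-column TSV
#'
#' Columns `aa` and `value`, one row per residue, so user-supplied scales
#' round-trip through plain text.
#'
#' @param table An `aa_property_table`.
#' @param path Output file path.
#' @export
write_property_table <- function(table, path) {
  stopifnot(inherits(table, "aa_property_table"))
  df <- data.frame(aa = names(table), value = as.numeric(table))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a property table from a two-column TSV
#'
#' @param path File with columns `aa` and `value` covering the 20 standard
#'   amino acids.
#' @param name Scale identifier for the resulting table; defaults to the
#'   file name.
#' @return An `aa_property_table`.
#' @export
read_property_table <- function(path, name = basename(path)) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  if (!all(c("aa", "value") %in% names(df))) {
    stop("property TSV must have columns 'aa' and 'value'", call. = FALSE)
  }
  aa_property_table(stats::setNames(df$value, df$aa), name = name)
}
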