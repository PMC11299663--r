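#' Correlate an expression panel with case complementarity scores
#'
#' Per gene, the Pearson correlation (two-sided test) between expression
#' and the per-case maximal complementarity score over the shared cases,
#' with pairwise-complete deletion of missing expression values. The
#' family-wise significance flag uses the Bonferroni threshold
#' `alpha / m`, where `m` is the number of tests actually performed in
#' this run (genes with a defined correlation), and `m` is reported so
#' the threshold is transparent.
#'
#' @param expr Numeric matrix, genes x cases (dimnames required), or a
#'   data frame whose first column is the gene symbol.
#' @param scores Case score table from [score_cases()].
#' @param panel Optional character vector of gene symbols to test; genes
#'   absent from `expr` are skipped with a warning. Default: all genes.
#' @param alpha Family-wise significance level. Default 0.05.
#' @param log2_transform Apply `log2(x + 1)` to expression before
#'   correlating. Default `FALSE` (raw values).
#' @param value_col Score column. Default `"max_cs"`.
#' @return Data frame of class `correlation_table`, sorted by descending
#'   `pearson_r`, with columns `gene`, `n`, `pearson_r`, `p`,
#'   `significant_after_bonferroni`; attributes `m_tests`, `alpha`,
#'   `threshold`. Zero-variance genes yield `NaN` r, are flagged not
#'   significant, and do not count toward `m`.
#' @export
correlate_panel <- function(expr, scores, panel = NULL, alpha = 0.05,
                            log2_transform = FALSE, value_col = "max_cs") {
  m <- as_expression_matrix(expr)
  genes <- rownames(m)
  if (!is.null(panel)) {
    missing <- setdiff(panel, genes)
    if (length(missing) > 0L) {
      warning(sprintf("%d panel gene(s) absent from the expression matrix: %s",
                      length(missing),
                      paste(utils::head(missing, 5), collapse = ", ")),
              call. = FALSE)
    }
    genes <- panel[panel %in% genes]
  }
  if (length(genes) == 0L) stop("no panel genes present in the expression matrix",
                                call. = FALSE)
  shared <- intersect(scores$case_id, colnames(m))
  if (length(shared) < 3L) {
    stop("need at least 3 cases shared between scores and expression",
         call. = FALSE)
  }
  x <- scores[[value_col]][match(shared, scores$case_id)]
  vals <- m[genes, shared, drop = FALSE]
  if (log2_transform) vals <- log2(vals + 1)

  rows <- lapply(seq_along(genes), function(i) {
    y <- vals[i, ]
    ok <- is.finite(y) & is.finite(x)
    if (sum(ok) < 3L || stats::sd(y[ok]) == 0 || stats::sd(x[ok]) == 0) {
      return(data.frame(gene = genes[i], n = sum(ok), pearson_r = NaN,
                        p = NaN, stringsAsFactors = FALSE))
    }
    ct <- stats::cor.test(x[ok], y[ok], method = "pearson",
                          alternative = "two.sided")
    data.frame(gene = genes[i], n = sum(ok),
               pearson_r = unname(ct$estimate), p = ct$p.value,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  n_nan <- sum(is.nan(tab$pearson_r))
  if (n_nan > 0L) {
    warning(sprintf("%d gene(s) had zero variance or too few pairs; r set to NaN",
                    n_nan), call. = FALSE)
  }
  m_tests <- sum(!is.nan(tab$p))
  threshold <- alpha / max(m_tests, 1L)
  tab$significant_after_bonferroni <- !is.nan(tab$p) & tab$p < threshold
  tab <- tab[order(-tab$pearson_r), , drop = FALSE]  # NaN sorts last
  rownames(tab) <- NULL
  structure(tab, m_tests = m_tests, alpha = alpha, threshold = threshold,
            class = c("correlation_table", "data.frame"))
}

# Accept a genes-x-cases matrix or a data frame with gene symbols in the
# first column; returns a numeric matrix with gene rownames.
as_expression_matrix <- function(expr) {
  if (is.matrix(expr)) {
    if (is.null(rownames(expr)) || is.null(colnames(expr))) {
      stop("expression matrix needs gene rownames and case colnames",
           call. = FALSE)
    }
    if (anyDuplicated(rownames(expr))) {
      stop("duplicate gene symbols in expression matrix", call. = FALSE)
    }
    return(expr)
  }
  if (is.data.frame(expr)) {
    genes <- as.character(expr[[1]])
    if (anyDuplicated(genes)) stop("duplicate gene symbols in expression table",
                                   call. = FALSE)
    m <- as.matrix(expr[, -1, drop = FALSE])
    storage.mode(m) <- "double"
    rownames(m) <- genes
    return(m)
  }
  stop("expr must be a matrix or data frame", call. = FALSE)
}

#' Histogram of Pearson coefficients
#'
#' Binned counts of the per-gene correlation coefficients, by default 20
#' equal-width bins on [-1, 1]. Non-finite coefficients are excluded; the
#' bin counts sum to the number of finite rows.
#'
#' @param table A [correlate_panel()] result.
#' @param bins Number of bins. Default 20.
#' @param file Optional PDF path for a simple rendering.
#' @return Data frame with `bin_low`, `bin_high`, `count`.
#' @export
coefficient_histogram <- function(table, bins = 20, file = NULL) {
  if (nrow(table) == 0L) stop("empty correlation table", call. = FALSE)
  r <- table$pearson_r[is.finite(table$pearson_r)]
  breaks <- seq(-1, 1, length.out = bins + 1)
  h <- graphics::hist(r, breaks = breaks, plot = FALSE)
  out <- data.frame(bin_low = utils::head(breaks, -1),
                    bin_high = breaks[-1], count = h$counts)
  if (!is.null(file)) {
    grDevices::pdf(file, width = 6, height = 4)
    on.exit(grDevices::dev.off())
    graphics::plot(h, main = "Pearson coefficients across the panel",
                   xlab = "Pearson r", col = "grey")
  }
  out
}

#' Kaplan-Meier analysis on an expression median split
#'
#' Splits the cases at the median expression of one gene (ties to the
#' lower group, the same deterministic rule as [dichotomize()]) and runs
#' the Kaplan-Meier / log-rank comparison of the two groups.
#'
#' @param expr Expression matrix or data frame (see [correlate_panel()]).
#' @param gene Gene symbol to split on.
#' @param clinical Clinical data frame (see [cox_univariate()]).
#' @param percentile Split percentile. Default 50.
#' @return A `km_result` (see [km_logrank()]).
#' @export
expression_median_split_km <- function(expr, gene, clinical, percentile = 50) {
  m <- as_expression_matrix(expr)
  if (!gene %in% rownames(m)) {
    stop(sprintf("gene '%s' not present in the expression matrix", gene),
         call. = FALSE)
  }
  df <- data.frame(case_id = colnames(m), max_cs = as.numeric(m[gene, ]),
                   stringsAsFactors = FALSE)
  df <- df[is.finite(df$max_cs), , drop = FALSE]
  part <- dichotomize(df, percentile = percentile)
  km_logrank(part, clinical)
}
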