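#' Fold changes between two libraries
#'
#' Differential expression here follows the convention of normalized-value
#' fold-change tables: `log2fc = log2(value_b / value_a)` with explicit
#' infinities — a feature absent from A but present in B has `log2fc = +Inf`
#' (newly appearing), absent from B but present in A has `-Inf` (completely
#' suppressed), and absent from both is undefined (`NA`). The companion
#' signed fold is `b/a` when `b >= a` and `-(a/b)` when `a > b`, so a
#' halving reads as -2 rather than 0.5. No hypothesis testing is attached:
#' these tables report effect sizes only.
#'
#' @name differential
NULL

#' log2 fold change with infinite-fold conventions
#'
#' @param value_a,value_b non-negative normalized expression values
#'   (vectorized).
#' @return `log2(value_b / value_a)`; `+Inf` when `value_a == 0 < value_b`,
#'   `-Inf` when `value_b == 0 < value_a`, `NA` when both are zero.
#'   Antisymmetric under argument swap.
#' @export
log2_fold_change <- function(value_a, value_b) {
  if (any(value_a < 0, na.rm = TRUE) || any(value_b < 0, na.rm = TRUE)) {
    stop("normalized expression values must be non-negative")
  }
  out <- ifelse(value_a == 0 & value_b == 0, NA_real_,
         ifelse(value_a == 0, Inf,
         ifelse(value_b == 0, -Inf, log2(value_b / value_a))))
  out
}

#' Signed fold with infinite-fold conventions
#'
#' @inheritParams log2_fold_change
#' @return `value_b / value_a` when `value_b >= value_a > 0`;
#'   `-(value_a / value_b)` when `value_a > value_b > 0`; `+Inf` / `-Inf` /
#'   `NA` under the same zero conventions as [log2_fold_change()].
#' @export
signed_fold <- function(value_a, value_b) {
  if (any(value_a < 0, na.rm = TRUE) || any(value_b < 0, na.rm = TRUE)) {
    stop("normalized expression values must be non-negative")
  }
  ifelse(value_a == 0 & value_b == 0, NA_real_,
  ifelse(value_a == 0, Inf,
  ifelse(value_b == 0, -Inf,
  ifelse(value_b >= value_a, value_b / value_a, -(value_a / value_b)))))
}

#' Ranked differential expression table between two libraries
#'
#' @param norm normalized feature-by-library matrix.
#' @param pair character vector `c(library_a, library_b)`; fold changes are
#'   B relative to A.
#' @param log2_threshold keep rows with `|log2fc| >= log2_threshold` or
#'   infinite (default 1).
#' @return data.frame `feature`, `value_a`, `value_b`, `fold`, `log2fc`,
#'   sorted by descending `log2fc` (`+Inf` rows first, `-Inf` last, ties by
#'   feature id). Rows undefined in both libraries are excluded.
#' @export
de_table <- function(norm, pair, log2_threshold = 1) {
  if (length(pair) != 2L || !all(pair %in% colnames(norm))) {
    stop("pair must name two libraries present in the matrix")
  }
  a <- norm[, pair[1]]
  b <- norm[, pair[2]]
  lfc <- log2_fold_change(a, b)
  sf <- signed_fold(a, b)
  keep <- !is.na(lfc) & (is.infinite(lfc) | abs(lfc) >= log2_threshold)
  out <- data.frame(feature = rownames(norm)[keep], value_a = a[keep],
                    value_b = b[keep], fold = sf[keep], log2fc = lfc[keep],
                    stringsAsFactors = FALSE)
  out <- out[order(-out$log2fc, out$feature), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Recompute fold changes from a normalized-value table
#'
#' Direct entry point for reproducing published fold-change tables from
#' their printed normalized-value columns. Accepts a data.frame or a TSV
#' path with feature ids in the first column and the two normalized-value
#' columns named by `cols` (default: second and third column).
#'
#' @param x data.frame or TSV path.
#' @param cols names or indices of the value columns `c(a, b)`.
#' @return the input table with recomputed `fold` and `log2fc` columns.
#' @export
fold_change_table <- function(x, cols = c(2L, 3L)) {
  df <- if (is.character(x) && length(x) == 1L) read_tsv(x) else as.data.frame(x)
  a <- as_num_inf(as.character(df[[cols[1]]]))
  b <- as_num_inf(as.character(df[[cols[2]]]))
  if (anyNA(a) || anyNA(b)) {
    bad <- which(is.na(a) | is.na(b))
    stop("malformed normalized value in row(s): ",
         paste(df[[1]][bad], collapse = ", "))
  }
  df$fold <- signed_fold(a, b)
  df$log2fc <- log2_fold_change(a, b)
  df
}

#' Render fold changes for human-readable reports
#'
#' Formats infinities with the conventional infinity glyphs; machine TSV
#' output keeps the literal strings `inf` / `-inf` instead.
#'
#' @param x numeric vector of fold changes.
#' @param digits decimal places for finite values.
#' @return character vector.
#' @export
format_fold <- function(x, digits = 2L) {
  out <- formatC(x, format = "f", digits = digits)
  out[is.infinite(x) & x > 0] <- "∞"
  out[is.infinite(x) & x < 0] <- "−∞"
  out[is.na(x)] <- "NA"
  out
}
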