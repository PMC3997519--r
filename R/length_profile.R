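#' Read-length distributions and small RNA length classes
#'
#' Length histograms of mappable reads are the quickest view of a small RNA
#' library's composition: miRNA-sized reads populate 18-22 nt, piRNA-sized
#' reads 26-30 nt. Histograms are computed on unique reads weighted by their
#' counts; lengths outside the configured display range are pooled into the
#' edge bins and flagged, but range summaries always use the true lengths.
#'
#' @name length_profile
NULL

#' Length histogram of a read collection
#'
#' @param reads data.frame with columns `sequence`, `count` (unique reads).
#' @param library library label attached to the output.
#' @param range inclusive display range of lengths (default `c(15, 35)`).
#' @return data.frame `library`, `length`, `count`, `fraction`, `pooled`
#'   (`TRUE` on an edge bin that absorbed out-of-range lengths). The true
#'   per-length table is attached as attribute `true_lengths`. Counts sum
#'   to the summed read counts of the input.
#' @export
length_distribution <- function(reads, library = NA_character_,
                                range = c(15L, 35L)) {
  lens <- nchar(reads$sequence)
  true_tab <- if (nrow(reads)) {
    agg <- rowsum(reads$count, lens)
    data.frame(length = as.integer(rownames(agg)), count = agg[, 1])
  } else {
    data.frame(length = integer(), count = numeric())
  }
  bins <- range[1]:range[2]
  pooled_len <- pmin(pmax(true_tab$length, range[1]), range[2])
  count <- vapply(bins, function(b) sum(true_tab$count[pooled_len == b]), 0)
  total <- sum(count)
  out <- data.frame(
    library = library, length = bins, count = count,
    fraction = if (total > 0) count / total else 0,
    pooled = (bins == range[1] & any(true_tab$length < range[1])) |
             (bins == range[2] & any(true_tab$length > range[2])))
  attr(out, "true_lengths") <- true_tab
  out
}

#' miRNA-range and piRNA-range mass of a length histogram
#'
#' @param hist a histogram from [length_distribution()].
#' @param mirna_range,pirna_range inclusive length ranges (defaults 18-22
#'   and 26-30 nt). Overlapping ranges are a configuration error.
#' @return named numeric vector `c(mirna, pirna)`: fraction of total read
#'   counts falling in each range (by true read length, unaffected by edge
#'   pooling).
#' @export
range_summary <- function(hist, mirna_range = c(18L, 22L),
                          pirna_range = c(26L, 30L)) {
  if (mirna_range[1] <= pirna_range[2] && pirna_range[1] <= mirna_range[2]) {
    stop("miRNA and piRNA length ranges overlap")
  }
  tab <- attr(hist, "true_lengths")
  if (is.null(tab)) tab <- data.frame(length = hist$length, count = hist$count)
  total <- sum(tab$count)
  frac <- function(rng) {
    if (total == 0) return(0)
    sum(tab$count[tab$length >= rng[1] & tab$length <= rng[2]]) / total
  }
  c(mirna = frac(mirna_range), pirna = frac(pirna_range))
}
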