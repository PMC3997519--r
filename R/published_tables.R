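#' Published validation tables
#'
#' The package ships the published expression tables of the GSE55210
#' nucleus/cytoplasm small RNA study of Wolbachia-infected (Pop) versus
#' uninfected (Aag2) Aedes aegypti cells: the most differentially expressed
#' miRNAs per compartment (normalized values, signed fold and log2 fold
#' change), the differentially expressed piRNAs per compartment, and the
#' compartment-exclusive miRNA lists. They serve as ground truth for the
#' fold-change and set-algebra machinery: recomputing fold changes from the
#' printed normalized-value pairs must reproduce the printed columns.
#'
#' @name published_tables
NULL

extdata_path <- function(file) {
  system.file("extdata", file, package = "sRNAshuttle", mustWork = TRUE)
}

#' Published fold-change table for one feature class and compartment
#'
#' @param class `"mirna"` or `"pirna"`.
#' @param compartment `"nucleus"` or `"cytoplasm"`.
#' @return data.frame with columns `feature`, `aag2`, `pop` (normalized
#'   expression values), `log2fc` and, for miRNAs, `fold` — the published
#'   values as printed (infinite log2 fold changes as `Inf`/`-Inf`).
#' @export
published_fold_changes <- function(class = c("mirna", "pirna"),
                                   compartment = c("nucleus", "cytoplasm")) {
  class <- match.arg(class)
  compartment <- match.arg(compartment)
  df <- read_tsv(extdata_path(paste0(class, "_fold_changes_", compartment,
                                     ".tsv")))
  df$log2fc <- as_num_inf(as.character(df$log2fc))
  if ("fold" %in% names(df)) df$fold <- as_num_inf(as.character(df$fold))
  df
}

#' Published compartment-exclusive miRNA lists
#'
#' @return data.frame with columns `condition` (`Aag2`/`Pop`),
#'   `compartment_class` (`nucleus_only`/`cytoplasm_only`), `feature`.
#' @export
published_exclusive_mirnas <- function() {
  read_tsv(extdata_path("detection_exclusive_mirnas.tsv"))
}

# Shared-set sizes reported for the two conditions: 57 miRNAs detected in
# both compartments of Aag2 cells, 64 in Pop cells.
PUBLISHED_SHARED_SIZES <- c(Aag2 = 57L, Pop = 64L)

#' Reconstruct a published detection partition
#'
#' Builds the nucleus/cytoplasm detection partition of one condition from
#' the published exclusive-miRNA lists and the published shared-set size.
#' The individual shared miRNAs are not listed in the source tables, so the
#' shared set uses synthetic placeholder ids (`shared_01`, ...); the set
#' sizes, which is what the partition algebra operates on, are exact.
#'
#' @param condition `"Aag2"` or `"Pop"`.
#' @return a [detection_partition()].
#' @export
published_partition <- function(condition = c("Aag2", "Pop")) {
  condition <- match.arg(condition)
  excl <- published_exclusive_mirnas()
  excl <- excl[excl$condition == condition, , drop = FALSE]
  n_only <- excl$feature[excl$compartment_class == "nucleus_only"]
  c_only <- excl$feature[excl$compartment_class == "cytoplasm_only"]
  shared <- sprintf("shared_%02d", seq_len(PUBLISHED_SHARED_SIZES[[condition]]))
  detection_partition(nucleus = c(shared, n_only),
                      cytoplasm = c(shared, c_only),
                      condition = condition)
}
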