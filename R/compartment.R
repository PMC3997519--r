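#' Nucleus/cytoplasm detection partitions and compartment shifts
#'
#' For one condition, the features detected in the nuclear and cytoplasmic
#' libraries are partitioned into nucleus-only, cytoplasm-only and shared
#' sets. Comparing the partitions of two conditions (e.g. uninfected versus
#' Wolbachia-infected) labels each feature with its compartment transition,
#' exposing trafficking events such as a miRNA moving from cytoplasm-only
#' to nucleus-only upon infection.
#'
#' @name compartment
NULL

#' Detected feature set of one library
#'
#' @param counts feature-by-library count matrix (raw counts; detection is
#'   presence/absence on read counts, not normalized values).
#' @param library library (column) id.
#' @param min_count detection threshold, inclusive (default 1 read).
#' @return character vector of detected feature ids.
#' @export
detect_features <- function(counts, library, min_count = 1) {
  if (!library %in% colnames(counts)) stop("unknown library: ", library)
  rn <- rownames(counts)
  if (is.null(rn)) rn <- character(0)
  rn[counts[, library] >= min_count]
}

#' Nucleus/cytoplasm detection partition
#'
#' @param nucleus,cytoplasm character vectors of detected feature ids.
#' @param condition condition label carried through to reports.
#' @return a `detection_partition`: list with `condition`, `nucleus_only`,
#'   `cytoplasm_only`, `shared` (disjoint sets), plus the input sets. The
#'   sizes satisfy `|N| + |C| - |shared| = |union|`.
#' @export
detection_partition <- function(nucleus, cytoplasm, condition = NA_character_) {
  nucleus <- unique(as.character(nucleus))
  cytoplasm <- unique(as.character(cytoplasm))
  structure(list(
    condition = condition,
    nucleus = nucleus,
    cytoplasm = cytoplasm,
    nucleus_only = sort(setdiff(nucleus, cytoplasm)),
    cytoplasm_only = sort(setdiff(cytoplasm, nucleus)),
    shared = sort(intersect(nucleus, cytoplasm))
  ), class = "detection_partition")
}

#' @export
print.detection_partition <- function(x, ...) {
  cat("detection_partition [", x$condition, "]: ",
      length(union(x$nucleus, x$cytoplasm)), " features; nucleus ",
      length(x$nucleus), ", cytoplasm ", length(x$cytoplasm), ", shared ",
      length(x$shared), " (N-only ", length(x$nucleus_only), ", C-only ",
      length(x$cytoplasm_only), ")\n", sep = "")
  invisible(x)
}

partition_class <- function(partition, features) {
  cls <- rep("absent", length(features))
  cls[features %in% partition$shared] <- "shared"
  cls[features %in% partition$nucleus_only] <- "N-only"
  cls[features %in% partition$cytoplasm_only] <- "C-only"
  cls
}

#' Compartment-shift labels between two conditions
#'
#' @param partition_a,partition_b `detection_partition`s of condition A and
#'   condition B.
#' @return data.frame `feature`, `class_a`, `class_b`, `transition` (e.g.
#'   `"C-only -> N-only"`), one row per feature detected in either
#'   condition.
#' @export
compartment_shift <- function(partition_a, partition_b) {
  features <- sort(unique(c(partition_a$nucleus, partition_a$cytoplasm,
                            partition_b$nucleus, partition_b$cytoplasm)))
  class_a <- partition_class(partition_a, features)
  class_b <- partition_class(partition_b, features)
  data.frame(feature = features, class_a = class_a, class_b = class_b,
             transition = paste(class_a, "->", class_b),
             stringsAsFactors = FALSE)
}
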