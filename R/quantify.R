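#' Feature counting and library-size normalization
#'
#' Assigned reads are aggregated into a feature-by-library count matrix.
#' Reads whose best hits tie across several features are split equally
#' (1/k to each of k tied features), so column sums are conserved exactly.
#' Normalization divides each column by a per-library size factor, either
#' the median-of-ratios estimator (default; each library's factor is the
#' median, over features positive in every library, of the ratio of the
#' feature's count to a pseudo-reference, the across-library geometric mean
#' of the depth-scaled count profiles) or simple counts-per-million. The
#' median-of-ratios factors are on the scale of library sizes and are
#' exactly equivariant under per-library count scaling.
#'
#' @name quantification
NULL

#' Build a feature-by-library count matrix from read assignments
#'
#' @param assignments data.frame with columns `library`, `count` and a list
#'   column `feature_ids` (character vector of tied best-hit features for
#'   that read).
#' @param features optional character vector fixing row order (features
#'   never observed get zero rows).
#' @param libraries optional character vector fixing column order.
#' @return numeric matrix, features as rows, libraries as columns. Column
#'   sums equal the summed counts of assigned reads per library.
#' @export
count_features <- function(assignments, features = NULL, libraries = NULL) {
  if (is.null(libraries)) {
    libraries <- sort(unique(as.character(assignments$library)))
  }
  if (is.null(features)) {
    features <- sort(unique(unlist(assignments$feature_ids)))
  }
  counts <- matrix(0, nrow = length(features), ncol = length(libraries),
                   dimnames = list(features, libraries))
  for (i in seq_len(nrow(assignments))) {
    f <- assignments$feature_ids[[i]]
    if (!length(f)) next
    share <- assignments$count[i] / length(f)
    counts[f, as.character(assignments$library[i])] <-
      counts[f, as.character(assignments$library[i])] + share
  }
  counts
}

#' Per-library size factors
#'
#' @param counts feature-by-library count matrix.
#' @param method `"median_of_ratios"` (default) or `"per_million"`.
#' @return named numeric vector of positive size factors, one per library.
#'   Under `median_of_ratios`, when no feature is positive in all libraries
#'   the method falls back to `per_million` with a warning. Under
#'   `per_million` an all-zero library is an error.
#' @export
size_factors <- function(counts, method = c("median_of_ratios", "per_million")) {
  method <- match.arg(method)
  if (ncol(counts) < 1L) stop("need at least one library")
  if (method == "median_of_ratios") {
    pos <- rowSums(counts > 0) == ncol(counts)
    if (!any(pos)) {
      warning("no feature positive in all libraries; ",
              "falling back to per-million size factors", call. = FALSE)
      return(size_factors(counts, "per_million"))
    }
    sub <- counts[pos, , drop = FALSE]
    # pseudo-reference: per-feature geometric mean of the depth-scaled
    # profiles (counts divided by library totals). Using proportions rather
    # than raw counts makes the estimator exactly equivariant: multiplying
    # one library's counts by c multiplies only that library's factor by c
    # and leaves the normalized matrix untouched.
    prop <- sweep(sub, 2, colSums(counts), "/")
    geo <- exp(rowMeans(log(prop)))
    f <- apply(sub / geo, 2, stats::median)
  } else {
    tot <- colSums(counts)
    if (any(tot <= 0)) {
      stop("per-million size factor is zero for library ",
           paste(colnames(counts)[tot <= 0], collapse = ", "))
    }
    f <- tot / 1e6
  }
  stats::setNames(f, colnames(counts))
}

#' Normalize a count matrix by size factors
#'
#' @param counts feature-by-library count matrix.
#' @param factors named positive size factors (default computed by
#'   [size_factors()] with `median_of_ratios`).
#' @return matrix of normalized expression values (`counts / factor`), with
#'   the factors attached as attribute `size_factors`.
#' @export
normalize_counts <- function(counts, factors = size_factors(counts)) {
  if (any(!is.finite(factors)) || any(factors <= 0)) {
    stop("size factors must be positive and finite")
  }
  factors <- factors[colnames(counts)]
  norm <- sweep(counts, 2, factors, "/")
  attr(norm, "size_factors") <- factors
  norm
}

#' Rank features by normalized abundance in one library
#'
#' @param norm normalized matrix.
#' @param library library (column) id.
#' @param top_n number of features to return.
#' @return character vector of feature ids, descending abundance, ties
#'   broken lexicographically.
#' @export
abundance_ranking <- function(norm, library, top_n = 20L) {
  if (top_n < 1L) stop("top_n must be >= 1")
  v <- norm[, library]
  ord <- order(-v, rownames(norm))
  utils::head(rownames(norm)[ord], top_n)
}
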