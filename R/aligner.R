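#' Seeded, ungapped, mismatch-tolerant short read alignment
#'
#' The pipeline's workhorse aligner follows the classic short-read seed
#' scheme: the first `seed_len` bases of the read must match a reference
#' position exactly, and the full-length ungapped extension may carry at most
#' `max_mismatches` substitutions. Seed lengths mirror standard small RNA
#' practice: 17 for known-miRNA references, 19 for genome-scale collections,
#' 20 for other transcribed libraries (Rfam/Repbase-like, piRNA databases).
#' Ambiguous bases (N) count as mismatches. No indels.
#'
#' @name aligner
NULL

#' Aligner configuration
#'
#' @param seed_len exact-match seed length (first `seed_len` read bases).
#' @param max_mismatches maximum substitutions over the full read.
#' @param strands `"forward"` (sense-only, e.g. reads on their hairpin) or
#'   `"both"` (genome-style collections).
#' @return an `aligner_config` list.
#' @export
aligner_config <- function(seed_len = 17L, max_mismatches = 2L,
                           strands = c("forward", "both")) {
  strands <- match.arg(strands)
  seed_len <- as.integer(seed_len)
  max_mismatches <- as.integer(max_mismatches)
  if (is.na(seed_len) || seed_len < 1L) stop("seed_len must be >= 1")
  if (is.na(max_mismatches) || max_mismatches < 0L) {
    stop("max_mismatches must be >= 0")
  }
  structure(list(seed_len = seed_len, max_mismatches = max_mismatches,
                 strands = strands), class = "aligner_config")
}

#' Build a seed index over a reference collection
#'
#' Hashes every `seed_len`-mer of every reference (and of the reverse
#' complement when `strands = "both"`) to its locations. References shorter
#' than `seed_len` contribute nothing (with a warning).
#'
#' @param refs named character vector of reference sequences.
#' @param seed_len seed k-mer length.
#' @param strands `"forward"` or `"both"`.
#' @return a `seed_index` object.
#' @export
build_index <- function(refs, seed_len, strands = c("forward", "both")) {
  strands <- match.arg(strands)
  seed_len <- as.integer(seed_len)
  if (is.na(seed_len) || seed_len < 1L) stop("seed_len must be >= 1")
  refs <- canonicalize_dna(stats::setNames(as.character(refs), names(refs)))
  env <- new.env(parent = emptyenv(), size = max(16L, 4L * sum(nchar(refs))))
  short <- character()
  add_strand <- function(seqs, strand) {
    for (i in seq_along(seqs)) {
      s <- seqs[[i]]
      n <- nchar(s) - seed_len + 1L
      if (n < 1L) next
      kmers <- substring(s, seq_len(n), seq_len(n) + seed_len - 1L)
      for (p in seq_len(n)) {
        key <- kmers[p]
        loc <- list(ref_id = names(seqs)[i], pos = p, strand = strand)
        env[[key]] <- c(env[[key]], list(loc))
      }
    }
  }
  short <- names(refs)[nchar(refs) < seed_len]
  if (length(short)) {
    warning("reference(s) shorter than seed_len contribute no seeds: ",
            paste(short, collapse = ", "), call. = FALSE)
  }
  add_strand(refs, "+")
  if (strands == "both") {
    rc <- revcomp(refs)
    names(rc) <- names(refs)
    add_strand(rc, "-")
  }
  structure(list(env = env, refs = refs,
                 rc_refs = if (strands == "both") {
                   stats::setNames(revcomp(refs), names(refs))
                 } else NULL,
                 seed_len = seed_len, strands = strands),
            class = "seed_index")
}

#' Align one read against a seed index
#'
#' Returns exactly the hits whose first `seed_len` read bases match the
#' reference exactly and whose full-length ungapped extension has at most
#' `max_mismatches` substitutions. Hits on the minus strand are reported in
#' plus-strand reference coordinates. Hits are sorted by
#' (n_mismatches, ref_id, ref_start, strand).
#'
#' @param read a read sequence.
#' @param index a `seed_index` from [build_index()].
#' @param config an [aligner_config()]; its `seed_len` and `strands` must
#'   match the index.
#' @return data.frame of hits with columns `read`, `ref_id`, `ref_start`
#'   (0-based), `ref_end` (exclusive), `strand`, `n_mismatches`, and a list
#'   column `mismatch_positions` (1-based read-relative offsets). Zero rows
#'   when unaligned; attribute `reason` is `"too_short_for_seed"` when the
#'   read is shorter than the seed.
#' @export
align_read <- function(read, index, config = aligner_config()) {
  if (config$seed_len != index$seed_len) {
    stop("config seed_len (", config$seed_len,
         ") does not match index seed_len (", index$seed_len, ")")
  }
  read <- canonicalize_dna(read)
  L <- nchar(read)
  empty <- data.frame(read = character(), ref_id = character(),
                      ref_start = integer(), ref_end = integer(),
                      strand = character(), n_mismatches = integer(),
                      stringsAsFactors = FALSE)
  empty$mismatch_positions <- list()
  if (L < index$seed_len) {
    attr(empty, "reason") <- "too_short_for_seed"
    return(empty)
  }
  seed <- substr(read, 1L, index$seed_len)
  locs <- index$env[[seed]]
  if (is.null(locs)) return(empty)
  rows <- list()
  for (loc in locs) {
    refseq <- if (loc$strand == "+") index$refs[[loc$ref_id]] else
      index$rc_refs[[loc$ref_id]]
    if (loc$pos + L - 1L > nchar(refseq)) next  # read runs off the reference
    window <- substr(refseq, loc$pos, loc$pos + L - 1L)
    mmpos <- mismatch_positions(read, window)
    if (length(mmpos) > config$max_mismatches) next
    # report in plus-strand coordinates of the original reference
    if (loc$strand == "+") {
      start0 <- loc$pos - 1L
    } else {
      start0 <- nchar(refseq) - (loc$pos - 1L) - L
    }
    rows[[length(rows) + 1L]] <- list(ref_id = loc$ref_id, ref_start = start0,
                                      strand = loc$strand,
                                      n_mismatches = length(mmpos),
                                      mismatch_positions = mmpos)
  }
  if (!length(rows)) return(empty)
  out <- data.frame(
    read = read,
    ref_id = vapply(rows, `[[`, "", "ref_id"),
    ref_start = vapply(rows, `[[`, 0L, "ref_start"),
    stringsAsFactors = FALSE)
  out$ref_end <- out$ref_start + L
  out$strand <- vapply(rows, `[[`, "", "strand")
  out$n_mismatches <- vapply(rows, `[[`, 0L, "n_mismatches")
  out$mismatch_positions <- lapply(rows, `[[`, "mismatch_positions")
  ord <- order(out$n_mismatches, out$ref_id, out$ref_start, out$strand)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Keep the minimal-mismatch subset of hits
#'
#' @param hits a hit data.frame from [align_read()].
#' @return list with `hits` (the subset achieving the minimum
#'   `n_mismatches`) and `multimap` (its size; 0 for empty input).
#' @export
best_hits <- function(hits) {
  if (is.null(hits) || nrow(hits) == 0L) {
    return(list(hits = hits, multimap = 0L))
  }
  m <- min(hits$n_mismatches)
  sub <- hits[hits$n_mismatches == m, , drop = FALSE]
  rownames(sub) <- NULL
  list(hits = sub, multimap = nrow(sub))
}

#' Does any alignment exist for each read?
#'
#' Vectorized presence/absence wrapper around [align_read()], used by the
#' sequential filtering stages where only membership matters.
#'
#' @param reads character vector of read sequences.
#' @param index a `seed_index`.
#' @param config an [aligner_config()].
#' @return logical vector: read has at least one qualifying hit.
#' @export
has_hit <- function(reads, index, config = aligner_config()) {
  if (config$seed_len != index$seed_len) {
    stop("config seed_len does not match index seed_len")
  }
  reads <- canonicalize_dna(reads)
  env <- index$env
  k <- index$seed_len
  maxmm <- config$max_mismatches
  vapply(reads, function(r) {
    L <- nchar(r)
    if (L < k) return(FALSE)
    locs <- env[[substr(r, 1L, k)]]
    if (is.null(locs)) return(FALSE)
    rr <- charToRaw(r)
    for (loc in locs) {
      refseq <- if (loc$strand == "+") index$refs[[loc$ref_id]] else
        index$rc_refs[[loc$ref_id]]
      if (loc$pos + L - 1L > nchar(refseq)) next
      w <- charToRaw(substr(refseq, loc$pos, loc$pos + L - 1L))
      if (sum(rr != w | rr == as.raw(78L)) <= maxmm) return(TRUE)
    }
    FALSE
  }, logical(1), USE.NAMES = FALSE)
}
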