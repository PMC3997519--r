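#' Full-sensitivity hairpin alignment with 3' tail tolerance
#'
#' The known-miRNA assignment stage must see every isomiR a read can carry:
#' internal substitutions anywhere in the mature (including its first bases),
#' non-templated 3' additions that do not match the hairpin, and reads
#' running past the hairpin's 3' terminus. An exact-prefix-seed aligner is
#' blind to all three, so hairpin assignment uses a full-sensitivity scan:
#' a read is placed at every reference offset where its aligned portion has
#' at most `max_mismatches` substitutions, allowing up to `max_tail3`
#' trailing bases (a non-aligned 3' tail and/or bases beyond the hairpin
#' end) to be excluded from the aligned portion. Candidate offsets are
#' generated by pigeonhole seeding (one of `max_mismatches + 1` chunks of
#' the aligned prefix must be exact), which makes the scan exact and fast.
#' Forward strand only: mature reads are sense to their hairpin.
#'
#' @name hairpin_alignment
NULL

#' Precompute the scan structure for a hairpin collection
#'
#' @param hairpins named character vector of hairpin sequences.
#' @return a `hairpin_scan_ref` object.
#' @export
hairpin_scan_ref <- function(hairpins) {
  hairpins <- canonicalize_dna(stats::setNames(as.character(hairpins),
                                               names(hairpins)))
  lens <- nchar(hairpins)
  # concatenation with X separators for fixed-string candidate search
  concat <- paste(hairpins, collapse = "X")
  offsets <- cumsum(c(0L, utils::head(lens + 1L, -1L)))  # 0-based starts
  raws <- lapply(hairpins, charToRaw)
  structure(list(hairpins = hairpins, lens = lens, concat = concat,
                 offsets = offsets, ids = names(hairpins), raws = raws),
            class = "hairpin_scan_ref")
}

# Map 1-based positions in the concatenated string to (hairpin index, pos).
concat_to_ref <- function(scan_ref, pos) {
  idx <- findInterval(pos - 1L, scan_ref$offsets)
  within <- pos - scan_ref$offsets[idx]  # 1-based within hairpin (or separator)
  ok <- within <= scan_ref$lens[idx]
  list(idx = idx[ok], pos = within[ok])
}

#' Align reads to hairpins by exhaustive mismatch-tolerant scan
#'
#' For every read, every qualifying placement `(hairpin, start, tail)` is
#' found, where the aligned portion (the read minus its last `tail` bases,
#' `0 <= tail <= max_tail3`) lies within the hairpin with at most
#' `max_mismatches` substitutions. Each placement is scored
#' `n_mismatches + tail` (total non-matching read bases) and, per placement,
#' the smallest tail achieving the minimal score is kept; [best_hits] logic
#' across placements keeps the minimal-score set.
#'
#' @param reads character vector of read sequences.
#' @param scan_ref a [hairpin_scan_ref()] (or a named character vector of
#'   hairpins, converted on the fly).
#' @param max_mismatches maximum substitutions in the aligned portion
#'   (default 2).
#' @param max_tail3 maximum non-aligned 3' tail length (default 3).
#' @return list of per-read hit data.frames (minimal-score set), each with
#'   columns `ref_id`, `ref_start` (0-based), `aligned_len`, `tail3`,
#'   `n_mismatches`, `score`; zero-row data.frame for unaligned reads.
#' @export
align_hairpins <- function(reads, scan_ref, max_mismatches = 2L,
                           max_tail3 = 3L) {
  if (!inherits(scan_ref, "hairpin_scan_ref")) {
    scan_ref <- hairpin_scan_ref(scan_ref)
  }
  reads <- canonicalize_dna(reads)
  rawN <- as.raw(78L)
  empty <- data.frame(ref_id = character(), ref_start = integer(),
                      aligned_len = integer(), tail3 = integer(),
                      n_mismatches = integer(), score = integer(),
                      stringsAsFactors = FALSE)
  lapply(reads, function(r) {
    L <- nchar(r)
    P0 <- L - max_tail3            # minimal aligned prefix
    if (P0 < max_mismatches + 1L) return(empty)
    rr <- charToRaw(r)
    # pigeonhole chunks over the first P0 bases
    n_chunk <- max_mismatches + 1L
    clen <- P0 %/% n_chunk
    if (clen < 1L) return(empty)
    starts <- 1L + (seq_len(n_chunk) - 1L) * clen
    cand_idx <- integer(0); cand_pos <- integer(0)
    for (ci in seq_len(n_chunk)) {
      chunk <- substr(r, starts[ci], starts[ci] + clen - 1L)
      if (grepl("X", chunk, fixed = TRUE)) next
      m <- gregexpr(chunk, scan_ref$concat, fixed = TRUE)[[1]]
      if (m[1] == -1L) next
      hit <- concat_to_ref(scan_ref, as.integer(m))
      # candidate read start position within that hairpin (1-based)
      s <- hit$pos - (starts[ci] - 1L)
      keep <- s >= 1L
      cand_idx <- c(cand_idx, hit$idx[keep])
      cand_pos <- c(cand_pos, s[keep])
    }
    if (!length(cand_idx)) return(empty)
    key <- paste0(cand_idx, ":", cand_pos)
    first <- !duplicated(key)
    cand_idx <- cand_idx[first]; cand_pos <- cand_pos[first]
    rows <- list()
    for (j in seq_along(cand_idx)) {
      hi <- cand_idx[j]; s <- cand_pos[j]
      hlen <- scan_ref$lens[hi]
      ov <- min(L, hlen - s + 1L)    # read bases lying on the hairpin
      if (ov < P0) next              # too much would hang off the 3' end
      rh <- scan_ref$raws[[hi]]
      seg <- rh[s:(s + ov - 1L)]
      mmvec <- rr[seq_len(ov)] != seg | rr[seq_len(ov)] == rawN
      cum <- cumsum(mmvec)
      t_min <- L - ov                # bases beyond the hairpin end
      best <- NULL
      for (t in t_min:max_tail3) {
        La <- L - t
        if (La < P0) break
        mm <- cum[La]
        if (mm <= max_mismatches) {
          score <- mm + t
          if (is.null(best) || score < best$score) {
            best <- list(tail = t, mm = mm, score = score, La = La)
          }
        }
      }
      if (!is.null(best)) {
        rows[[length(rows) + 1L]] <- data.frame(
          ref_id = scan_ref$ids[hi], ref_start = s - 1L,
          aligned_len = best$La, tail3 = best$tail,
          n_mismatches = as.integer(best$mm), score = as.integer(best$score),
          stringsAsFactors = FALSE)
      }
    }
    if (!length(rows)) return(empty)
    out <- do.call(rbind, rows)
    out <- out[out$score == min(out$score), , drop = FALSE]
    out <- out[order(out$ref_id, out$ref_start), , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}
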