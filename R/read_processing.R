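#' Read cleaning: 3' adapter trimming, length/quality filters, collapsing
#'
#' Raw small RNA reads (fixed-cycle sequencing, typically 36 nt) consist of
#' the biological insert followed by the 3' sequencing adapter. Cleaning
#' locates the adapter, truncates the read at the match start, discards reads
#' without a recognizable adapter or with inserts shorter than `min_len`
#' (default 16 nt), optionally drops low-quality reads, and collapses the
#' survivors to unique sequences with per-library counts.
#'
#' @name read_processing
NULL

#' Locate the 3' adapter in each read
#'
#' Ungapped scan over all start positions, left to right. At position `p` the
#' overlap is the adapter prefix that fits in the remaining read; a position
#' qualifies when the overlap is at least `min_overlap` and its mismatch
#' fraction is at most `max_mismatch_rate`. The leftmost qualifying position
#' wins.
#'
#' @param seqs character vector of read sequences.
#' @param adapter the 3' adapter sequence.
#' @param min_overlap minimum read/adapter overlap (default 6).
#' @param max_mismatch_rate maximum fraction of mismatching bases in the
#'   overlap (default 0.1).
#' @return integer vector of 1-based adapter start positions, `NA` where no
#'   qualifying match exists. A value of 1 means the whole read is adapter.
#' @export
find_adapter <- function(seqs, adapter, min_overlap = 6L,
                         max_mismatch_rate = 0.1) {
  adapter <- canonicalize_dna(adapter)
  alen <- nchar(adapter)
  if (alen < min_overlap) stop("adapter shorter than min_overlap")
  seqs <- canonicalize_dna(seqs)
  lens <- nchar(seqs)
  best <- rep(NA_integer_, length(seqs))
  if (!length(seqs)) return(best)
  maxp <- max(lens) - min_overlap + 1L
  if (maxp < 1L) return(best)
  abases <- substring(adapter, seq_len(alen), seq_len(alen))
  for (p in seq_len(maxp)) {
    open <- which(is.na(best) & lens - p + 1L >= min_overlap)
    if (!length(open)) break
    ovl <- pmin(alen, lens[open] - p + 1L)
    mm <- integer(length(open))
    max_j <- max(ovl)
    for (j in seq_len(max_j)) {
      active <- ovl >= j
      rb <- substr(seqs[open[active]], p + j - 1L, p + j - 1L)
      mm[active] <- mm[active] + (rb != abases[j] | rb == "N")
    }
    hit <- mm <= max_mismatch_rate * ovl
    best[open[hit]] <- p
  }
  best
}

#' Trim the 3' adapter from reads
#'
#' @inheritParams find_adapter
#' @return data.frame with columns `insert` (the trimmed sequence, `""` when
#'   the adapter starts at position 1) and `status` (`"trimmed"` or
#'   `"no_adapter"`).
#' @export
trim_adapter <- function(seqs, adapter, min_overlap = 6L,
                         max_mismatch_rate = 0.1) {
  pos <- find_adapter(seqs, adapter, min_overlap, max_mismatch_rate)
  insert <- ifelse(is.na(pos), NA_character_,
                   substr(canonicalize_dna(seqs), 1L, pos - 1L))
  data.frame(insert = insert,
             status = ifelse(is.na(pos), "no_adapter", "trimmed"),
             stringsAsFactors = FALSE)
}

#' Minimum-length filter for trimmed inserts
#'
#' Keeps inserts of length `min_len` or more; the boundary is inclusive
#' (a 16 nt insert is kept at the default).
#'
#' @param inserts character vector of adapter-trimmed inserts.
#' @param min_len minimum insert length (default 16).
#' @return logical keep vector.
#' @export
length_filter <- function(inserts, min_len = 16L) {
  !is.na(inserts) & nchar(inserts) >= min_len
}

#' Collapse kept reads to unique sequences with counts
#'
#' @param seqs character vector of kept insert sequences (one element per
#'   read; repeats allowed).
#' @return data.frame with columns `sequence`, `count`, sorted by decreasing
#'   count then sequence. The sum of `count` equals `length(seqs)`.
#' @export
collapse_reads <- function(seqs) {
  if (!length(seqs)) {
    return(data.frame(sequence = character(), count = integer(),
                      stringsAsFactors = FALSE))
  }
  tab <- table(seqs)
  out <- data.frame(sequence = names(tab), count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$sequence), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Clean one small RNA library
#'
#' Full cleaning pass for one library: adapter detection and trimming,
#' optional mean-quality filter (applied when per-base qualities are
#' available, i.e. FASTQ input), inclusive minimum-length filter, and
#' collapsing to unique reads. Reads are processed at the unique-raw-sequence
#' level internally, which leaves all results identical to per-read
#' processing.
#'
#' @param input path to a FASTQ/FASTA file (gzip accepted), or a character
#'   vector of raw read sequences.
#' @param adapter 3' adapter sequence.
#' @param min_len minimum insert length, inclusive (default 16).
#' @param min_overlap,max_mismatch_rate adapter-matching parameters, see
#'   [find_adapter()].
#' @param min_mean_quality discard FASTQ reads whose mean Phred quality is
#'   below this value (default 20); ignored for FASTA or sequence input.
#' @return list with `reads` (unique-read data.frame: `sequence`, `count`)
#'   and `accounting` (one-row data.frame: `raw`, `low_quality`, `no_adapter`,
#'   `too_short`, `kept`). Conservation holds:
#'   `raw = low_quality + no_adapter + too_short + kept`.
#' @export
process_reads <- function(input, adapter, min_len = 16L, min_overlap = 6L,
                          max_mismatch_rate = 0.1, min_mean_quality = 20) {
  n_lowq <- 0L
  if (length(input) == 1L && file.exists(input)) {
    fmt <- sniff_format(input)
    if (fmt == "fastq") {
      sq <- Biostrings::readDNAStringSet(input, format = "fastq",
                                         with.qualities = TRUE)
      seqs <- as.character(sq)
      if (!is.na(min_mean_quality) && min_mean_quality > 0 && length(sq)) {
        qual <- Biostrings::PhredQuality(S4Vectors::mcols(sq)$qualities)
        mq <- vapply(as(qual, "IntegerList"), mean, 0)
        lowq <- mq < min_mean_quality
        n_lowq <- sum(lowq)
        seqs <- seqs[!lowq]
      }
    } else {
      seqs <- as.character(Biostrings::readBStringSet(input, format = "fasta"))
    }
  } else {
    seqs <- as.character(input)
  }
  seqs <- canonicalize_dna(seqs)
  n_raw <- length(seqs) + n_lowq

  # collapse raw reads first; trimming is per-sequence so this is exact
  raw_tab <- collapse_reads(seqs)
  tr <- trim_adapter(raw_tab$sequence, adapter, min_overlap, max_mismatch_rate)
  no_adapter <- tr$status == "no_adapter"
  keep_len <- length_filter(tr$insert, min_len)
  too_short <- !no_adapter & !keep_len
  kept <- !no_adapter & keep_len

  n_no_adapter <- sum(raw_tab$count[no_adapter])
  n_too_short <- sum(raw_tab$count[too_short])
  n_kept <- sum(raw_tab$count[kept])

  reads <- if (any(kept)) {
    agg <- rowsum(raw_tab$count[kept], tr$insert[kept])
    out <- data.frame(sequence = rownames(agg), count = as.integer(agg[, 1]),
                      stringsAsFactors = FALSE)
    out <- out[order(-out$count, out$sequence), , drop = FALSE]
    rownames(out) <- NULL
    out
  } else {
    data.frame(sequence = character(), count = integer(),
               stringsAsFactors = FALSE)
  }
  accounting <- data.frame(raw = n_raw, low_quality = n_lowq,
                           no_adapter = n_no_adapter, too_short = n_too_short,
                           kept = n_kept)
  list(reads = reads, accounting = accounting)
}

sniff_format <- function(path) {
  con <- gzfile(path, "rt")
  on.exit(close(con))
  first <- readLines(con, n = 1L)
  if (!length(first)) return("fasta")
  if (startsWith(first, "@")) "fastq" else "fasta"
}
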