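#' @keywords internal
"_PACKAGE"

# DNA canonicalization: uppercase, U -> T. All internal sequence handling is
# DNA-alphabet; RNA-flavoured output is produced only on request at the I/O edge.
canonicalize_dna <- function(x) {
  chartr("u", "T", chartr("U", "T", toupper(x)))
}

to_rna <- function(x) chartr("T", "U", toupper(x))

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Hamming distance between two equal-length strings (N counts as mismatch
# against everything, including another N).
hamming <- function(a, b) {
  ra <- charToRaw(a)
  rb <- charToRaw(b)
  stopifnot(length(ra) == length(rb))
  n_mm <- sum(ra != rb | ra == charToRaw("N"))
  n_mm
}

# Positions (1-based, read-relative) where two equal-length strings differ.
mismatch_positions <- function(a, b) {
  ra <- charToRaw(a)
  rb <- charToRaw(b)
  which(ra != rb | ra == charToRaw("N"))
}

# Read a FASTA file (optionally gzipped) into a named character vector of
# canonicalized DNA sequences. Duplicate ids are a validation error.
read_fasta_seqs <- function(path) {
  ss <- Biostrings::readBStringSet(path, format = "fasta")
  ids <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(ids)) {
    stop("duplicate sequence id(s) in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- canonicalize_dna(as.character(ss))
  names(seqs) <- ids
  seqs
}

write_fasta_seqs <- function(seqs, path, rna = FALSE) {
  x <- if (rna) to_rna(seqs) else seqs
  ss <- Biostrings::BStringSet(x)
  names(ss) <- names(seqs)
  Biostrings::writeXStringSet(ss, path, format = "fasta")
  invisible(path)
}

# Tab-separated tables with a commented header line, used for all machine
# output. Infinite values serialize as "inf"/"-inf".
write_tsv <- function(df, path) {
  con <- file(path, "w")
  on.exit(close(con))
  fmt <- function(v) {
    if (is.numeric(v)) {
      out <- as.character(v)
      out[is.infinite(v) & v > 0] <- "inf"
      out[is.infinite(v) & v < 0] <- "-inf"
      out
    } else as.character(v)
  }
  writeLines(paste0("#", paste(names(df), collapse = "\t")), con)
  if (nrow(df)) {
    body <- do.call(paste, c(lapply(df, fmt), sep = "\t"))
    writeLines(body, con)
  }
  invisible(path)
}

read_tsv <- function(path) {
  header <- sub("^#", "", readLines(path, n = 1L))
  df <- utils::read.table(path, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE, quote = "",
                          col.names = strsplit(header, "\t", fixed = TRUE)[[1]])
  for (j in seq_along(df)) {
    if (is.character(df[[j]]) && all(grepl("^-?(inf|[0-9.eE+-]+)$", df[[j]])) &&
        !all(is.na(suppressWarnings(as_num_inf(df[[j]]))))) {
      v <- as_num_inf(df[[j]])
      if (!anyNA(v)) df[[j]] <- v
    }
  }
  df
}

as_num_inf <- function(x) {
  v <- suppressWarnings(as.numeric(x))
  v[x == "inf"] <- Inf
  v[x == "-inf"] <- -Inf
  v
}
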