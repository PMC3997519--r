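# Independent brute-force oracles and tiny fixtures. Everything here is
# written against the *definitions*, not against the package internals, so
# oracle tests stay a genuine second route.

# Small simulation config: scales the special-role counts down so tiny
# feature sets stay valid (the package default is the full study design).
small_sim_config <- function(n_features, ...) {
  roles <- c("n_condition_up", "n_condition_down", "n_infected_only",
             "n_uninfected_only", "n_nucleus_only", "n_cytoplasm_only")
  counts <- stats::setNames(rep(0L, length(roles)), roles)
  counts[seq_len(min(n_features, length(roles)))] <- 1L
  args <- list(...)
  for (r in roles) if (is.null(args[[r]])) args[[r]] <- counts[[r]]
  do.call(sim_config, c(list(n_features = n_features), args))
}

rand_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# Toy hairpin fixture used across isomiR/aligner tests.
toy_hairpin <- "GGGGACGTACGTACGTCCCC"
toy_mature_start <- 4L   # 0-based; mature = ACGTACGTACGT, interval [4, 16)
toy_mature_end <- 16L

toy_refs <- function() {
  reference_set(
    hairpins = c(hp1 = toy_hairpin),
    matures = data.frame(mature_id = "mir-1", hairpin_id = "hp1",
                         start = toy_mature_start, end = toy_mature_end,
                         arm = "unknown", stringsAsFactors = FALSE))
}

# Brute-force seeded aligner: exhaustive Hamming comparison at every offset
# and strand, subject to the exact-seed constraint on the first seed_len
# read bases. Mismatch rule: differing characters, or an N anywhere.
oracle_char_mm <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  sum(ca != cb | ca == "N" | cb == "N")
}

oracle_align <- function(read, refs, seed_len, max_mm,
                         strands = c("forward", "both")) {
  strands <- match.arg(strands)
  L <- nchar(read)
  out <- list()
  scan_one <- function(refseq, ref_id, strand) {
    n <- nchar(refseq) - L + 1L
    if (n < 1L) return()
    for (p in seq_len(n)) {
      w <- substr(refseq, p, p + L - 1L)
      if (substr(read, 1L, seed_len) != substr(w, 1L, seed_len)) next
      mm <- oracle_char_mm(read, w)
      if (mm > max_mm) next
      start0 <- if (strand == "+") p - 1L else nchar(refseq) - (p - 1L) - L
      out[[length(out) + 1L]] <<- data.frame(
        ref_id = ref_id, ref_start = start0, strand = strand,
        n_mismatches = mm, stringsAsFactors = FALSE)
    }
  }
  for (i in seq_along(refs)) scan_one(refs[[i]], names(refs)[i], "+")
  if (strands == "both") {
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(refs)))
    for (i in seq_along(refs)) scan_one(rc[i], names(refs)[i], "-")
  }
  if (!length(out)) {
    return(data.frame(ref_id = character(), ref_start = integer(),
                      strand = character(), n_mismatches = integer(),
                      stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, out)
  df <- df[order(df$n_mismatches, df$ref_id, df$ref_start, df$strand), ,
           drop = FALSE]
  rownames(df) <- NULL
  df
}

# Brute-force exhaustive hairpin placement scan mirroring the tail-tolerant
# contract: every (start, tail) with <= max_mm mismatches in the aligned
# portion, scored mismatches + tail, minimal-score set kept.
oracle_scan <- function(read, hairpins, max_mm = 2L, max_tail = 3L) {
  L <- nchar(read)
  P0 <- L - max_tail
  rows <- list()
  for (hid in names(hairpins)) {
    hp <- hairpins[[hid]]
    for (s in seq_len(nchar(hp))) {           # 1-based start
      ov <- min(L, nchar(hp) - s + 1L)
      if (ov < P0) next
      best <- NULL
      for (t in (L - ov):max_tail) {
        La <- L - t
        if (La < P0) next
        mm <- oracle_char_mm(substr(read, 1L, La), substr(hp, s, s + La - 1L))
        if (mm <= max_mm) {
          score <- mm + t
          if (is.null(best) || score < best$score) {
            best <- list(t = t, mm = mm, score = score, La = La)
          }
        }
      }
      if (!is.null(best)) {
        rows[[length(rows) + 1L]] <- data.frame(
          ref_id = hid, ref_start = s - 1L, aligned_len = best$La,
          tail3 = best$t, n_mismatches = best$mm, score = best$score,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(ref_id = character(), ref_start = integer(),
                      aligned_len = integer(), tail3 = integer(),
                      n_mismatches = integer(), score = integer(),
                      stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, rows)
  df <- df[df$score == min(df$score), , drop = FALSE]
  df <- df[order(df$ref_id, df$ref_start), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# Independent isomiR classifier, written directly from the category
# definitions with per-base loops (no shared code with the package).
oracle_isomir <- function(read, hairpin, mstart, mend, s) {
  L <- nchar(read)
  hlen <- nchar(hairpin)
  rs <- s
  re <- s + L
  mm_inside <- 0L
  for (k in seq_len(L)) {
    hp_pos <- s + k                           # 1-based hairpin position
    if (hp_pos > mstart && hp_pos <= mend && hp_pos <= hlen) {
      if (substr(read, k, k) != substr(hairpin, hp_pos, hp_pos)) {
        mm_inside <- mm_inside + 1L
      }
    }
  }
  if (rs == mstart && re == mend) {
    return(if (mm_inside == 0L) "CANONICAL" else "SUBST")
  }
  if (rs > mstart && re == mend) return("TRIM5")
  if (rs < mstart && re == mend) return("EXT5")
  if (rs == mstart && re < mend) return("TRIM3")
  if (rs == mstart && re >= mend + 2L) {
    templated <- TRUE
    for (k in (mend - s + 1L):L) {
      hp_pos <- s + k
      if (hp_pos > hlen ||
          substr(read, k, k) != substr(hairpin, hp_pos, hp_pos)) {
        templated <- FALSE
      }
    }
    return(if (templated) "EXT3" else "ADD3")
  }
  "OTHER"
}
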