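#' Reference model for small RNA analysis
#'
#' A `reference_set` bundles the sequence collections a small RNA pipeline
#' maps against: miRNA hairpin precursors with their mature arms anchored at
#' explicit coordinates, piRNA sequences, contaminant sequences
#' (Rfam/Repbase-like), and protein-coding mRNA sequences used to flag
#' degradation products. All coordinates are 0-based half-open internally.
#'
#' @name reference_set
NULL

new_mature_annotation <- function(mature_id, hairpin_id, start, end,
                                  arm = c("unknown", "5p", "3p")) {
  arm <- match.arg(arm)
  data.frame(mature_id = mature_id, hairpin_id = hairpin_id,
             start = as.integer(start), end = as.integer(end),
             arm = arm, stringsAsFactors = FALSE)
}

#' Build a reference set from in-memory sequences
#'
#' @param hairpins named character vector of hairpin sequences.
#' @param matures data.frame with columns `mature_id`, `hairpin_id`, `start`,
#'   `end`, `arm` (0-based half-open coordinates on the hairpin).
#' @param pirnas,contaminants,mrnas optional named character vectors.
#' @return A `reference_set` object.
#' @export
reference_set <- function(hairpins = character(), matures = NULL,
                          pirnas = character(), contaminants = character(),
                          mrnas = character()) {
  if (is.null(matures)) {
    matures <- data.frame(mature_id = character(), hairpin_id = character(),
                          start = integer(), end = integer(),
                          arm = character(), stringsAsFactors = FALSE)
  }
  refs <- structure(list(
    hairpins = canonicalize_dna(stats::setNames(as.character(hairpins), names(hairpins))),
    matures = matures,
    pirnas = canonicalize_dna(stats::setNames(as.character(pirnas), names(pirnas))),
    contaminants = canonicalize_dna(stats::setNames(as.character(contaminants), names(contaminants))),
    mrnas = canonicalize_dna(stats::setNames(as.character(mrnas), names(mrnas)))
  ), class = "reference_set")
  report <- validate_reference(refs)
  if (nrow(report)) {
    stop("invalid reference set:\n",
         paste(report$message, collapse = "\n"))
  }
  refs
}

#' Load a reference set from FASTA files
#'
#' Mature arms are anchored on their hairpins either through an annotation
#' table (TSV with columns `mature_id`, `hairpin_id`, `start`, `end`, `arm`)
#' or, when no table is given, by exact substring search of each mature
#' sequence within its hairpin (leftmost occurrence wins, with a warning when
#' several exist). U and T are treated as equivalent. Without an annotation
#' table each mature is searched in every hairpin and anchored on the first
#' hairpin (by id order) that contains it.
#'
#' @param hairpin_fasta path to the hairpin FASTA (gzip accepted).
#' @param mature_fasta path to the mature miRNA FASTA.
#' @param annotation_table optional path to the mature-coordinate TSV.
#' @param pirna_fasta,contaminant_fasta,mrna_fasta optional FASTA paths.
#' @return A `reference_set`.
#' @export
load_reference <- function(hairpin_fasta, mature_fasta, annotation_table = NULL,
                           pirna_fasta = NULL, contaminant_fasta = NULL,
                           mrna_fasta = NULL) {
  hairpins <- read_fasta_seqs(hairpin_fasta)
  mature_seqs <- read_fasta_seqs(mature_fasta)
  if (!is.null(annotation_table)) {
    ann <- read_tsv(annotation_table)
    need <- c("mature_id", "hairpin_id", "start", "end", "arm")
    if (!all(need %in% names(ann))) {
      stop("annotation table must have columns: ", paste(need, collapse = ", "))
    }
    matures <- ann[, need]
    matures$start <- as.integer(matures$start)
    matures$end <- as.integer(matures$end)
  } else {
    matures <- anchor_matures(mature_seqs, hairpins)
  }
  opt <- function(p) if (is.null(p)) character() else read_fasta_seqs(p)
  reference_set(hairpins = hairpins, matures = matures,
                pirnas = opt(pirna_fasta), contaminants = opt(contaminant_fasta),
                mrnas = opt(mrna_fasta))
}

# Anchor each mature sequence by exact substring search over the hairpins.
anchor_matures <- function(mature_seqs, hairpins) {
  rows <- lapply(names(mature_seqs), function(mid) {
    mseq <- mature_seqs[[mid]]
    for (hid in names(hairpins)) {
      hits <- gregexpr(mseq, hairpins[[hid]], fixed = TRUE)[[1]]
      if (hits[1] != -1L) {
        if (length(hits) > 1L) {
          warning("mature ", mid, " occurs ", length(hits), " times in hairpin ",
                  hid, "; anchoring at the leftmost occurrence", call. = FALSE)
        }
        start <- hits[1] - 1L
        arm <- infer_arm(mid, start, start + nchar(mseq), nchar(hairpins[[hid]]))
        return(new_mature_annotation(mid, hid, start, start + nchar(mseq), arm))
      }
    }
    stop("anchoring error: mature ", mid, " not found in any hairpin")
  })
  do.call(rbind, rows)
}

# Arm from the id suffix when present (miRBase style), else from position.
infer_arm <- function(mature_id, start, end, hairpin_len) {
  if (grepl("-5p$", mature_id)) return("5p")
  if (grepl("-3p$", mature_id)) return("3p")
  mid <- (start + end) / 2
  if (mid < hairpin_len / 2) "5p" else if (mid > hairpin_len / 2) "3p" else "unknown"
}

#' Validate a reference set
#'
#' Report-only check of all reference-set invariants: non-empty sequences
#' over the DNA alphabet, unique identifiers per collection, unique mature
#' ids, mature intervals inside their hairpin, and exact agreement between
#' each mature interval and the hairpin subsequence it names (the anchored
#' sequence itself is the source of truth, so this reduces to bounds checks
#' plus hairpin existence).
#'
#' @param refs a `reference_set`.
#' @return data.frame with columns `collection`, `id`, `message`; zero rows
#'   iff the set is valid.
#' @export
validate_reference <- function(refs) {
  bad <- list()
  note <- function(collection, id, message) {
    bad[[length(bad) + 1L]] <<- data.frame(collection = collection, id = id,
                                           message = message,
                                           stringsAsFactors = FALSE)
  }
  for (coll in c("hairpins", "pirnas", "contaminants", "mrnas")) {
    seqs <- refs[[coll]]
    if (length(seqs) == 0) next
    if (is.null(names(seqs)) || any(names(seqs) == "")) {
      note(coll, NA, paste0(coll, ": unnamed sequence(s)"))
      next
    }
    dup <- unique(names(seqs)[duplicated(names(seqs))])
    for (d in dup) note(coll, d, paste0("duplicate id in ", coll, ": ", d))
    empty <- names(seqs)[nchar(seqs) == 0]
    for (e in empty) note(coll, e, paste0("empty sequence: ", e))
    alpha <- names(seqs)[grepl("[^ACGTN]", seqs)]
    for (a in alpha) note(coll, a, paste0("non-ACGTN characters in ", a))
  }
  m <- refs$matures
  dup <- unique(m$mature_id[duplicated(m$mature_id)])
  for (d in dup) note("matures", d, paste0("duplicate mature id: ", d))
  for (i in seq_len(nrow(m))) {
    mid <- m$mature_id[i]
    hid <- m$hairpin_id[i]
    if (!hid %in% names(refs$hairpins)) {
      note("matures", mid, paste0(mid, ": unknown hairpin ", hid))
      next
    }
    hlen <- nchar(refs$hairpins[[hid]])
    if (is.na(m$start[i]) || is.na(m$end[i]) ||
        m$start[i] < 0L || m$end[i] <= m$start[i] || m$end[i] > hlen) {
      note("matures", mid,
           paste0(mid, ": interval [", m$start[i], ",", m$end[i],
                  ") outside hairpin ", hid, " of length ", hlen))
    }
    if (!m$arm[i] %in% c("5p", "3p", "unknown")) {
      note("matures", mid, paste0(mid, ": invalid arm '", m$arm[i], "'"))
    }
  }
  if (length(bad)) do.call(rbind, bad) else
    data.frame(collection = character(), id = character(),
               message = character(), stringsAsFactors = FALSE)
}

#' Extract the mature sequence for one annotation row
#' @param refs a `reference_set`.
#' @param mature_id a mature id present in `refs$matures`.
#' @return the mature sequence (DNA alphabet).
#' @export
mature_sequence <- function(refs, mature_id) {
  i <- match(mature_id, refs$matures$mature_id)
  if (is.na(i)) stop("unknown mature id: ", mature_id)
  substr(refs$hairpins[[refs$matures$hairpin_id[i]]],
         refs$matures$start[i] + 1L, refs$matures$end[i])
}

#' Write a reference set to FASTA + annotation table
#'
#' Emits `hairpins.fa`, `matures.fa`, `matures.tsv` and, when non-empty,
#' `pirnas.fa`, `contaminants.fa`, `mrnas.fa` under `dir`. Reloading with
#' [load_reference()] round-trips the set exactly.
#'
#' @param refs a `reference_set`.
#' @param dir output directory (created if missing).
#' @param rna write sequences in the RNA alphabet (U instead of T).
#' @return `dir`, invisibly.
#' @export
write_reference <- function(refs, dir, rna = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta_seqs(refs$hairpins, file.path(dir, "hairpins.fa"), rna = rna)
  mseqs <- vapply(refs$matures$mature_id, function(m) mature_sequence(refs, m), "")
  write_fasta_seqs(mseqs, file.path(dir, "matures.fa"), rna = rna)
  write_tsv(refs$matures, file.path(dir, "matures.tsv"))
  for (coll in c("pirnas", "contaminants", "mrnas")) {
    if (length(refs[[coll]])) {
      write_fasta_seqs(refs[[coll]], file.path(dir, paste0(coll, ".fa")), rna = rna)
    }
  }
  invisible(dir)
}

#' @export
print.reference_set <- function(x, ...) {
  cat("reference_set:", length(x$hairpins), "hairpins,",
      nrow(x$matures), "matures,", length(x$pirnas), "piRNAs,",
      length(x$contaminants), "contaminants,", length(x$mrnas), "mRNAs\n")
  invisible(x)
}
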