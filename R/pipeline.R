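#' Sequential filtering and the full pipeline
#'
#' The pipeline processes each library through ordered stages: adapter and
#' length cleaning, removal of reads matching contaminant references
#' (Rfam/Repbase-like; seed 20, at most 1 mismatch), assignment to known
#' miRNA hairpins (full-sensitivity scan, at most 2 mismatches, up to a
#' 3 nt non-aligned 3' tail), assignment of the remainder to piRNA
#' references (seed 20, at most 1 mismatch), and removal of still-unassigned
#' reads matching mRNA (degradation products; seed 20, at most 2
#' mismatches). Multi-class reads are resolved by stage order, not score.
#' What survives contaminant and degradation removal constitutes the
#' mappable read set used for length profiling.
#'
#' @name pipeline
NULL

#' Partition unique reads by contaminant match
#'
#' @param reads data.frame of unique reads (column `sequence`, plus any
#'   count columns, carried through).
#' @param contaminants named character vector of contaminant sequences.
#' @param seed_len,max_mismatches aligner settings (defaults 20 and 1).
#' @return list `kept`, `removed` (row partitions of `reads`) and
#'   `fraction_removed` (of unique sequences). Empty contaminant set keeps
#'   everything.
#' @export
filter_contaminants <- function(reads, contaminants, seed_len = 20L,
                                max_mismatches = 1L) {
  if (!length(contaminants) || !nrow(reads)) {
    return(list(kept = reads, removed = reads[0, , drop = FALSE],
                fraction_removed = 0))
  }
  idx <- build_index(contaminants, seed_len)
  hit <- has_hit(reads$sequence, idx,
                 aligner_config(seed_len, max_mismatches))
  list(kept = reads[!hit, , drop = FALSE],
       removed = reads[hit, , drop = FALSE],
       fraction_removed = mean(hit))
}

#' Partition unique reads by mRNA (degradation) match
#'
#' Reads matching protein-coding mRNA are treated as RNA degradation
#' products. Run after miRNA/piRNA assignment, so only the unassigned
#' remainder is eligible. A missing mRNA reference skips the stage.
#'
#' @inheritParams filter_contaminants
#' @param mrnas named character vector of mRNA sequences.
#' @param seed_len,max_mismatches aligner settings (defaults 20 and 2).
#' @return list `kept`, `removed`, `fraction_removed`.
#' @export
filter_mrna_degradation <- function(reads, mrnas, seed_len = 20L,
                                    max_mismatches = 2L) {
  if (!length(mrnas) || !nrow(reads)) {
    return(list(kept = reads, removed = reads[0, , drop = FALSE],
                fraction_removed = 0))
  }
  idx <- build_index(mrnas, seed_len)
  hit <- has_hit(reads$sequence, idx,
                 aligner_config(seed_len, max_mismatches))
  list(kept = reads[!hit, , drop = FALSE],
       removed = reads[hit, , drop = FALSE],
       fraction_removed = mean(hit))
}

# Assign hairpin-aligned unique reads to mature features and classify them.
#
# A hit is mature-compatible only when the read sits where an isomiR can:
# both the 5' and 3' offsets against the mature must be within `max_shift`
# (the trim/extension length bound), and a non-aligned 3' tail is only
# admissible for reads that start exactly at the mature start and reach its
# 3' end (the non-templated-addition geometry). This keeps short spurious
# matches elsewhere on a hairpin from being counted as miRNA.
assign_hairpin_reads <- function(seqs, refs, max_mismatches = 2L,
                                 max_tail3 = 3L, max_shift = 3L) {
  scan_ref <- hairpin_scan_ref(refs$hairpins)
  hits_list <- align_hairpins(seqs, scan_ref, max_mismatches, max_tail3)
  matures <- refs$matures
  out <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    hits <- hits_list[[i]]
    if (!nrow(hits)) next
    L <- nchar(seqs[i])
    feats <- character(0)
    first_call <- NULL
    for (j in seq_len(nrow(hits))) {
      m <- matures[matures$hairpin_id == hits$ref_id[j], , drop = FALSE]
      if (!nrow(m)) next
      s <- hits$ref_start[j]
      so <- s - m$start
      eo <- (s + L) - m$end
      compatible <- abs(so) <= max_shift & abs(eo) <= max_shift &
        (hits$tail3[j] == 0L | (so == 0L & eo >= 0L))
      m <- m[compatible, , drop = FALSE]
      if (!nrow(m)) next
      ov <- pmin(s + L, m$end) - pmax(s, m$start)
      if (max(ov) <= 0L) next
      best_m <- m[which.max(ov), , drop = FALSE]
      feats <- c(feats, best_m$mature_id)
      if (is.null(first_call)) {
        first_call <- classify_isomir(
          seqs[i], refs$hairpins[[hits$ref_id[j]]],
          best_m$start, best_m$end, s, mature_id = best_m$mature_id)
      }
    }
    if (!length(feats)) next
    out[[i]] <- list(feature_ids = unique(feats), call = first_call)
  }
  out
}

# Assign reads to piRNA references via the seeded aligner; returns a list of
# tied best-hit id vectors (empty when unassigned).
assign_pirna_reads <- function(seqs, pirnas, seed_len = 20L,
                               max_mismatches = 1L) {
  if (!length(pirnas)) return(rep(list(character(0)), length(seqs)))
  idx <- build_index(pirnas, seed_len)
  cfg <- aligner_config(seed_len, max_mismatches)
  lapply(seqs, function(s) {
    hits <- align_read(s, idx, cfg)
    if (!nrow(hits)) return(character(0))
    unique(best_hits(hits)$hits$ref_id)
  })
}

#' Run the complete small RNA pipeline
#'
#' @param inputs named list (or vector) of per-library inputs: FASTQ/FASTA
#'   paths or raw read character vectors. Names are the library ids; the
#'   convention `<condition>_<compartment>` (e.g. `Aag2_nucleus`) enables
#'   the automatic condition/compartment analyses.
#' @param refs a `reference_set`.
#' @param adapter 3' adapter sequence.
#' @param min_len minimum insert length (default 16, inclusive).
#' @param min_overlap,max_mismatch_rate,min_mean_quality cleaning
#'   parameters, see [process_reads()].
#' @param contaminant_seed,contaminant_mm,pirna_seed,pirna_mm,mrna_seed,mrna_mm
#'   per-stage aligner settings.
#' @param hairpin_mm,max_tail3 hairpin-stage scan settings.
#' @param max_shift maximum 5'/3' offset against the mature for a hairpin
#'   hit to count as that miRNA (default 3, the trim/extension bound).
#' @param mrna_before_mirna run degradation removal before miRNA assignment
#'   (default FALSE: miRNA assignment first, mirroring pipelines where about
#'   half of clean reads count as known miRNAs).
#' @param size_factor_method [size_factors()] method; normalization is
#'   computed per compared library pair.
#' @param log2_threshold differential-table inclusion threshold.
#' @param min_count detection threshold for compartment partitions.
#' @param pairs list of `c(library_a, library_b)` comparisons; defaults to
#'   Aag2 versus Pop within each compartment when the library names follow
#'   the `<condition>_<compartment>` convention.
#' @return list with per-stage results: `accounting` (per-library read
#'   conservation table), `reads` (master unique-read table with per-library
#'   counts and assigned class), `mirna_counts`, `pirna_counts`,
#'   `isomir_calls`, `isomir_summary`, `length_profiles`, `range_summaries`,
#'   `de` (per pair and feature class), `partitions` and `shifts` (when the
#'   naming convention applies).
#' @export
run_pipeline <- function(inputs, refs, adapter,
                         min_len = 16L, min_overlap = 6L,
                         max_mismatch_rate = 0.1, min_mean_quality = 20,
                         contaminant_seed = 20L, contaminant_mm = 1L,
                         hairpin_mm = 2L, max_tail3 = 3L, max_shift = 3L,
                         pirna_seed = 20L, pirna_mm = 1L,
                         mrna_seed = 20L, mrna_mm = 2L,
                         mrna_before_mirna = FALSE,
                         size_factor_method = "median_of_ratios",
                         log2_threshold = 1, min_count = 1,
                         pairs = NULL) {
  lib_names <- names(inputs)
  if (is.null(lib_names) || any(lib_names == "")) {
    stop("inputs must be a named list of libraries")
  }

  # stage 1: per-library cleaning and collapsing
  cleaned <- lapply(inputs, process_reads, adapter = adapter,
                    min_len = min_len, min_overlap = min_overlap,
                    max_mismatch_rate = max_mismatch_rate,
                    min_mean_quality = min_mean_quality)
  accounting <- do.call(rbind, lapply(lib_names, function(nm) {
    cbind(library = nm, cleaned[[nm]]$accounting)
  }))

  # master table: unique sequence x per-library counts
  all_seqs <- sort(unique(unlist(lapply(cleaned, function(x) x$reads$sequence))))
  master <- data.frame(sequence = all_seqs, stringsAsFactors = FALSE)
  for (nm in lib_names) {
    v <- stats::setNames(cleaned[[nm]]$reads$count, cleaned[[nm]]$reads$sequence)
    cnt <- v[master$sequence]
    cnt[is.na(cnt)] <- 0L
    master[[nm]] <- as.integer(cnt)
  }
  master$class <- rep("unassigned", nrow(master))

  # stage 2: contaminant removal
  fc <- filter_contaminants(master, refs$contaminants,
                            seed_len = contaminant_seed,
                            max_mismatches = contaminant_mm)
  master$class[master$sequence %in% fc$removed$sequence] <- "contaminant"
  remaining <- fc$kept

  # optional early degradation removal
  if (mrna_before_mirna) {
    fm <- filter_mrna_degradation(remaining, refs$mrnas, seed_len = mrna_seed,
                                  max_mismatches = mrna_mm)
    master$class[master$sequence %in% fm$removed$sequence] <- "degradation"
    remaining <- fm$kept
  }

  # stage 3: known-miRNA assignment + isomiR classification
  assignments <- NULL
  isomir_calls <- data.frame()
  if (length(refs$hairpins) && nrow(remaining)) {
    asg <- assign_hairpin_reads(remaining$sequence, refs,
                                max_mismatches = hairpin_mm,
                                max_tail3 = max_tail3, max_shift = max_shift)
    assigned <- !vapply(asg, is.null, logical(1))
    if (any(assigned)) {
      arows <- remaining[assigned, , drop = FALSE]
      feature_ids <- lapply(asg[assigned], `[[`, "feature_ids")
      calls <- do.call(rbind, lapply(asg[assigned], `[[`, "call"))
      assignments <- cbind(arows, call_category = calls$category)
      assignments$feature_ids <- feature_ids
      isomir_calls <- cbind(calls, arows[, lib_names, drop = FALSE])
      master$class[master$sequence %in% arows$sequence] <- "mirna"
      remaining <- remaining[!assigned, , drop = FALSE]
    }
  }

  # stage 4: piRNA assignment
  pirna_assign <- NULL
  if (length(refs$pirnas) && nrow(remaining)) {
    pids <- assign_pirna_reads(remaining$sequence, refs$pirnas,
                               seed_len = pirna_seed, max_mismatches = pirna_mm)
    hit <- lengths(pids) > 0L
    if (any(hit)) {
      pirna_assign <- remaining[hit, , drop = FALSE]
      pirna_assign$feature_ids <- pids[hit]
      master$class[master$sequence %in% pirna_assign$sequence] <- "pirna"
      remaining <- remaining[!hit, , drop = FALSE]
    }
  }

  # stage 5: late degradation removal of the unassigned remainder
  if (!mrna_before_mirna && nrow(remaining)) {
    fm <- filter_mrna_degradation(remaining, refs$mrnas, seed_len = mrna_seed,
                                  max_mismatches = mrna_mm)
    master$class[master$sequence %in% fm$removed$sequence] <- "degradation"
    remaining <- fm$kept
  }

  # count matrices
  long_assign <- function(adf) {
    do.call(rbind, lapply(lib_names, function(nm) {
      data.frame(library = nm, count = adf[[nm]],
                 feature_ids = I(adf$feature_ids), stringsAsFactors = FALSE)
    }))
  }
  mirna_counts <- if (!is.null(assignments)) {
    count_features(long_assign(assignments),
                   features = refs$matures$mature_id, libraries = lib_names)
  } else {
    matrix(0, nrow = nrow(refs$matures), ncol = length(lib_names),
           dimnames = list(refs$matures$mature_id, lib_names))
  }
  pirna_counts <- if (!is.null(pirna_assign)) {
    count_features(long_assign(pirna_assign),
                   features = names(refs$pirnas), libraries = lib_names)
  } else {
    matrix(0, nrow = length(refs$pirnas), ncol = length(lib_names),
           dimnames = list(names(refs$pirnas), lib_names))
  }

  # isomiR summary (per library, category counts over classified reads)
  iso_summary <- if (nrow(isomir_calls)) {
    long <- do.call(rbind, lapply(lib_names, function(nm) {
      data.frame(library = nm, category = isomir_calls$category,
                 count = isomir_calls[[nm]], stringsAsFactors = FALSE)
    }))
    isomir_summary(long[long$count > 0, , drop = FALSE])
  } else {
    isomir_summary(data.frame(library = character(), category = character(),
                              count = numeric()))
  }

  # per-library stage accounting (summed read counts)
  class_counts <- t(vapply(lib_names, function(nm) {
    vapply(c("contaminant", "mirna", "pirna", "degradation", "unassigned"),
           function(cl) sum(master[[nm]][master$class == cl]), 0)
  }, numeric(5)))
  accounting <- cbind(accounting, class_counts)

  # length profiles on mappable reads (everything except contaminant and
  # degradation classes)
  mappable <- master[!master$class %in% c("contaminant", "degradation"), ,
                     drop = FALSE]
  length_profiles <- lapply(lib_names, function(nm) {
    length_distribution(data.frame(sequence = mappable$sequence,
                                   count = mappable[[nm]]), library = nm)
  })
  names(length_profiles) <- lib_names
  range_summaries <- t(vapply(length_profiles, range_summary, numeric(2)))

  # differential expression per pair, normalized per pair
  if (is.null(pairs)) pairs <- default_pairs(lib_names)
  de <- list()
  for (p in pairs) {
    key <- paste(p, collapse = "_vs_")
    de[[key]] <- list()
    for (cls in c("mirna", "pirna")) {
      m <- if (cls == "mirna") mirna_counts else pirna_counts
      if (!nrow(m)) next
      sub <- m[, p, drop = FALSE]
      sf <- suppressWarnings(size_factors(sub, size_factor_method))
      norm <- normalize_counts(sub, sf)
      de[[key]][[cls]] <- list(
        normalized = norm, size_factors = sf,
        table = de_table(norm, p, log2_threshold = log2_threshold))
    }
  }

  # detection partitions per condition (naming convention)
  partitions <- list()
  shifts <- NULL
  conds <- unique(sub("_(nucleus|cytoplasm)$", "",
                      grep("_(nucleus|cytoplasm)$", lib_names, value = TRUE)))
  for (cond in conds) {
    nl <- paste0(cond, "_nucleus"); cl <- paste0(cond, "_cytoplasm")
    if (all(c(nl, cl) %in% lib_names)) {
      partitions[[cond]] <- detection_partition(
        detect_features(mirna_counts, nl, min_count),
        detect_features(mirna_counts, cl, min_count), condition = cond)
    }
  }
  if (length(partitions) == 2L) {
    shifts <- compartment_shift(partitions[[1]], partitions[[2]])
  }

  list(accounting = accounting, reads = master,
       mirna_counts = mirna_counts, pirna_counts = pirna_counts,
       isomir_calls = isomir_calls, isomir_summary = iso_summary,
       length_profiles = length_profiles, range_summaries = range_summaries,
       de = de, partitions = partitions, shifts = shifts)
}

default_pairs <- function(lib_names) {
  pairs <- list()
  for (comp in c("nucleus", "cytoplasm")) {
    a <- paste0("Aag2_", comp); b <- paste0("Pop_", comp)
    if (all(c(a, b) %in% lib_names)) pairs[[comp]] <- c(a, b)
  }
  pairs
}

#' Write the main pipeline result tables as TSV
#'
#' @param result a [run_pipeline()] result.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_pipeline_results <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv(result$accounting, file.path(dir, "accounting.tsv"))
  mat_df <- function(m) cbind(data.frame(feature = rownames(m),
                                         stringsAsFactors = FALSE),
                              as.data.frame(m))
  write_tsv(mat_df(result$mirna_counts), file.path(dir, "mirna_counts.tsv"))
  write_tsv(mat_df(result$pirna_counts), file.path(dir, "pirna_counts.tsv"))
  write_tsv(result$isomir_summary, file.path(dir, "isomir_summary.tsv"))
  lp <- do.call(rbind, result$length_profiles)
  write_tsv(lp, file.path(dir, "length_profiles.tsv"))
  for (key in names(result$de)) {
    for (cls in names(result$de[[key]])) {
      write_tsv(result$de[[key]][[cls]]$table,
                file.path(dir, paste0("de_", cls, "_", key, ".tsv")))
    }
  }
  if (!is.null(result$shifts)) {
    write_tsv(result$shifts, file.path(dir, "compartment_shifts.tsv"))
  }
  invisible(dir)
}
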