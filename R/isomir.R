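#' IsomiR classification against the annotated mature sequence
#'
#' A read placed on its hairpin is compared with the reference mature arm
#' and assigned one of seven categories plus a fallback:
#' \describe{
#'   \item{CANONICAL}{same start, same end, no internal mismatch.}
#'   \item{TRIM5}{starts after the mature start but ends at the mature end.}
#'   \item{TRIM3}{starts at the mature start but is shorter at the 3' end.}
#'   \item{EXT5}{starts before the mature start and ends at the mature end
#'     (the extra 5' bases are, by placement, templated on the hairpin).}
#'   \item{EXT3}{same start, at least two bases longer at the 3' end, and
#'     every overhang base matches the hairpin continuation (templated).}
#'   \item{ADD3}{same start, at least two bases longer at the 3' end, and
#'     at least one overhang base does not match the hairpin continuation;
#'     bases beyond the hairpin's 3' terminus cannot be templated and count
#'     as non-matching.}
#'   \item{SUBST}{same start and same length as the mature, with at least
#'     one internal substitution.}
#'   \item{OTHER}{anything else (e.g. a single-base 3' elongation, or
#'     combined 5' and 3' changes); the reason is kept in `detail`.}
#' }
#' Single-base 3' elongations are deliberately not called EXT3/ADD3: the
#' addition/extension categories are defined for reads at least two
#' nucleotides longer than the mature.
#'
#' @name isomir
NULL

ISOMIR_CATEGORIES <- c("CANONICAL", "TRIM5", "TRIM3", "EXT5", "EXT3",
                       "ADD3", "SUBST", "OTHER")

#' Classify one read placement as an isomiR category
#'
#' @param read the read sequence.
#' @param hairpin the hairpin sequence the read is placed on.
#' @param mature_start,mature_end 0-based half-open mature interval on the
#'   hairpin.
#' @param align_start 0-based position of the read's first base on the
#'   hairpin (the read may run past the hairpin's 3' end).
#' @param mature_id optional mature identifier carried through to the output.
#' @return one-row data.frame: `mature_id`, `read`, `start_offset`
#'   (read start minus mature start), `end_offset` (read end minus mature
#'   end), `category`, `n_internal_mm` (substitutions inside the overlap
#'   with the mature span), `overhang` (3' overhang bases, `""` if none),
#'   `detail` (semicolon-separated notes, e.g. mismatch offsets).
#' @export
classify_isomir <- function(read, hairpin, mature_start, mature_end,
                            align_start, mature_id = NA_character_) {
  read <- canonicalize_dna(read)
  hairpin <- canonicalize_dna(hairpin)
  L <- nchar(read)
  hlen <- nchar(hairpin)
  read_end <- align_start + L                     # 0-based exclusive
  if (max(align_start, mature_start) >= min(read_end, mature_end)) {
    stop("read placement does not overlap the mature interval")
  }
  start_offset <- align_start - mature_start
  end_offset <- read_end - mature_end

  # internal mismatches: read vs hairpin over the part of the read lying
  # inside the mature span (and on the hairpin)
  ov_from <- max(align_start, mature_start)       # 0-based
  ov_to <- min(read_end, mature_end, hlen)        # exclusive
  mm_off <- integer(0)
  if (ov_to > ov_from) {
    rpart <- substr(read, ov_from - align_start + 1L, ov_to - align_start)
    hpart <- substr(hairpin, ov_from + 1L, ov_to)
    mm_off <- mismatch_positions(rpart, hpart) + (ov_from - align_start)
  }
  n_mm <- length(mm_off)

  # 3' overhang relative to the mature end, and its templated-ness
  overhang <- ""
  overhang_templated <- NA
  if (end_offset > 0L) {
    overhang <- substr(read, L - end_offset + 1L, L)
    n_templ <- max(0L, min(read_end, hlen) - mature_end)  # bases on hairpin
    templ <- if (n_templ > 0L) {
      substr(hairpin, mature_end + 1L, mature_end + n_templ)
    } else ""
    cmp_len <- nchar(templ)
    matches_template <- cmp_len == nchar(overhang) &&
      length(mismatch_positions(substr(overhang, 1L, cmp_len), templ)) == 0L
    overhang_templated <- matches_template
  }

  detail <- character(0)
  category <- NULL
  if (start_offset == 0L && end_offset == 0L) {
    category <- if (n_mm == 0L) "CANONICAL" else "SUBST"
    if (n_mm > 0L) detail <- c(detail, paste0("mm_at=", paste(mm_off, collapse = ",")))
  } else if (start_offset > 0L && end_offset == 0L) {
    category <- "TRIM5"
  } else if (start_offset < 0L && end_offset == 0L) {
    category <- "EXT5"
  } else if (start_offset == 0L && end_offset < 0L) {
    category <- "TRIM3"
  } else if (start_offset == 0L && end_offset >= 2L) {
    category <- if (isTRUE(overhang_templated)) "EXT3" else "ADD3"
    detail <- c(detail, paste0("overhang=", overhang))
  } else if (start_offset == 0L && end_offset == 1L) {
    category <- "OTHER"
    detail <- c(detail, if (isTRUE(overhang_templated)) "elong1_templated"
                else "elong1_nontemplated")
  } else {
    category <- "OTHER"
    detail <- c(detail, "combined_5p_3p_change")
  }
  if (n_mm > 0L && category != "SUBST") {
    detail <- c(detail, paste0("internal_mm=", paste(mm_off, collapse = ",")))
  }
  data.frame(mature_id = mature_id, read = read,
             start_offset = as.integer(start_offset),
             end_offset = as.integer(end_offset),
             category = category, n_internal_mm = n_mm,
             overhang = overhang,
             detail = paste(detail, collapse = ";"),
             stringsAsFactors = FALSE)
}

#' Summarize isomiR categories per library
#'
#' @param calls data.frame with at least columns `library`, `category`,
#'   `count` (summed read counts for that call).
#' @return data.frame `library`, `category`, `reads`, `fraction`, one row
#'   per library and category (all categories always present, zero-filled);
#'   fractions are over all classified reads of the library, canonical
#'   included.
#' @export
isomir_summary <- function(calls) {
  libs <- if (nrow(calls)) sort(unique(calls$library)) else character(0)
  grid <- expand.grid(library = libs, category = ISOMIR_CATEGORIES,
                      stringsAsFactors = FALSE)
  if (nrow(calls)) {
    agg <- stats::aggregate(count ~ library + category, data = calls, FUN = sum)
    grid <- merge(grid, agg, by = c("library", "category"), all.x = TRUE)
    grid$count[is.na(grid$count)] <- 0
  } else {
    grid$count <- numeric(0)
  }
  names(grid)[names(grid) == "count"] <- "reads"
  totals <- if (nrow(grid)) stats::ave(grid$reads, grid$library, FUN = sum) else numeric(0)
  grid$fraction <- ifelse(totals > 0, grid$reads / totals, 0)
  grid$category <- factor(grid$category, levels = ISOMIR_CATEGORIES)
  grid <- grid[order(grid$library, grid$category), , drop = FALSE]
  grid$category <- as.character(grid$category)
  rownames(grid) <- NULL
  grid
}
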