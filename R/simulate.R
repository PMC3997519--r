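#' Synthetic four-library small RNA experiment
#'
#' The generator emulates the structure of a nucleus/cytoplasm small RNA
#' sequencing experiment in uninfected (Aag2) and Wolbachia-infected (Pop)
#' mosquito cells: four libraries (condition x compartment) of fixed-cycle
#' 36 nt reads, each read an insert followed by the 3' adapter. Inserts are
#' drawn from miRNA matures (with per-read isomiR modifications), piRNA
#' loci (26-30 nt), contaminant references and mRNA degradation fragments.
#' Per-feature base abundances are log-normal; condition effects are
#' per-feature log2 fold changes (including full on/off features for the
#' infinite-fold cases); compartment effects include exclusive features.
#' Sampling is multinomial at fixed depth so library totals are exact, and
#' everything is reproducible byte-for-byte from one seed.
#'
#' @name synthetic_data
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' Simulation configuration
#'
#' Defaults describe the study conditions the pipeline is validated under:
#' 30 miRNA features (3 up- and 3 down-regulated at |log2FC| = 2 upon
#' infection, 1 infected-only, 1 uninfected-only, 1 nucleus-only,
#' 1 cytoplasm-only), 40 piRNA loci with a piRNA-rich cytoplasm, isomiR
#' rates TRIM3 0.1, EXT3 0.2, ADD3 0.05, SUBST 0.05, and depth 1e5 reads
#' per library.
#'
#' @param n_features number of miRNA features (one annotated mature per
#'   hairpin).
#' @param n_pirna number of piRNA loci.
#' @param hairpin_len,mature_len,pirna_len inclusive length ranges.
#' @param abundance_meanlog,abundance_sdlog log-normal base-abundance
#'   parameters (per feature, shared across libraries).
#' @param n_condition_up,n_condition_down features with finite infection
#'   effects of `+condition_lfc` / `-condition_lfc` log2 units.
#' @param condition_lfc magnitude of the finite infection effect.
#' @param n_infected_only,n_uninfected_only condition-exclusive features
#'   (true log2FC `+Inf` / `-Inf`).
#' @param n_nucleus_only,n_cytoplasm_only compartment-exclusive features.
#' @param nucleus_enrichment_sdlog log-normal spread of per-feature
#'   nucleus/cytoplasm enrichment for non-exclusive features.
#' @param isomir_rates named per-read modification probabilities over
#'   `TRIM5`, `TRIM3`, `EXT5`, `EXT3`, `ADD3`, `SUBST`; their sum must be
#'   at most 1 and the remainder is the canonical rate.
#' @param adapter 3' adapter appended to every insert.
#' @param read_len raw read length (fixed-cycle; default 36).
#' @param depth reads per library.
#' @param contaminant_fraction,degradation_fraction read-class fractions
#'   shared by all libraries.
#' @param pirna_fraction_nucleus,pirna_fraction_cytoplasm piRNA read-class
#'   fraction per compartment (piRNA-sized reads dominate the cytoplasm);
#'   the miRNA class receives the remainder.
#' @param n_pirna_up,pirna_lfc piRNA loci up-regulated upon infection and
#'   their log2 effect; `n_pirna_on` / `n_pirna_off` are infected-only /
#'   uninfected-only piRNA loci.
#' @param n_contaminants,contaminant_len,n_mrnas,mrna_len decoy reference
#'   geometry.
#' @param min_mature_distance minimum pairwise Hamming distance enforced
#'   between matures (and on their first 16 bases) so that mismatch-tolerant
#'   alignment cannot cross-assign canonical reads.
#' @param seed integer seed fixing the complete output.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_features = 30L, n_pirna = 40L,
                       hairpin_len = c(60L, 100L), mature_len = c(20L, 23L),
                       pirna_len = c(26L, 30L),
                       abundance_meanlog = 0, abundance_sdlog = 0.5,
                       n_condition_up = 3L, n_condition_down = 3L,
                       condition_lfc = 2,
                       n_infected_only = 1L, n_uninfected_only = 1L,
                       n_nucleus_only = 1L, n_cytoplasm_only = 1L,
                       nucleus_enrichment_sdlog = 0.3,
                       isomir_rates = c(TRIM5 = 0, TRIM3 = 0.1, EXT5 = 0,
                                        EXT3 = 0.2, ADD3 = 0.05, SUBST = 0.05),
                       adapter = "TGGAATTCTCGGGTGCCAAGG",
                       read_len = 36L, depth = 1e5,
                       contaminant_fraction = 0.08,
                       degradation_fraction = 0.10,
                       pirna_fraction_nucleus = 0.20,
                       pirna_fraction_cytoplasm = 0.35,
                       n_pirna_up = 3L, pirna_lfc = 1.5,
                       n_pirna_on = 1L, n_pirna_off = 1L,
                       n_contaminants = 5L, contaminant_len = 200L,
                       n_mrnas = 5L, mrna_len = 500L,
                       min_mature_distance = 8L,
                       seed = 1L) {
  rates <- c(TRIM5 = 0, TRIM3 = 0, EXT5 = 0, EXT3 = 0, ADD3 = 0, SUBST = 0)
  rates[names(isomir_rates)] <- isomir_rates
  if (any(rates < 0) || sum(rates) > 1) {
    stop("isomiR rates must be in [0,1] and sum to at most 1")
  }
  n_special <- n_condition_up + n_condition_down + n_infected_only +
    n_uninfected_only + n_nucleus_only + n_cytoplasm_only
  if (n_special > n_features) {
    stop("more special features requested than features available")
  }
  if (depth < 0) stop("depth must be >= 0")
  cfg <- as.list(environment())
  cfg$isomir_rates <- rates
  structure(cfg, class = "sim_config")
}

rand_seqs <- function(lens) {
  vapply(lens, function(l) paste(sample(DNA_BASES, l, replace = TRUE),
                                 collapse = ""), "")
}

# Feature roles: disjoint assignment of condition/compartment effects.
assign_roles <- function(cfg) {
  ids <- sprintf("syn-miR-%02d", seq_len(cfg$n_features))
  role <- rep("none", cfg$n_features)
  pool <- sample(seq_len(cfg$n_features))
  take <- function(n) {
    out <- pool[seq_len(n)]
    pool <<- pool[-seq_len(n)]
    out
  }
  if (cfg$n_condition_up) role[take(cfg$n_condition_up)] <- "cond_up"
  if (cfg$n_condition_down) role[take(cfg$n_condition_down)] <- "cond_down"
  if (cfg$n_infected_only) role[take(cfg$n_infected_only)] <- "infected_only"
  if (cfg$n_uninfected_only) role[take(cfg$n_uninfected_only)] <- "uninfected_only"
  if (cfg$n_nucleus_only) role[take(cfg$n_nucleus_only)] <- "nucleus_only"
  if (cfg$n_cytoplasm_only) role[take(cfg$n_cytoplasm_only)] <- "cytoplasm_only"
  lfc <- rep(0, cfg$n_features)
  lfc[role == "cond_up"] <- cfg$condition_lfc
  lfc[role == "cond_down"] <- -cfg$condition_lfc
  lfc[role == "infected_only"] <- Inf
  lfc[role == "uninfected_only"] <- -Inf
  compartment <- rep("both", cfg$n_features)
  compartment[role == "nucleus_only"] <- "nucleus"
  compartment[role == "cytoplasm_only"] <- "cytoplasm"
  data.frame(feature_id = ids, role = role, true_lfc = lfc,
             compartment = compartment, stringsAsFactors = FALSE)
}

# Draw mature sequences with enforced pairwise separation, then embed each
# in a random hairpin with >= 4 nt flanks on both sides.
generate_reference_impl <- function(cfg) {
  n <- cfg$n_features
  matseqs <- character(0)
  tries <- 0L
  while (length(matseqs) < n) {
    if (tries > 200L * max(1L, n)) {
      stop("could not satisfy mature distinctness after bounded retries")
    }
    tries <- tries + 1L
    cand <- rand_seqs(sample(cfg$mature_len[1]:cfg$mature_len[2], 1L))
    ok <- all(vapply(matseqs, function(m) {
      k <- min(nchar(m), nchar(cand))
      full <- hamming(substr(m, 1L, k), substr(cand, 1L, k))
      head16 <- hamming(substr(m, 1L, min(16L, k)), substr(cand, 1L, min(16L, k)))
      full >= cfg$min_mature_distance && head16 >= 6L
    }, logical(1)))
    if (ok) matseqs <- c(matseqs, cand)
  }
  roles <- assign_roles(cfg)
  hp_ids <- sprintf("syn-hp-%02d", seq_len(n))
  hairpins <- character(n)
  starts <- integer(n)
  for (i in seq_len(n)) {
    hlen <- sample(cfg$hairpin_len[1]:cfg$hairpin_len[2], 1L)
    mlen <- nchar(matseqs[i])
    start <- sample(4L:(hlen - mlen - 4L), 1L)   # 0-based, >=4 nt flanks
    left <- rand_seqs(start)
    right <- rand_seqs(hlen - start - mlen)
    hairpins[i] <- paste0(left, matseqs[i], right)
    starts[i] <- start
  }
  names(hairpins) <- hp_ids
  matures <- data.frame(mature_id = roles$feature_id, hairpin_id = hp_ids,
                        start = starts,
                        end = starts + nchar(matseqs),
                        arm = "unknown", stringsAsFactors = FALSE)
  pirnas <- rand_seqs(sample(cfg$pirna_len[1]:cfg$pirna_len[2], cfg$n_pirna,
                             replace = TRUE))
  names(pirnas) <- sprintf("PIR%04d", seq_len(cfg$n_pirna))
  contaminants <- rand_seqs(rep(cfg$contaminant_len, cfg$n_contaminants))
  names(contaminants) <- sprintf("syn-contam-%02d", seq_len(cfg$n_contaminants))
  mrnas <- rand_seqs(rep(cfg$mrna_len, cfg$n_mrnas))
  names(mrnas) <- sprintf("syn-mrna-%02d", seq_len(cfg$n_mrnas))
  refs <- reference_set(hairpins = hairpins, matures = matures,
                        pirnas = pirnas, contaminants = contaminants,
                        mrnas = mrnas)
  list(refs = refs, roles = roles)
}

#' Generate a synthetic reference set
#'
#' @param config a [sim_config()].
#' @return a `reference_set` with the per-feature role table attached as
#'   attribute `roles`.
#' @export
generate_reference <- function(config) {
  set.seed(config$seed)
  if (config$n_features == 0L) {
    out <- reference_set()
    attr(out, "roles") <- assign_roles(config)
    return(out)
  }
  gen <- generate_reference_impl(config)
  out <- gen$refs
  attr(out, "roles") <- gen$roles
  out
}

# piRNA role table: abundances and infection effects for piRNA loci.
assign_pirna_roles <- function(cfg) {
  ids <- sprintf("PIR%04d", seq_len(cfg$n_pirna))
  role <- rep("none", cfg$n_pirna)
  pool <- sample(seq_len(cfg$n_pirna))
  take <- function(n) { out <- pool[seq_len(n)]; pool <<- pool[-seq_len(n)]; out }
  if (cfg$n_pirna_up) role[take(cfg$n_pirna_up)] <- "cond_up"
  if (cfg$n_pirna_on) role[take(cfg$n_pirna_on)] <- "infected_only"
  if (cfg$n_pirna_off) role[take(cfg$n_pirna_off)] <- "uninfected_only"
  lfc <- rep(0, cfg$n_pirna)
  lfc[role == "cond_up"] <- cfg$pirna_lfc
  lfc[role == "infected_only"] <- Inf
  lfc[role == "uninfected_only"] <- -Inf
  data.frame(feature_id = ids, role = role, true_lfc = lfc,
             stringsAsFactors = FALSE)
}

# Relative within-class weight of each feature in one library.
library_weights <- function(base, lfc, comp_class, infected, compartment,
                            nucleus_enrich) {
  w <- base
  w <- w * ifelse(compartment == "nucleus", nucleus_enrich, 1)
  if (infected) {
    w <- w * ifelse(is.finite(lfc), 2^lfc, ifelse(lfc > 0, 1, 0))
  } else {
    w <- w * ifelse(is.finite(lfc) | lfc < 0, 1, 0)
  }
  w[comp_class == "nucleus" & compartment != "nucleus"] <- 0
  w[comp_class == "cytoplasm" & compartment != "cytoplasm"] <- 0
  w
}

# Apply one isomiR category to n copies of a mature; returns read sequences.
apply_isomir <- function(category, n, mature, hairpin, mstart, mend) {
  if (n == 0L) return(character(0))
  mlen <- nchar(mature)
  switch(category,
    CANONICAL = rep(mature, n),
    TRIM3 = {
      k <- sample(1:3, n, replace = TRUE, prob = c(4, 2, 1) / 7)
      substr(rep(mature, n), 1L, mlen - k)
    },
    TRIM5 = {
      k <- sample(1:3, n, replace = TRUE, prob = c(4, 2, 1) / 7)
      substring(rep(mature, n), k + 1L)
    },
    EXT5 = {
      k <- sample(1:3, n, replace = TRUE, prob = c(4, 2, 1) / 7)
      paste0(substring(hairpin, mstart - k + 1L, mstart), mature)
    },
    EXT3 = {
      k <- sample(2:3, n, replace = TRUE, prob = c(2, 1) / 3)
      paste0(mature, substring(hairpin, mend + 1L, mend + k))
    },
    ADD3 = {
      k <- sample(2:3, n, replace = TRUE, prob = c(2, 1) / 3)
      tails <- vapply(k, function(kk) {
        templ <- strsplit(substr(hairpin, mend + 1L, mend + kk), "")[[1]]
        paste(vapply(templ, function(tb) sample(setdiff(DNA_BASES, tb), 1L), ""),
              collapse = "")
      }, "")
      paste0(mature, tails)
    },
    SUBST = {
      pos <- sample.int(mlen, n, replace = TRUE)
      vapply(seq_len(n), function(i) {
        orig <- substr(mature, pos[i], pos[i])
        sub <- sample(setdiff(DNA_BASES, orig), 1L)
        paste0(substr(mature, 1L, pos[i] - 1L), sub,
               substring(mature, pos[i] + 1L))
      }, "")
    },
    stop("unknown isomiR category: ", category))
}

# Simulate one library; returns inserts (one per read, emission order) and
# the aggregated emission log.
simulate_library_impl <- function(cfg, refs, roles, pirna_roles,
                                  base_abund, nucleus_enrich, pirna_abund,
                                  condition, compartment) {
  infected <- condition == "Pop"
  pirna_frac <- if (compartment == "nucleus") cfg$pirna_fraction_nucleus else
    cfg$pirna_fraction_cytoplasm
  mirna_frac <- 1 - pirna_frac - cfg$contaminant_fraction -
    cfg$degradation_fraction
  stopifnot(mirna_frac > 0)

  w_mir <- library_weights(base_abund, roles$true_lfc, roles$compartment,
                           infected, compartment, nucleus_enrich)
  w_pir <- library_weights(pirna_abund, pirna_roles$true_lfc,
                           rep("both", cfg$n_pirna), infected, compartment,
                           rep(1, cfg$n_pirna))
  atoms <- c(
    if (cfg$n_features) mirna_frac * w_mir / sum(w_mir),
    if (cfg$n_pirna) pirna_frac * w_pir / sum(w_pir),
    cfg$contaminant_fraction, cfg$degradation_fraction)
  atom_class <- c(rep("mirna", cfg$n_features), rep("pirna", cfg$n_pirna),
                  "contaminant", "degradation")
  atom_id <- c(roles$feature_id, pirna_roles$feature_id, "contaminant",
               "degradation")
  counts <- as.integer(stats::rmultinom(1, cfg$depth, atoms))

  inserts <- character(0)
  log_rows <- list()
  logit <- function(class, feature, category, seqs) {
    if (!length(seqs)) return(invisible())
    tab <- table(seqs)
    log_rows[[length(log_rows) + 1L]] <<- data.frame(
      condition = condition, compartment = compartment, class = class,
      feature_id = feature, category = category,
      sequence = names(tab), count = as.integer(tab),
      stringsAsFactors = FALSE)
  }
  cat_probs <- c(cfg$isomir_rates, CANONICAL = 1 - sum(cfg$isomir_rates))
  for (i in seq_along(counts)) {
    n <- counts[i]
    if (n == 0L) next
    cls <- atom_class[i]
    if (cls == "mirna") {
      fid <- atom_id[i]
      mi <- match(fid, refs$matures$mature_id)
      hp <- refs$hairpins[[refs$matures$hairpin_id[mi]]]
      mstart <- refs$matures$start[mi]
      mend <- refs$matures$end[mi]
      mature <- substr(hp, mstart + 1L, mend)
      ncat <- as.integer(stats::rmultinom(1, n, cat_probs))
      names(ncat) <- names(cat_probs)
      for (catg in names(ncat)) {
        seqs <- apply_isomir(catg, ncat[[catg]], mature, hp, mstart, mend)
        logit("mirna", fid, catg, seqs)
        inserts <- c(inserts, seqs)
      }
    } else if (cls == "pirna") {
      fid <- atom_id[i]
      seqs <- rep(refs$pirnas[[fid]], n)
      logit("pirna", fid, "CANONICAL", seqs)
      inserts <- c(inserts, seqs)
    } else if (cls == "contaminant") {
      src <- sample.int(length(refs$contaminants), n, replace = TRUE)
      lens <- sample(18:30, n, replace = TRUE)
      starts <- vapply(seq_len(n), function(j) {
        sample.int(nchar(refs$contaminants[[src[j]]]) - lens[j] + 1L, 1L)
      }, 0L)
      seqs <- substr(refs$contaminants[src], starts, starts + lens - 1L)
      logit("contaminant", "contaminant", "NA", seqs)
      inserts <- c(inserts, seqs)
    } else {
      src <- sample.int(length(refs$mrnas), n, replace = TRUE)
      lens <- sample(16:30, n, replace = TRUE)
      starts <- vapply(seq_len(n), function(j) {
        sample.int(nchar(refs$mrnas[[src[j]]]) - lens[j] + 1L, 1L)
      }, 0L)
      seqs <- substr(refs$mrnas[src], starts, starts + lens - 1L)
      logit("degradation", "degradation", "NA", seqs)
      inserts <- c(inserts, seqs)
    }
  }
  log <- if (length(log_rows)) do.call(rbind, log_rows) else
    data.frame(condition = character(), compartment = character(),
               class = character(), feature_id = character(),
               category = character(), sequence = character(),
               count = integer(), stringsAsFactors = FALSE)
  raw <- if (length(inserts)) {
    substr(paste0(inserts, cfg$adapter), 1L, cfg$read_len)
  } else character(0)
  list(raw_reads = raw, inserts = inserts, emission_log = log)
}

#' Simulate the full four-library experiment
#'
#' Generates the reference set, draws per-feature abundances and effects,
#' and simulates the four libraries Aag2-nucleus, Aag2-cytoplasm,
#' Pop-nucleus, Pop-cytoplasm. All randomness flows from `config$seed`.
#'
#' @param config a [sim_config()].
#' @return list with `config`, `refs`, `truth` (see [ground_truth()]),
#'   `libraries` (named list of per-library `raw_reads` vectors), and
#'   `emission_log` (aggregated per-sequence emission records across
#'   libraries).
#' @export
simulate_experiment <- function(config) {
  set.seed(config$seed)
  if (config$n_features == 0L && config$n_pirna == 0L) {
    stop("nothing to simulate: no miRNA features and no piRNA loci")
  }
  gen <- generate_reference_impl(config)
  refs <- gen$refs
  roles <- gen$roles
  pirna_roles <- assign_pirna_roles(config)
  base_abund <- stats::rlnorm(config$n_features, config$abundance_meanlog,
                              config$abundance_sdlog)
  nucleus_enrich <- stats::rlnorm(config$n_features, 0,
                                  config$nucleus_enrichment_sdlog)
  pirna_abund <- stats::rlnorm(config$n_pirna, config$abundance_meanlog,
                               config$abundance_sdlog)
  libs <- list()
  logs <- list()
  for (condition in c("Aag2", "Pop")) {
    for (compartment in c("nucleus", "cytoplasm")) {
      lib <- simulate_library_impl(config, refs, roles, pirna_roles,
                                   base_abund, nucleus_enrich, pirna_abund,
                                   condition, compartment)
      nm <- paste(condition, compartment, sep = "_")
      libs[[nm]] <- lib$raw_reads
      logs[[nm]] <- lib$emission_log
    }
  }
  emission_log <- do.call(rbind, logs)
  rownames(emission_log) <- NULL
  truth <- ground_truth(config, refs, roles, pirna_roles, base_abund,
                        nucleus_enrich, pirna_abund, emission_log)
  list(config = config, refs = refs, truth = truth, libraries = libs,
       emission_log = emission_log)
}

#' Assemble the ground-truth tables of a simulated experiment
#'
#' @param config the [sim_config()] used.
#' @param refs,roles,pirna_roles,base_abund,nucleus_enrich,pirna_abund
#'   internal generator state (as produced inside [simulate_experiment()]).
#' @param emission_log the aggregated emission log.
#' @return list with `features` (role table with per-library expected
#'   counts), `pirnas`, `isomir_rates` (configured category probabilities
#'   including the canonical remainder), `realized_counts` (per feature and
#'   library, from the log), and `library_totals`.
#' @export
ground_truth <- function(config, refs, roles, pirna_roles, base_abund,
                         nucleus_enrich, pirna_abund, emission_log) {
  lib_names <- c("Aag2_nucleus", "Aag2_cytoplasm", "Pop_nucleus",
                 "Pop_cytoplasm")
  feat <- roles
  feat$base_abundance <- base_abund
  feat$nucleus_enrichment <- nucleus_enrich
  for (nm in lib_names) {
    parts <- strsplit(nm, "_")[[1]]
    infected <- parts[1] == "Pop"
    compartment <- parts[2]
    pirna_frac <- if (compartment == "nucleus") config$pirna_fraction_nucleus
    else config$pirna_fraction_cytoplasm
    mirna_frac <- 1 - pirna_frac - config$contaminant_fraction -
      config$degradation_fraction
    w <- library_weights(base_abund, roles$true_lfc, roles$compartment,
                         infected, compartment, nucleus_enrich)
    feat[[paste0("expected_", nm)]] <- if (config$n_features && sum(w) > 0) {
      config$depth * mirna_frac * w / sum(w)
    } else rep(0, config$n_features)
  }
  pir <- pirna_roles
  pir$base_abundance <- pirna_abund
  if (nrow(emission_log)) {
    realized <- stats::aggregate(
      count ~ condition + compartment + class + feature_id,
      data = emission_log, FUN = sum)
    totals <- stats::aggregate(count ~ condition + compartment,
                               data = emission_log, FUN = sum)
  } else {
    realized <- emission_log[, c("condition", "compartment", "class",
                                 "feature_id", "count")]
    totals <- emission_log[, c("condition", "compartment", "count")]
  }
  rates <- c(config$isomir_rates,
             CANONICAL = 1 - sum(config$isomir_rates))
  list(features = feat, pirnas = pir, isomir_rates = rates,
       realized_counts = realized, library_totals = totals)
}

#' Write a simulated dataset to disk
#'
#' Emits the four FASTQ(.gz) libraries, the reference FASTA set with the
#' mature annotation table, and the ground-truth tables as TSV.
#'
#' @param config a [sim_config()].
#' @param dir output directory (created if needed).
#' @param gzip compress the FASTQ files (default TRUE).
#' @return the `simulate_experiment()` result, invisibly; file paths in
#'   attribute `paths`.
#' @export
simulate_dataset <- function(config, dir, gzip = TRUE) {
  sim <- simulate_experiment(config)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  for (nm in names(sim$libraries)) {
    reads <- sim$libraries[[nm]]
    fq <- file.path(dir, paste0(nm, if (gzip) ".fastq.gz" else ".fastq"))
    ids <- sprintf("%s_read%06d", nm, seq_along(reads))
    ss <- Biostrings::DNAStringSet(reads)
    names(ss) <- ids
    qual <- Biostrings::BStringSet(strrep("I", nchar(reads)))
    Biostrings::writeXStringSet(ss, fq, format = "fastq", compress = gzip,
                                qualities = qual)
    paths[[nm]] <- fq
  }
  refdir <- file.path(dir, "reference")
  write_reference(sim$refs, refdir)
  write_tsv(sim$truth$features, file.path(dir, "truth_features.tsv"))
  write_tsv(sim$truth$pirnas, file.path(dir, "truth_pirnas.tsv"))
  write_tsv(sim$truth$realized_counts, file.path(dir, "truth_realized_counts.tsv"))
  write_tsv(sim$emission_log, file.path(dir, "emission_log.tsv"))
  attr(sim, "paths") <- paths
  invisible(sim)
}
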