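test_that("seed index covers every k-mer position", {
  ref <- c(r1 = "ACGTACGTACGTACGTACGT")          # 20 nt
  idx <- build_index(ref, 17)
  expect_equal(length(ls(idx$env)), 4L)          # 20 - 17 + 1 distinct starts

  # two identical references: each seed maps to locations in both
  idx2 <- build_index(c(a = "ACGTACGTACGTACGTA", b = "ACGTACGTACGTACGTA"), 17)
  locs <- idx2$env[["ACGTACGTACGTACGTA"]]
  expect_setequal(vapply(locs, `[[`, "", "ref_id"), c("a", "b"))

  # reference shorter than the seed indexes nothing, with a warning
  expect_warning(idx3 <- build_index(c(s = "ACGT"), 17), "shorter than seed")
  expect_equal(length(ls(idx3$env)), 0L)

  expect_error(build_index(ref, 0), "seed_len")
  expect_error(aligner_config(seed_len = 0), "seed_len")
  expect_error(aligner_config(max_mismatches = -1), "max_mismatches")
})

test_that("align_read returns exact-seed hits with bounded mismatches", {
  ref <- c(r1 = "GGGGACGTACGTACGTACGTACGGGG")
  idx <- build_index(ref, 17)
  cfg <- aligner_config(17, 2)

  read <- substr(ref[[1]], 5, 24)                # exact 20-mer substring
  hits <- align_read(read, idx, cfg)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$ref_start, 4L)
  expect_equal(hits$ref_end, 24L)
  expect_equal(hits$n_mismatches, 0L)

  # 3 substitutions beyond the seed exceed the limit of 2
  read3 <- paste0(substr(read, 1, 17), "TTT")
  expect_equal(nrow(align_read(read3, idx, cfg)), 0L)

  # read shorter than the seed is reported unaligned with a reason
  short <- align_read("ACGTACGT", idx, cfg)
  expect_equal(nrow(short), 0L)
  expect_equal(attr(short, "reason"), "too_short_for_seed")

  # equal-mismatch tie across two references: both reported, ref_id order
  two <- c(a = "ACGTACGTACGTACGTACAT", b = "ACGTACGTACGTACGTACCT")
  idx2 <- build_index(two, 17)
  read_tie <- "ACGTACGTACGTACGTACGT"
  hits2 <- align_read(read_tie, idx2, cfg)
  expect_equal(hits2$ref_id, c("a", "b"))
  expect_equal(hits2$n_mismatches, c(1L, 1L))
  bh <- best_hits(hits2)
  expect_equal(bh$multimap, 2L)
})

test_that("best_hits keeps the minimal-mismatch subset", {
  h <- data.frame(ref_id = c("a", "b", "c"), n_mismatches = c(0L, 1L, 1L))
  expect_equal(best_hits(h)$multimap, 1L)
  expect_equal(best_hits(h)$hits$ref_id, "a")
  h2 <- h[2:3, ]
  expect_equal(best_hits(h2)$multimap, 2L)
  expect_equal(best_hits(h[0, ])$multimap, 0L)
})

test_that("align_read matches the brute-force Hamming oracle", {
  set.seed(101)
  for (case in 1:60) {
    n_refs <- sample(1:3, 1)
    refs <- stats::setNames(vapply(seq_len(n_refs), function(i) {
      rand_dna(sample(40:200, 1))
    }, ""), paste0("ref", seq_len(n_refs)))
    strands <- sample(c("forward", "both"), 1)
    seed_len <- sample(c(17L, 19L, 20L), 1)
    max_mm <- sample(0:2, 1)
    L <- sample(20:36, 1)
    # half planted (mutated substring), half random
    read <- if (case %% 2 == 0) {
      src <- refs[[sample(n_refs, 1)]]
      p <- sample(nchar(src) - L + 1L, 1)
      w <- substr(src, p, p + L - 1L)
      n_mut <- sample(0:3, 1)
      for (k in sample(L, n_mut)) {
        substr(w, k, k) <- sample(setdiff(c("A", "C", "G", "T"),
                                          substr(w, k, k)), 1)
      }
      w
    } else rand_dna(L)
    idx <- build_index(refs, seed_len, strands)
    got <- align_read(read, idx, aligner_config(seed_len, max_mm, strands))
    want <- oracle_align(read, refs, seed_len, max_mm, strands)
    expect_equal(got[, c("ref_id", "ref_start", "strand", "n_mismatches")],
                 want, ignore_attr = TRUE)
  }
})

test_that("seed and mismatch monotonicity hold", {
  set.seed(55)
  refs <- stats::setNames(replicate(2, rand_dna(120)), c("x", "y"))
  for (i in 1:25) {
    src <- refs[[sample(2, 1)]]
    p <- sample(nchar(src) - 24, 1)
    read <- substr(src, p, p + 23)
    for (k in sample(24, 2)) {
      substr(read, k, k) <- sample(c("A", "C", "G", "T"), 1)
    }
    key <- function(h) paste(h$ref_id, h$ref_start, h$strand)
    # increasing the seed never adds hits
    h17 <- align_read(read, build_index(refs, 17), aligner_config(17, 2))
    h20 <- align_read(read, build_index(refs, 20), aligner_config(20, 2))
    expect_true(all(key(h20) %in% key(h17)))
    # hits at m mismatches are a subset of hits at m + 1
    h_m1 <- align_read(read, build_index(refs, 17), aligner_config(17, 1))
    expect_true(all(key(h_m1) %in% key(h17)))
  }
})

test_that("hairpin scan alignment matches its exhaustive oracle", {
  set.seed(202)
  for (case in 1:40) {
    hairpins <- stats::setNames(
      vapply(1:2, function(i) rand_dna(sample(50:90, 1)), ""),
      c("hpA", "hpB"))
    L <- sample(16:30, 1)
    read <- if (case %% 2 == 0) {
      src <- hairpins[[sample(2, 1)]]
      p <- sample(nchar(src) - L + 1L, 1)
      w <- substr(src, p, p + L - 1L)
      for (k in sample(L, sample(0:3, 1))) {
        substr(w, k, k) <- sample(c("A", "C", "G", "T"), 1)
      }
      w
    } else rand_dna(L)
    got <- align_hairpins(read, hairpins)[[1]]
    want <- oracle_scan(read, hairpins)
    expect_equal(got, want, ignore_attr = TRUE)
  }
})
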