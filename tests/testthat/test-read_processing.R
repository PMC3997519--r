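adapter <- "TGGAATTCTCGGGTGCCAAGG"

test_that("adapter trimming finds the leftmost qualifying match", {
  insert <- "ACGTACGTACGTACGTAC"          # 18 nt
  raw <- substr(paste0(insert, adapter), 1, 36)
  tr <- trim_adapter(raw, adapter)
  expect_equal(tr$insert, insert)
  expect_equal(tr$status, "trimmed")

  # read with no adapter substring is discarded
  tr2 <- trim_adapter(strrep("AC", 18), adapter)
  expect_equal(tr2$status, "no_adapter")

  # adapter present with 1 mismatch in a 10 nt terminal overlap at the
  # rate limit 0.1; expected position derived by brute-force scanning all
  # start positions and counting mismatches
  insert3 <- "ACGTACGTACGTACGTACGTACGTAC"    # 26 nt
  ad10 <- paste0(substr(adapter, 1, 4), "A", substr(adapter, 6, 10))
  read3 <- paste0(insert3, ad10)             # 36 nt, mismatch at overlap pos 5
  brute <- function(read) {
    for (p in 1:(nchar(read) - 5)) {
      ovl <- min(nchar(adapter), nchar(read) - p + 1)
      if (ovl < 6) next
      mm <- oracle_char_mm(substr(read, p, p + ovl - 1), substr(adapter, 1, ovl))
      if (mm <= 0.1 * ovl) return(p)
    }
    NA_integer_
  }
  expect_equal(brute(read3), 27L)
  expect_equal(find_adapter(read3, adapter), 27L)
  expect_equal(trim_adapter(read3, adapter)$insert, insert3)

  # leftmost rule: a full adapter occurring twice trims at the first start
  double <- paste0("ACGT", adapter, adapter)
  expect_equal(find_adapter(double, adapter), 5L)
  # a partial internal adapter hit must extend to the read end to count:
  # the 8 nt prefix at position 5 is followed by non-adapter sequence, so
  # the match is the suffix-anchored one at position 17
  partial <- paste0("ACGT", substr(adapter, 1, 8), "ACGT", substr(adapter, 1, 8))
  expect_equal(find_adapter(partial, adapter), 17L)

  # vectorized agreement with per-read brute force on random reads
  set.seed(31)
  reads <- vapply(1:60, function(i) {
    ins <- rand_dna(sample(4:30, 1))
    substr(paste0(ins, adapter), 1, 36)
  }, "")
  expect_equal(find_adapter(reads, adapter),
               vapply(reads, brute, 1L, USE.NAMES = FALSE))
})

test_that("length filter boundary is inclusive at 16 nt", {
  expect_true(length_filter(strrep("A", 16)))
  expect_false(length_filter(strrep("A", 15)))
  expect_true(length_filter(strrep("A", 28)))
  expect_false(length_filter(strrep("A", 15), min_len = 16))
  expect_true(length_filter(strrep("A", 15), min_len = 15))
})

test_that("collapsing conserves counts and is order-independent", {
  out <- collapse_reads(c("ACGTACGTACGTACGTA", "ACGTACGTACGTACGTA",
                          "GTGTGTGTGTGTGTGTG"))
  expect_equal(sort(out$count), c(1L, 2L))
  expect_equal(sum(out$count), 3L)

  empty <- collapse_reads(character())
  expect_equal(nrow(empty), 0L)

  set.seed(7)
  pool <- replicate(20, rand_dna(18))
  reads <- sample(pool, 500, replace = TRUE)
  a <- collapse_reads(reads)
  b <- collapse_reads(rev(reads))
  cc <- collapse_reads(sample(reads))
  expect_identical(a, b)
  expect_identical(a, cc)
  expect_equal(sum(a$count), 500L)
})

test_that("process_reads conserves read accounting on FASTQ input", {
  dir <- withr::local_tempdir()
  fq <- file.path(dir, "lib.fastq")
  inserts <- c(rep("ACGTACGTACGTACGTAC", 3),      # kept (18 nt)
               rep("ACGTACGTACGTACG", 2),         # too short (15 nt)
               "ACGTACGTACGTACGTACGT")            # kept (20 nt)
  raws <- substr(paste0(inserts, adapter), 1, 36)
  raws <- c(raws, strrep("AC", 18))               # no adapter
  quals <- rep(strrep("I", 36), length(raws))
  quals[2] <- strrep("#", 36)                     # low quality (Phred 2)
  writeLines(as.vector(rbind(paste0("@r", seq_along(raws)), raws,
                             "+", quals)), fq)
  res <- process_reads(fq, adapter)
  acc <- res$accounting
  expect_equal(acc$raw, 7)
  expect_equal(acc$low_quality, 1)
  expect_equal(acc$no_adapter, 1)
  expect_equal(acc$too_short, 2)
  expect_equal(acc$kept, 3)
  expect_equal(acc$raw, acc$low_quality + acc$no_adapter + acc$too_short + acc$kept)
  expect_equal(sum(res$reads$count), acc$kept)
  expect_setequal(res$reads$sequence,
                  c("ACGTACGTACGTACGTAC", "ACGTACGTACGTACGTACGT"))

  # same input as plain sequences: no quality stage, conservation holds
  res2 <- process_reads(raws, adapter)
  expect_equal(res2$accounting$low_quality, 0)
  expect_equal(res2$accounting$raw,
               res2$accounting$no_adapter + res2$accounting$too_short +
                 res2$accounting$kept)
})

test_that("simulated library counts are conserved through cleaning", {
  cfg <- small_sim_config(n_features = 6L, n_pirna = 4L, depth = 1000, seed = 3L)
  sim <- simulate_experiment(cfg)
  res <- process_reads(sim$libraries$Aag2_nucleus, cfg$adapter)
  expect_equal(res$accounting$raw, 1000)
  expect_equal(sum(res$reads$count), res$accounting$kept)
  log <- sim$emission_log
  log <- log[log$condition == "Aag2" & log$compartment == "nucleus", ]
  expect_equal(sum(log$count), 1000)
})
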