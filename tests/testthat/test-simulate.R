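test_that("the generator is deterministic under a fixed seed", {
  cfg <- small_sim_config(n_features = 5L, n_pirna = 3L, depth = 500, seed = 1L)
  r1 <- generate_reference(cfg)
  r2 <- generate_reference(cfg)
  expect_identical(r1$hairpins, r2$hairpins)
  expect_identical(r1$matures, r2$matures)

  s1 <- simulate_experiment(cfg)
  s2 <- simulate_experiment(cfg)
  expect_identical(s1$libraries, s2$libraries)
  expect_identical(s1$emission_log, s2$emission_log)

  # byte-identical FASTQ on disk
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  simulate_dataset(cfg, d1, gzip = FALSE)
  simulate_dataset(cfg, d2, gzip = FALSE)
  for (f in list.files(d1, pattern = "fastq$")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }

  # a different seed changes the output
  s3 <- simulate_experiment(small_sim_config(n_features = 5L, n_pirna = 3L,
                                       depth = 500, seed = 2L))
  expect_false(identical(s1$libraries, s3$libraries))
})

test_that("degenerate configurations are handled", {
  empty_ref <- generate_reference(small_sim_config(n_features = 0L, seed = 4L))
  expect_equal(length(empty_ref$hairpins), 0L)
  expect_equal(nrow(validate_reference(empty_ref)), 0L)

  zero <- simulate_experiment(small_sim_config(n_features = 3L, n_pirna = 2L,
                                         depth = 0, seed = 4L))
  expect_true(all(lengths(zero$libraries) == 0L))

  expect_error(sim_config(isomir_rates = c(TRIM3 = 0.9, EXT3 = 0.3)), "sum")
  expect_error(sim_config(n_features = 3L, n_condition_up = 4L), "special")
})

test_that("zero modification rates emit only canonical mature inserts", {
  cfg <- small_sim_config(n_features = 5L, n_pirna = 0L, depth = 800,
                    contaminant_fraction = 0, degradation_fraction = 0,
                    pirna_fraction_nucleus = 0, pirna_fraction_cytoplasm = 0,
                    isomir_rates = c(TRIM3 = 0), seed = 6L)
  sim <- simulate_experiment(cfg)
  matures <- vapply(sim$refs$matures$mature_id,
                    function(m) mature_sequence(sim$refs, m), "")
  log <- sim$emission_log
  expect_true(all(log$category == "CANONICAL"))
  expect_true(all(log$sequence %in% matures))
})

test_that("emission logs reconcile with depth and declared roles", {
  cfg <- sim_config(n_features = 10L, n_pirna = 6L, depth = 2000, seed = 8L)
  sim <- simulate_experiment(cfg)
  log <- sim$emission_log
  per_lib <- tapply(log$count, paste(log$condition, log$compartment), sum)
  expect_true(all(per_lib == 2000))

  truth <- sim$truth$features
  # compartment-exclusive features have zero emissions in the other side
  for (i in seq_len(nrow(truth))) {
    sub <- log[log$feature_id == truth$feature_id[i], ]
    if (truth$compartment[i] == "nucleus") {
      expect_equal(sum(sub$count[sub$compartment == "cytoplasm"]), 0)
    }
    if (truth$compartment[i] == "cytoplasm") {
      expect_equal(sum(sub$count[sub$compartment == "nucleus"]), 0)
    }
    if (truth$role[i] == "infected_only") {
      expect_equal(sum(sub$count[sub$condition == "Aag2"]), 0)
    }
    if (truth$role[i] == "uninfected_only") {
      expect_equal(sum(sub$count[sub$condition == "Pop"]), 0)
    }
  }
  # the true fold-change table mirrors the configured effects
  expect_equal(sum(truth$true_lfc == cfg$condition_lfc), cfg$n_condition_up)
  expect_equal(sum(truth$true_lfc == -cfg$condition_lfc), cfg$n_condition_down)
  expect_equal(sum(is.infinite(truth$true_lfc)),
               cfg$n_infected_only + cfg$n_uninfected_only)
})

test_that("enforced mature separation prevents cross-assignment", {
  cfg <- small_sim_config(n_features = 8L, n_pirna = 0L, seed = 12L)
  refs <- generate_reference(cfg)
  scan_ref <- hairpin_scan_ref(refs$hairpins)
  for (i in seq_len(nrow(refs$matures))) {
    m <- refs$matures[i, ]
    read <- mature_sequence(refs, m$mature_id)
    hits <- align_hairpins(read, scan_ref, max_mismatches = 2L)[[1]]
    expect_equal(nrow(hits), 1L)
    expect_equal(hits$ref_id, m$hairpin_id)
    expect_equal(hits$ref_start, m$start)
    expect_equal(hits$n_mismatches, 0L)
  }
})

test_that("a configured condition effect is realized in expected counts", {
  cfg <- sim_config(depth = 1e4, seed = 14L)
  sim <- simulate_experiment(cfg)
  truth <- sim$truth$features
  up <- truth[truth$role == "cond_up", ][1, ]
  ratio <- up$expected_Pop_nucleus / up$expected_Aag2_nucleus
  # expected-count ratio equals the configured effect up to the shared
  # renormalization of the miRNA class (removed later by size factors)
  none <- truth[truth$role == "none", ][1, ]
  base_ratio <- none$expected_Pop_nucleus / none$expected_Aag2_nucleus
  expect_equal(log2(ratio / base_ratio), cfg$condition_lfc, tolerance = 1e-9)

  # realized counts are within 3 Poisson SE of expectation
  log <- sim$emission_log
  re <- sum(log$count[log$feature_id == up$feature_id &
                        log$condition == "Pop" & log$compartment == "nucleus"])
  expect_lt(abs(re - up$expected_Pop_nucleus),
            3 * sqrt(up$expected_Pop_nucleus) + 1)
})
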