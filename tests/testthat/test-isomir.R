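# toy hairpin "GGGGACGTACGTACGTCCCC", mature [4,16) = "ACGTACGTACGT"

classify_toy <- function(read, align_start) {
  classify_isomir(read, toy_hairpin, toy_mature_start, toy_mature_end,
                  align_start)
}

test_that("each worked example returns its forced category", {
  expect_equal(classify_toy("ACGTACGTACGT", 4)$category, "CANONICAL")
  # starts after the mature start, ends at the same position
  expect_equal(classify_toy("GTACGTACGT", 6)$category, "TRIM5")
  # overhang "CC" equals the hairpin continuation at [16,18)
  expect_equal(classify_toy("ACGTACGTACGTCC", 4)$category, "EXT3")
  # overhang "TT" differs from the continuation
  expect_equal(classify_toy("ACGTACGTACGTTT", 4)$category, "ADD3")
  # same span with one internal substitution, at offset 3 (0-based)
  call <- classify_toy("ACGAACGTACGT", 4)
  expect_equal(call$category, "SUBST")
  expect_match(call$detail, "mm_at=4")        # 1-based read position
  # starts before the mature start, ends at the same position
  expect_equal(classify_toy("GGACGTACGTACGT", 2)$category, "EXT5")
  # shorter at the 3' end, same start
  expect_equal(classify_toy("ACGTACGTAC", 4)$category, "TRIM3")
})

test_that("boundary and mixed cases follow the category definitions", {
  # a single-base 3' elongation is OTHER, not EXT3/ADD3
  one <- classify_toy("ACGTACGTACGTC", 4)
  expect_equal(one$category, "OTHER")
  expect_match(one$detail, "elong1")

  # mixed overhang (first base templated, second not) counts as ADD3
  mixed <- classify_toy("ACGTACGTACGTCA", 4)
  expect_equal(mixed$category, "ADD3")

  # read running past the hairpin's 3' terminus cannot be fully templated
  past <- classify_isomir("ACGTACGTACGTCCCCAA", toy_hairpin, 4, 16, 4)
  expect_equal(past$category, "ADD3")
  # ... but a fully-templated overhang reaching exactly the terminus is EXT3
  templ <- classify_isomir("ACGTACGTACGTCCCC", toy_hairpin, 4, 16, 4)
  expect_equal(templ$category, "EXT3")

  # TRIM5 with an internal mismatch stays TRIM5; the mismatch is detail
  t5mm <- classify_toy("GTACGTACCT", 6)
  expect_equal(t5mm$category, "TRIM5")
  expect_match(t5mm$detail, "internal_mm")

  # combined 5' and 3' changes fall through to OTHER
  expect_equal(classify_toy("GTACGTAC", 6)$category, "OTHER")

  # no overlap with the mature span is a contract violation
  expect_error(classify_isomir("GGGG", toy_hairpin, 4, 16, 0),
               "does not overlap")
})

test_that("classification agrees with the brute-force oracle", {
  set.seed(17)
  for (case in 1:200) {
    hlen <- sample(40:60, 1)
    hp <- rand_dna(hlen)
    mlen <- sample(18:22, 1)
    mstart <- sample(4:(hlen - mlen - 4), 1)          # 0-based
    mend <- mstart + mlen
    mature <- substr(hp, mstart + 1, mend)
    # random placement and edit around the mature
    s <- mstart + sample(-3:3, 1)
    e <- mend + sample(-3:3, 1)
    read <- substr(hp, s + 1, e)
    n_mut <- sample(0:2, 1)
    for (k in sample(nchar(read), n_mut)) {
      substr(read, k, k) <- sample(c("A", "C", "G", "T"), 1)
    }
    if (max(s, mstart) >= min(e, mend)) next
    got <- classify_isomir(read, hp, mstart, mend, s)
    expect_equal(got$category, oracle_isomir(read, hp, mstart, mend, s),
                 info = paste("case", case))
  }
})

test_that("isomiR summary tallies counts and fractions per library", {
  calls <- data.frame(
    library = "lib1",
    category = c("CANONICAL", "TRIM3", "EXT3"),
    count = c(5, 3, 2))
  s <- isomir_summary(calls)
  s1 <- s[s$library == "lib1", ]
  expect_equal(s1$reads[s1$category == "CANONICAL"], 5)
  expect_equal(s1$fraction[s1$category == "CANONICAL"], 0.5)
  expect_equal(s1$fraction[s1$category == "TRIM3"], 0.3)
  expect_equal(s1$fraction[s1$category == "EXT3"], 0.2)
  expect_equal(sum(s1$fraction), 1)

  empty <- isomir_summary(data.frame(library = character(),
                                     category = character(),
                                     count = numeric()))
  expect_equal(nrow(empty), 0L)
})

test_that("simulated EXT3 rate is recovered within 3 binomial SE", {
  cfg <- small_sim_config(n_features = 8L, n_pirna = 0L, depth = 5000,
                    contaminant_fraction = 0, degradation_fraction = 0,
                    pirna_fraction_nucleus = 0, pirna_fraction_cytoplasm = 0,
                    isomir_rates = c(EXT3 = 0.2), seed = 9L)
  sim <- simulate_experiment(cfg)
  res <- run_pipeline(sim$libraries["Aag2_nucleus"], sim$refs,
                      adapter = cfg$adapter)
  s <- res$isomir_summary
  obs <- s$fraction[s$library == "Aag2_nucleus" & s$category == "EXT3"]
  n <- sum(s$reads[s$library == "Aag2_nucleus"])
  se <- sqrt(0.2 * 0.8 / n)
  expect_lt(abs(obs - 0.2), 3 * se)
})
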