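test_that("log2 fold change and signed fold reproduce published rows", {
  # miRNA table rows (printed to 2 decimals)
  expect_equal(round(log2_fold_change(56.84, 602.34), 2), 3.41)
  expect_equal(round(signed_fold(56.84, 602.34), 2), 10.60)
  expect_equal(round(signed_fold(1721.87, 814.69), 2), -2.11)
  expect_equal(round(log2_fold_change(1721.87, 814.69), 2), -1.08)
  # piRNA table rows (printed to 9 decimals)
  expect_lt(abs(log2_fold_change(0.042309408, 1.322475452) - 4.966118624), 1e-6)
  expect_equal(log2_fold_change(0, 12.22396229), Inf)
  expect_equal(log2_fold_change(1.057735207, 0), -Inf)
})

test_that("zero conventions and algebraic identities hold", {
  expect_true(is.na(log2_fold_change(0, 0)))
  expect_true(is.na(signed_fold(0, 0)))
  expect_equal(signed_fold(0, 3), Inf)
  expect_equal(signed_fold(3, 0), -Inf)
  expect_equal(signed_fold(5, 5), 1)
  expect_error(log2_fold_change(-1, 2), "non-negative")

  set.seed(3)
  a <- rlnorm(50); b <- rlnorm(50)
  expect_equal(log2_fold_change(a, a), rep(0, 50))
  # antisymmetry
  expect_equal(log2_fold_change(a, b), -log2_fold_change(b, a))
  # sign agreement between the two fold conventions:
  # log2fc > 0 iff fold > 1, log2fc < 0 iff fold < -1 (fold is never in (-1, 1))
  lfc <- log2_fold_change(a, b)
  sf <- signed_fold(a, b)
  expect_equal(lfc > 0, sf > 1)
  expect_equal(lfc < 0, sf < -1)
  expect_true(all(abs(sf) >= 1))
})

test_that("de_table filters, orders and places infinities correctly", {
  norm <- matrix(c(4, 2, 8, 0, 5,
                   16, 2 * 2^0.5, 1, 3, 0), ncol = 2,
                 dimnames = list(c("f_up2", "f_half", "f_down3", "f_new", "f_off"),
                                 c("A", "B")))
  tab <- de_table(norm, c("A", "B"), log2_threshold = 1)
  expect_equal(tab$feature, c("f_new", "f_up2", "f_down3", "f_off"))
  expect_equal(tab$log2fc[1], Inf)
  expect_equal(tab$log2fc[4], -Inf)
  expect_equal(tab$log2fc[2], 2)
  expect_false("f_half" %in% tab$feature)

  # raising the threshold never adds rows
  for (thr in c(0.5, 1, 2, 3.5)) {
    t_lo <- de_table(norm, c("A", "B"), log2_threshold = thr)
    t_hi <- de_table(norm, c("A", "B"), log2_threshold = thr + 0.5)
    expect_true(all(t_hi$feature %in% t_lo$feature))
  }
  expect_equal(nrow(de_table(norm[c("f_half"), , drop = FALSE], c("A", "B"))), 0L)
  expect_error(de_table(norm, c("A", "nope")), "pair")
})

test_that("published tables are reproduced from their value columns", {
  for (comp in c("nucleus", "cytoplasm")) {
    mir <- published_fold_changes("mirna", comp)
    redone <- fold_change_table(mir[, c("feature", "aag2", "pop")],
                                cols = c("aag2", "pop"))
    # half a printed unit plus propagated input rounding (the published
    # columns were computed from unrounded normalized values)
    expect_true(all(abs(redone$log2fc - mir$log2fc) <= 0.006))
    expect_true(all(abs(redone$fold - mir$fold) <= 0.015))

    pir <- published_fold_changes("pirna", comp)
    redone_p <- fold_change_table(pir[, c("feature", "aag2", "pop")],
                                  cols = c("aag2", "pop"))
    fin <- is.finite(pir$log2fc)
    expect_true(all(abs(redone_p$log2fc[fin] - pir$log2fc[fin]) <= 1e-6))
    expect_identical(redone_p$log2fc[!fin], pir$log2fc[!fin])
  }
})

test_that("fold_change_table flags malformed numbers with the row id", {
  bad <- data.frame(feature = c("ok", "broken"), a = c("1.5", "oops"),
                    b = c("2", "3"))
  expect_error(fold_change_table(bad, cols = c("a", "b")), "broken")
  one <- fold_change_table(data.frame(feature = "solo", a = 2, b = 8),
                           cols = c("a", "b"))
  expect_equal(one$log2fc, 2)
})

test_that("infinities render as glyphs in reports, literals in TSV", {
  expect_equal(format_fold(c(Inf, -Inf, 1.234)), c("∞", "−∞", "1.23"))
  dir <- withr::local_tempdir()
  p <- file.path(dir, "x.tsv")
  write_tsv(data.frame(v = c(Inf, -Inf, 2)), p)
  expect_equal(readLines(p)[-1], c("inf", "-inf", "2"))
  expect_equal(read_tsv <- sRNAshuttle:::read_tsv(p)$v, c(Inf, -Inf, 2))
})
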