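test_that("single-offset scores match the stated convention and the brute-force oracle", {
  expect_equal(alignment_cs("K", "D", 0)$cs, 1)
  expect_equal(alignment_cs("D", "K", 0)$cs, 1)
  expect_equal(alignment_cs("G", "G", 0)$cs, 0)
  expect_equal(alignment_cs("KK", "DD", 0)$cs, 3)   # two direct + two diagonal
  expect_equal(alignment_cs("KK", "KK", 0)$cs, -3)  # same-sign mirror
  expect_equal(alignment_cs("GGG", "AGA", 0)$cs, 0)

  set.seed(11)
  for (rep in 1:25) {
    cdr3 <- rand_aa(sample(5:12, 1), charged_boost = 2)
    antigen <- rand_aa(sample(12:30, 1), charged_boost = 2)
    o <- sample(0:(nchar(antigen) - nchar(cdr3)), 1)
    for (mode in c("electrostatic", "combo")) {
      expect_equal(alignment_cs(cdr3, antigen, o, mode)$cs,
                   naive_alignment_cs(cdr3, antigen, o, mode),
                   tolerance = 1e-12)
    }
  }
})

test_that("alignment window coordinates and offset bounds are honored", {
  h <- alignment_cs("KK", "GGKKGG", 2)
  expect_equal(h$window_start, 2)
  expect_equal(h$window_end, 4)
  expect_error(alignment_cs("KK", "GGKKGG", 5), "out of range")
  expect_error(alignment_cs("KK", "GGKKGG", -1), "out of range")
  expect_error(alignment_cs("KK", "GGKKGG", 0, mode = "magnetic"))
})

test_that("sliding max finds the best window with smallest-offset tie-breaking", {
  h <- sliding_max_cs("KK", "GGGDDGGG")
  expect_equal(h$cs, 3)
  expect_equal(h$offset, 3)
  expect_equal(c(h$window_start, h$window_end), c(3, 5))
  # uncharged everywhere: every offset ties at 0, first offset returned
  flat <- sliding_max_cs("GGG", "AAAAGGGAAAA")
  expect_equal(flat$cs, 0)
  expect_equal(flat$offset, 0)
})

test_that("sliding max equals exhaustive enumeration on random instances in both modes", {
  set.seed(23)
  for (rep in 1:40) {
    cdr3 <- rand_aa(sample(8:24, 1), charged_boost = 1.5)
    antigen <- rand_aa(sample(25:80, 1), charged_boost = 1.5)
    mode <- sample(c("electrostatic", "combo"), 1)
    got <- sliding_max_cs(cdr3, antigen, mode)
    want <- naive_sliding_max(cdr3, antigen, mode)
    expect_equal(got$cs, want$cs, tolerance = 1e-10)
    expect_equal(got$offset, want$offset)
  }
})

test_that("scoring algebra: symmetry, charge-neutral null, combo reduces to electrostatic at lambda 0", {
  set.seed(31)
  for (rep in 1:20) {
    a <- rand_aa(10, charged_boost = 2)
    b <- rand_aa(10, charged_boost = 2)
    expect_equal(alignment_cs(a, b, 0)$cs, alignment_cs(b, a, 0)$cs,
                 tolerance = 1e-12)
  }
  # no charged residues in the CDR3 -> electrostatic score exactly 0
  neutral <- "GASTLVGY"
  for (rep in 1:10) {
    antigen <- rand_aa(30, charged_boost = 3)
    expect_identical(sliding_max_cs(neutral, antigen)$cs, 0)
  }
  p0 <- scoring_params(lambda = 0)
  for (rep in 1:10) {
    cdr3 <- rand_aa(9, 1)
    antigen <- rand_aa(40, 1)
    expect_equal(sliding_max_cs(cdr3, antigen, "combo", params = p0)$cs,
                 sliding_max_cs(cdr3, antigen, "electrostatic")$cs,
                 tolerance = 1e-12)
  }
})

test_that("an opposite-charge substitution at an isolated aligned position adds exactly w0", {
  antigen <- "GGGGDGGGG"   # single charge, uncharged neighbors
  before <- alignment_cs("GGG", antigen, 3)$cs   # center aligns with D
  after <- alignment_cs("GKG", antigen, 3)$cs
  expect_equal(after - before, 1)                # w0 * 1
  p <- scoring_params(w0 = 2, w1 = 0.5)
  expect_equal(alignment_cs("GKG", antigen, 3, params = p)$cs -
                 alignment_cs("GGG", antigen, 3, params = p)$cs, 2)
})

test_that("roles swap when the CDR3 is longer than the antigen", {
  long_cdr3 <- "GGGGGKKGGGGG"        # 12 AA
  short_ant <- "DDG"                 # 3 AA antigen
  h <- sliding_max_cs(long_cdr3, short_ant)
  expect_equal(h$cs, naive_sliding_max(long_cdr3, short_ant)$cs)
  expect_true(h$swapped)
  expect_equal(c(h$window_start, h$window_end), c(0, 3))  # whole antigen
})

test_that("normalized scores divide by CDR3 length", {
  p <- scoring_params(normalize = TRUE)
  expect_equal(alignment_cs("KK", "DD", 0, params = p)$cs, 1.5)
})

test_that("score_cases aggregates per case with lexicographic tie-breaks and drops bad records", {
  recs <- data.frame(
    case_id = c("c1", "c1", "c2", "c3", "c3"),
    chain = c("TRA", "TRB", "TRA", "TRB", "TRA"),
    cdr3_aa = c("KKGGG", "GGGGG", "KKGGG", "GGGGG", "GGGGG"),
    stringsAsFactors = FALSE)
  sc <- score_cases(recs, "DDGGGGG")  # KK over DD: 2 direct + 2 diagonal = 3
  expect_equal(nrow(sc), 3)
  expect_equal(sc$max_cs[sc$case_id == "c1"], 3)
  expect_equal(sc$best_cdr3[sc$case_id == "c1"], "KKGGG")
  expect_equal(sc$n_cdr3[sc$case_id == "c1"], 2)
  # single-CDR3 case equals its own sliding max
  expect_equal(sc$max_cs[sc$case_id == "c2"],
               sliding_max_cs("KKGGG", "DDGGGGG")$cs)
  # all-tie case records the lexicographically smallest CDR3
  tie <- data.frame(case_id = "t", chain = c("TRA", "TRB"),
                    cdr3_aa = c("GGGGT", "GGGGA"), stringsAsFactors = FALSE)
  expect_equal(score_cases(tie, "AAAAAAAA")$best_cdr3, "GGGGA")
})

test_that("score_cases is invariant to row order and to duplicate CDR3s", {
  set.seed(47)
  recs <- data.frame(
    case_id = rep(sprintf("c%02d", 1:6), each = 4),
    chain = sample(c("TRA", "TRB"), 24, replace = TRUE),
    cdr3_aa = replicate(24, rand_aa(sample(8:14, 1), 2)),
    stringsAsFactors = FALSE)
  antigen <- rand_aa(50, 2)
  base <- score_cases(recs, antigen)
  shuf <- score_cases(recs[sample(nrow(recs)), ], antigen)
  expect_equal(base, shuf)
  dup <- score_cases(rbind(recs, recs[1, ]), antigen)
  expect_equal(dup$max_cs, base$max_cs)
})

test_that("score_cases validates input and warns on dropped records", {
  expect_error(score_cases(data.frame(case_id = character(0),
                                      chain = character(0),
                                      cdr3_aa = character(0)),
                           "GGGGGGGG"), "empty")
  bad <- data.frame(case_id = c("a", "a"), chain = c("TRA", "TRG"),
                    cdr3_aa = c("CAXSL", "KKKKK"), stringsAsFactors = FALSE)
  expect_warning(expect_error(score_cases(bad, "GGGGGGGG"), "no valid"),
                 "dropped 2")
})

test_that("dichotomize sends ties at the cut to the lower group", {
  sc <- function(x) data.frame(case_id = paste0("c", seq_along(x)), max_cs = x)
  d <- dichotomize(sc(c(1, 2, 3, 4)))
  expect_setequal(d$upper, c("c3", "c4"))
  expect_setequal(d$lower, c("c1", "c2"))
  d2 <- dichotomize(sc(c(1, 2, 2, 9)))
  expect_setequal(d2$upper, "c4")          # both 2s fall lower
  expect_setequal(d2$lower, c("c1", "c2", "c3"))
  expect_warning(d3 <- dichotomize(sc(c(5, 5, 5))), "identical")
  expect_length(d3$upper, 0)
  expect_true(d3$degenerate)
  expect_length(d3$lower, 3)
  expect_error(dichotomize(sc(7)), "at least 2")
  # partition is exhaustive
  set.seed(5)
  x <- rnorm(31)
  d4 <- dichotomize(sc(x), percentile = 70)
  expect_equal(length(d4$upper) + length(d4$lower), 31)
})
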