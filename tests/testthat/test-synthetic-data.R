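test_that("a fully conserved profile yields identical rows; seeds reproduce", {
  msa <- generateMsa(12, 30, conservation = rep(1, 30), seed = 3)
  seqs <- alignedSequences(msa)
  expect_true(all(seqs == seqs[["wildtype"]]))

  a <- generateMsa(25, 40, truth = fixture_truth(), seed = 9)
  b <- generateMsa(25, 40, truth = fixture_truth(), seed = 9)
  expect_identical(sequenceMatrix(a), sequenceMatrix(b))
  c <- generateMsa(25, 40, truth = fixture_truth(), seed = 10)
  expect_false(identical(sequenceMatrix(a), sequenceMatrix(c)))

  expect_error(generateMsa(1, 30), "at least 2")
  expect_error(generateMsa(10, 5), "at least 10")
})

test_that("mean pairwise identity tracks the brute-force column expectation", {
  # independent oracle: replay the generative column process symbolically
  # (consensus vs clade-profile vs residual alternates) 10,000 times and
  # average the match indicator for a random pair of sequences
  oracle_expected_identity <- function(profile, n_clades = 6, div = 0.6,
                                       n_draws = 10000) {
    set.seed(99)
    hits <- 0
    for (i in seq_len(n_draws)) {
      c <- sample(profile, 1)
      k1 <- sample.int(n_clades, 1); k2 <- sample.int(n_clades, 1)
      draw_profile <- function(k) {
        if (k == 1 || runif(1) >= (1 - c) * div) "cons"
        else paste0("alt", sample.int(3, 1))
      }
      p1 <- draw_profile(k1)
      p2 <- if (k2 == k1) p1 else draw_profile(k2)
      s1 <- if (runif(1) < c) p1 else paste0("alt", sample.int(3, 1))
      s2 <- if (runif(1) < c) p2 else paste0("alt", sample.int(3, 1))
      hits <- hits + (s1 == s2)
    }
    hits / n_draws
  }

  profile <- defaultConservation(120)
  expected <- oracle_expected_identity(profile)

  msa <- generateMsa(200, 120, seed = 13)
  m <- sequenceMatrix(msa)[-1, ]  # pairwise identity over the ortholog rows
  n <- nrow(m)
  match_pairs <- 0
  for (j in seq_len(ncol(m))) {
    tab <- table(m[, j])
    match_pairs <- match_pairs + sum(tab * (tab - 1) / 2)
  }
  observed <- match_pairs / (n * (n - 1) / 2) / ncol(m)
  expect_lt(abs(observed - expected), 0.05)
})

test_that("true tmax is additive over stabilized key positions", {
  truth <- groundTruth(key_positions = c(5L, 10L, 15L), stabilizing_residue = "G",
                      base_tmax = 30, delta_tmax = 6)
  wt <- strrep("A", 20)
  expect_equal(trueTmax(wt, truth), 30)
  one <- paste0(strrep("A", 4), "G", strrep("A", 15))
  expect_equal(trueTmax(one, truth), 36)
  all3 <- paste0("AAAAG", "AAAAG", "AAAAG", "AAAAA")
  expect_equal(trueTmax(all3, truth), 30 + 3 * 6)
  expect_error(trueTmax("AAA", truth), "width")

  # trade-off: activity shrinks multiplicatively per substitution
  expect_equal(trueActivityScale(all3, truth), truth@activityScale^3)
})

test_that("ground truth validity catches bad configurations", {
  expect_error(groundTruth(key_positions = c(3L, 3L)), "distinct")
  expect_error(groundTruth(activity_scale = 0), "activityScale")
  expect_error(groundTruth(base_tmax = 38, delta_tmax = 100), "ladder")
})

test_that("noiseless traces are flat when killed, decaying when active", {
  truth <- fixture_truth_clean()
  wt <- paste0(strrep("A", 24), "P", strrep("A", 15))  # tmax 38

  dead <- simulateTrace(wt, 46, truth, seed = 2)
  expect_true(all(dead$a340 == dead$a340[1]))

  alive <- simulateTrace(wt, 38, truth, seed = 2)
  expect_true(all(diff(alive$a340) < 0))

  # fitted initial slope equals the configured decay rate analytically
  expect_equal(fitRate(alive), -0.01, tolerance = 1e-9)
  stab <- paste0(strrep("A", 24), "G", strrep("A", 15))  # tmax 46, scaled
  tr <- simulateTrace(stab, 42, truth, seed = 2)
  expect_equal(fitRate(tr), -0.01 * truth@activityScale, tolerance = 1e-9)

  # determinism of the noisy path
  noisy <- fixture_truth()
  t1 <- simulateTrace(wt, "RT", noisy, seed = 77)
  t2 <- simulateTrace(wt, "RT", noisy, seed = 77)
  expect_identical(t1, t2)

  expect_error(simulateTrace(wt, 38, truth, duration = 0), "duration")
  expect_error(simulateTrace(wt, 38, truth, n_points = 2), "timepoints")
})

test_that("noiseless slope sign equals the survival indicator on 1,000 pairs", {
  truth <- fixture_truth_clean()
  set.seed(31)
  ladder <- c(rcaRoomTemp(), rcaLadder())
  aa <- setdiff(rcaAlphabet(), "-")
  for (i in seq_len(1000)) {
    chars <- sample(aa, 30, replace = TRUE)
    chars[25] <- sample(c("P", "G"), 1)
    s <- paste(chars, collapse = "")
    shock <- sample(ladder, 1)
    tr <- simulateTrace(s, shock, truth, n_points = 5, seed = i)
    slope <- fitRate(tr)
    survives <- shock <= trueTmax(s, truth)
    # sign at floating precision: a dead well is flat up to round-off
    if (survives) expect_lt(slope, -1e-6) else expect_lt(abs(slope), 1e-12)
  }
})

test_that("alignment and trace files round-trip", {
  msa <- fixture_msa_small()
  fa <- tempfile(fileext = ".fasta")
  writeAlignedFasta(msa, fa)
  back <- readAlignedFasta(fa, wildtype_id = "wildtype")
  expect_identical(sequenceMatrix(back), sequenceMatrix(msa))

  tr <- simulateTrace(wildtypeSequence(msa), "RT", fixture_truth(), seed = 4)
  csv <- tempfile(fileext = ".csv")
  writeTraceCsv(tr, csv)
  back_tr <- readTraceCsv(csv)
  expect_equal(back_tr$a340, tr$a340)
  expect_identical(names(back_tr),
                   c("well_id", "sequence_id", "shock_temp_C", "time_min", "a340"))
})
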