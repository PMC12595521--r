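test_that("percent identity on equal-length pairs matches positional counting", {
  expect_equal(percentIdentity("ACDE", "ACDE"), 1.0)
  expect_equal(percentIdentity("ACDE", "ACDF"), 0.75)
  expect_error(percentIdentity("", "ACDE"), "non-empty")

  # independent position-by-position oracle on random length-100 pairs
  set.seed(21)
  aa <- setdiff(rcaAlphabet(), "-")
  for (i in 1:30) {
    a <- paste(sample(aa, 100, replace = TRUE), collapse = "")
    b <- paste(sample(aa, 100, replace = TRUE), collapse = "")
    want <- oracle_hamming(a, b)
    expect_equal(percentIdentity(a, b), (100 - want) / 100)
    expect_equal(percentIdentity(a, b), percentIdentity(b, a))
  }
})

test_that("percent identity of unequal lengths uses the global alignment", {
  # a perfect prefix: 40 of 50 positions match an alignment of width 50
  ref <- paste(rep(c("A", "C", "D", "E", "F"), 10), collapse = "")
  short <- substr(ref, 1, 40)
  expect_equal(percentIdentity(short, ref), 40 / 50)
  expect_equal(percentIdentity(short, ref, method = "shorter"), 1.0)
})

test_that("candidate filtering applies both rules, preserves order, idempotent", {
  ref <- paste(rep("ACDEFGHIKL", 15), collapse = "")  # 150-mer
  # toy set with hand-known identities and lengths
  recs <- sequenceRecords(
    id = sprintf("r%02d", 1:6),
    residues = c(
      ref,                                  # identical, long -> keep
      substr(ref, 1, 139),                  # too short -> reject (length)
      paste(rep("W", 150), collapse = ""),  # 0% identity -> reject (identity)
      chartr("A", "V", ref),                # 90% identity -> keep
      substr(ref, 1, 140),                  # boundary length -> keep
      paste(rep("WY", 75), collapse = "")   # 0% identity -> reject
    ))
  out <- filterCandidates(recs, ref, quiet = TRUE)
  expect_identical(out$id, c("r01", "r04", "r05"))
  rep_tab <- attr(out, "report")
  expect_identical(rep_tab$reason[rep_tab$id == "r02"], "length")
  expect_identical(rep_tab$reason[rep_tab$id == "r03"], "identity")

  # brute-force check of every predicate on the toy set
  want <- recs$id[nchar(recs$residues) >= 140 &
                  vapply(recs$residues, percentIdentity, numeric(1), b = ref) > 0.2]
  expect_identical(out$id, want)

  # idempotence
  again <- filterCandidates(out, ref, quiet = TRUE)
  expect_identical(again$id, out$id)
})

test_that("cTP stripping slices the mature protein and round-trips", {
  prec <- paste(c(rep("M", 50), rep("ACDEFGHIKL", 35)), collapse = "")  # 400-mer
  recs <- sequenceRecords("p1", prec, ctp_length = 50L)
  mat <- stripCtp(recs)
  expect_equal(nchar(mat$residues), 350)
  expect_identical(mat$residues, substr(prec, 51, 400))
  expect_equal(mat$mature_offset, 50L)
  # inverse: cTP + mature reproduces the precursor
  expect_identical(paste0(mat$ctp_residues, mat$residues), prec)

  # ctp_length = 0 leaves the sequence unchanged
  r0 <- stripCtp(sequenceRecords("p2", prec, ctp_length = 0L))
  expect_identical(r0$residues, prec)

  # missing prediction is an error
  expect_error(stripCtp(sequenceRecords("p3", prec)), "prediction required")
})

test_that("heuristic cTP stub flags everything before the anchor motif", {
  mature <- "ACDEFGHIKLMNPQRSTVWY"
  recs <- sequenceRecords(c("a", "b"),
                          c(paste0(strrep("M", 30), mature),
                            mature))
  out <- predictCtp(recs, reference = mature)
  expect_equal(out$ctp_length, c(30L, 0L))
})

test_that("alignment trimming drops gappy columns then gappy rows", {
  msa <- alignedSet(c(wt = "AC-D", a = "AC-D", b = "A--D"), wildtype_id = "wt")
  # permissive limits leave the input unchanged
  same <- trimAlignment(msa, 1.0, 1.0)
  expect_identical(sequenceMatrix(same), sequenceMatrix(msa))
  # the all-gap column is removed at (0.5, 0.9); all rows survive
  trimmed <- trimAlignment(msa, 0.5, 0.9)
  expect_equal(alignmentWidth(trimmed), 3)
  expect_equal(length(alignmentIds(trimmed)), 3)
  expect_identical(alignedSequences(trimmed)[["wt"]], "ACD")
})

test_that("trimming matches a brute-force two-pass filter on random MSAs", {
  set.seed(5)
  for (i in 1:40) {
    n <- sample(4:10, 1); L <- sample(8:20, 1)
    m <- random_msa(n, L)
    rownames(m)[1] <- "wt"
    m[1, ] <- sample(setdiff(rcaAlphabet(), "-"), L, replace = TRUE)
    msa <- alignedSet(m, wildtype_id = "wt")
    cg <- runif(1); rg <- runif(1)
    got <- trimAlignment(msa, cg, rg)
    # independent recount
    keep_c <- colMeans(m == "-") <= cg
    m2 <- m[, keep_c, drop = FALSE]
    keep_r <- rowMeans(m2 == "-") <= rg | rownames(m2) == "wt"
    expect_identical(sequenceMatrix(got), m2[keep_r, , drop = FALSE])
    # never grows, preserves order, keeps the wildtype
    expect_lte(alignmentWidth(got), L)
    expect_true("wt" %in% alignmentIds(got))
    expect_identical(alignmentIds(got),
                     rownames(m)[rownames(m) %in% alignmentIds(got)])
  }
})
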