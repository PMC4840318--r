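test_that("weighted Levenshtein matches worked cases", {
  expect_equal(weightedLevenshtein("CARDYW", "CARDYW"), 0)
  expect_equal(weightedLevenshtein("CARDYW", "CARDGYW"), 2)  # 1 indel x 2
  expect_equal(weightedLevenshtein("CARDYW", "CARDFW"), 1)   # 1 substitution
  expect_equal(weightedLevenshtein("AB", ""), 4)             # 2 deletions x 2
  expect_equal(weightedLevenshtein("", ""), 0)
})

test_that("weighted Levenshtein equals the recursive oracle exhaustively on short strings", {
  strs <- allStrings(2)  # all 4-letter-alphabet strings up to length 2
  for (a in strs) for (b in strs) {
    expect_equal(weightedLevenshtein(a, b), oracleWlev(a, b))
  }
})

test_that("weighted Levenshtein equals the recursive oracle on sampled pairs up to length 6", {
  set.seed(421)
  for (i in 1:400) {
    a <- randomString(sample(0:6, 1))
    b <- randomString(sample(0:6, 1))
    d <- weightedLevenshtein(a, b)
    expect_equal(d, oracleWlev(a, b))
    expect_equal(d, weightedLevenshtein(b, a))  # symmetry
    if (a == b) expect_equal(d, 0) else expect_gt(d, 0)
  }
})

test_that("weighted Levenshtein agrees with adist under weighted costs", {
  set.seed(99)
  for (i in 1:200) {
    a <- randomString(sample(0:12, 1))
    b <- randomString(sample(0:12, 1))
    ref <- as.numeric(utils::adist(
      a, b, costs = list(insertions = 2, deletions = 2,
                         substitutions = 1)))
    expect_equal(weightedLevenshtein(a, b), ref)
  }
})

test_that("gapless distance is forced for equal lengths and bounds the gapped one", {
  expect_equal(gaplessDistance("ABCDEF", "ABCDEF"), 0)
  # rotation: gapless 6, gapped alignment would give a deceptive 4
  expect_equal(gaplessDistance("ABCDEF", "BCDEFA"), 6)
  expect_equal(weightedLevenshtein("ABCDEF", "BCDEFA"), 4)
  expect_error(gaplessDistance("AB", "ABC"), "equal-length")
  set.seed(5)
  for (i in 1:100) {
    len <- sample(1:10, 1)
    a <- randomString(len); b <- randomString(len)
    expect_gte(gaplessDistance(a, b), weightedLevenshtein(a, b))
  }
})

test_that("shared mutations are exact (pos, ref, alt) matches", {
  g45a <- data.frame(pos = 45, ref = "G", alt = "A")
  c120t <- data.frame(pos = 120, ref = "C", alt = "T")
  g45t <- data.frame(pos = 45, ref = "G", alt = "T")
  expect_equal(sharedMutationCount(rbind(g45a, c120t), g45a), 1)
  expect_equal(sharedMutationCount(g45a, g45t), 0)  # same pos, different alt
  expect_equal(sharedMutationCount(data.frame(), g45a), 0)
  expect_equal(sharedMutationCount(NULL, NULL), 0)
  # duplicates count once
  expect_equal(sharedMutationCount(rbind(g45a, g45a), g45a), 1)
})

test_that("pairwise score reproduces the metric's worked examples", {
  base <- makeRecord("a", cdr3 = "CARDYW")
  expect_equal(pairwiseScore(base, makeRecord("b", cdr3 = "CARDYW")), 0)
  # same V/J, one CDR3 substitution, length 6
  expect_equal(pairwiseScore(base, makeRecord("b", cdr3 = "CARDFW")),
               1 / 6)
  # identical CDR3s, same V, different J: penalty 8 normalized by 6
  expect_equal(pairwiseScore(base, makeRecord("b", cdr3 = "CARDYW",
                                              j = "IGHJ6*02")),
               8 / 6)
  # 1 CDR3 mismatch, 3 shared mutations: 1 - 3*0.35 clamps to 0
  muts <- data.frame(pos = c(10, 20, 30), ref = c("G", "C", "A"),
                     alt = c("A", "T", "G"))
  expect_equal(pairwiseScore(makeRecord("a", cdr3 = "CARDYW",
                                        mutations = muts),
                             makeRecord("b", cdr3 = "CARDFW",
                                        mutations = muts)),
               0)
  # cross-family pair short-circuits to the sentinel
  expect_equal(pairwiseScore(makeRecord("a", v = "IGHV1-2*01"),
                             makeRecord("b", v = "IGHV3-23*01")),
               100)
  # ... unless the pre-screen is off: then the V penalty applies instead
  off <- scoreParams(familyPrescreen = FALSE)
  expect_equal(pairwiseScore(makeRecord("a", v = "IGHV1-2*01",
                                        cdr3 = "CARDYW"),
                             makeRecord("b", v = "IGHV3-23*01",
                                        cdr3 = "CARDYW"), off),
               10 / 6)
})

test_that("V/J penalties compare gene level, alleles ignored", {
  a <- makeRecord("a", v = "IGHV3-23*01", j = "IGHJ4*01")
  b <- makeRecord("b", v = "IGHV3-23*04", j = "IGHJ4*02")
  expect_equal(pairwiseScore(a, b), 0)
  c <- makeRecord("c", v = "IGHV3-30*01")  # same family, different gene
  expect_equal(pairwiseScore(a, c), 10 / 5)
})

test_that("pairwise score is symmetric, zero on identity, finite and non-negative", {
  set.seed(33)
  recs <- randomRecords(24)
  for (i in 1:40) {
    ij <- sample(nrow(recs), 2)
    r1 <- recs[ij[1], ]; r2 <- recs[ij[2], ]
    s12 <- pairwiseScore(r1, r2)
    expect_equal(s12, pairwiseScore(r2, r1))
    expect_gte(s12, 0)
    expect_true(is.finite(s12))
  }
  for (i in sample(nrow(recs), 5))
    expect_equal(pairwiseScore(recs[i, ], recs[i, ]), 0)
})

test_that("condensed distances agree with the per-pair route", {
  set.seed(87)
  recs <- randomRecords(12)
  d <- condensedDistances(recs)
  expect_s3_class(d, "dist")
  expect_length(d, 12 * 11 / 2)
  m <- as.matrix(d)
  for (i in 1:11) for (j in (i + 1):12) {
    expect_equal(m[i, j], pairwiseScore(recs[i, ], recs[j, ]),
                 tolerance = 1e-12)
  }
})

test_that("condensed distances handle edge cases", {
  recs <- rbind(makeRecord("a"), makeRecord("b"))
  expect_length(condensedDistances(recs), 1)
  same <- do.call(rbind, lapply(1:5, function(i)
    makeRecord(paste0("s", i))))
  expect_true(all(as.numeric(condensedDistances(same)) == 0))
  expect_error(condensedDistances(makeRecord("one")), "at least 2")
})
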