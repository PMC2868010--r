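test_that("relative difference is symmetric, bounded and guards the zero case", {
  expect_equal(relDiff(1.3, 1.3), 0)
  expect_equal(relDiff(1, 3), 1)          # |1-3| / mean(1,3)
  expect_equal(relDiff(0, 0), 0)
  expect_equal(relDiff(0, 5), 2)          # upper bound of the mean convention
  expect_equal(relDiff(1, 3, method = "max"), 2 / 3)
  expect_equal(relDiff(0, 5, method = "max"), 1)
  expect_equal(relDiff(2, 7), relDiff(7, 2))
  expect_error(relDiff(-1, 2), "non-negative")
})

test_that("the logistic PMS crosses zero exactly at the cut-off", {
  p <- ScoreParams()
  # d = cutoff: construct b so that relDiff(a, b) = t
  t <- p@cutoff
  b <- 1 * (2 + t) / (2 - t)
  expect_equal(relDiff(1, b), t, tolerance = 1e-12)
  expect_equal(pms(1, b, p), 0, tolerance = 1e-10)
  # asymmetric scores shift the crossing but keep s(cutoff) = 0
  p2 <- ScoreParams(sPlus = 2, sMinus = -0.5, cutoff = 0.3, lambda = 25)
  b2 <- 1 * (2 + 0.3) / (2 - 0.3)
  expect_equal(pms(1, b2, p2), 0, tolerance = 1e-10)
})

test_that("PMS approaches its ceiling at d = 0 and its floor at maximal d", {
  p <- ScoreParams()
  expect_gt(pms(1.3, 1.3, p), 0.99)
  # closed form at d = 0
  x0 <- 0.25 - log(1) / 40
  expect_equal(pms(2, 2, p), -1 + 2 / (1 + exp(-40 * x0)), tolerance = 1e-12)
  # maximal dissimilarity: one entry zero
  expect_lt(abs(pms(0, 5, p) - p@sMinus), 1e-3)
})

test_that("PMS is monotone non-increasing in d and bounded in (sMinus, sPlus)", {
  for (p in list(ScoreParams(),
                 ScoreParams(sPlus = 2, sMinus = -0.3, cutoff = 0.4, lambda = 8))) {
    d <- seq(0, 2, by = 0.01)
    s <- dfmalign:::pmsFromDiff(d, p)
    expect_true(all(diff(s) <= 0))
    # open interval mathematically; the floor/ceiling saturate in floating
    # point at extreme d, so bounds are checked non-strictly
    expect_true(all(s >= p@sMinus & s <= p@sPlus))
    expect_true(all(s[d <= 1] > p@sMinus & s[d <= 1] < p@sPlus))
    # positive iff d < cutoff
    expect_true(all((s > 0) == (d < p@cutoff)))
  }
})

test_that("collapsed DFMs pick out the aligned principal submatrices", {
  set.seed(30)
  Fa <- randomDFM(5); Fb <- randomDFM(6)
  # identity self-alignment reproduces the matrix
  id <- MatchAlignment(1:5, 1:5)
  sub <- extractSubmatrices(Fa, Fa, id)
  expect_equal(sub$a, unname(dfmMatrix(Fa)))
  expect_equal(sub$b, unname(dfmMatrix(Fa)))
  # explicit 2-column case
  aln <- MatchAlignment(c(1, 3), c(2, 4))
  sub2 <- extractSubmatrices(Fa, Fb, aln)
  ma <- unname(dfmMatrix(Fa)); mb <- unname(dfmMatrix(Fb))
  expect_equal(sub2$a, ma[c(1, 3), c(1, 3)])
  expect_equal(sub2$b, mb[c(2, 4), c(2, 4)])
  # empty alignment gives 0 x 0 matrices
  sub0 <- extractSubmatrices(Fa, Fb, MatchAlignment())
  expect_equal(dim(sub0$a), c(0L, 0L))
  expect_equal(dim(sub0$b), c(0L, 0L))
  # out-of-range indices
  expect_error(extractSubmatrices(Fa, Fb, MatchAlignment(c(1, 6), c(1, 2))),
               "exceed")
})

test_that("alignment score equals the brute-force double loop", {
  set.seed(31)
  for (rep in 1:25) {
    Fa <- randomDFM(6); Fb <- randomDFM(7)
    k <- sample(0:5, 1)
    aln <- randomAlignmentFixture(6, 7, k)
    expect_equal(alignmentScore(Fa, Fb, aln),
                 naiveAlignmentScore(Fa, Fb, aln), tolerance = 1e-12)
  }
})

test_that("alignments shorter than two columns score zero", {
  set.seed(32)
  Fa <- randomDFM(4); Fb <- randomDFM(4)
  expect_equal(alignmentScore(Fa, Fb, MatchAlignment()), 0)
  expect_equal(alignmentScore(Fa, Fb, MatchAlignment(2, 3)), 0)
})

test_that("identity self-alignment attains the maximal score C(n,2) * s(0)", {
  set.seed(33)
  Fa <- randomDFM(8)
  s0 <- pms(1, 1, ScoreParams())
  expect_equal(alignmentScore(Fa, Fa, MatchAlignment(1:8, 1:8)),
               choose(8, 2) * s0, tolerance = 1e-9)
})

test_that("score is symmetric under swapping the two proteins", {
  set.seed(34)
  Fa <- randomDFM(6); Fb <- randomDFM(8)
  aln <- randomAlignmentFixture(6, 8, 4)
  swapped <- MatchAlignment(aln@b, aln@a)
  expect_identical(alignmentScore(Fa, Fb, aln),
                   alignmentScore(Fb, Fa, swapped))
})

test_that("SMS decomposition: column removal drops the score by exactly its SMS", {
  set.seed(35)
  for (rep in 1:15) {
    Fa <- randomDFM(7); Fb <- randomDFM(7)
    k <- sample(2:6, 1)
    aln <- randomAlignmentFixture(7, 7, k)
    sms <- smsProfile(Fa, Fb, aln)
    total <- alignmentScore(Fa, Fb, aln)
    expect_equal(total, sum(sms) / 2, tolerance = 1e-9)
    for (i in seq_len(k)) {
      reduced <- MatchAlignment(aln@a[-i], aln@b[-i])
      expect_equal(total - alignmentScore(Fa, Fb, reduced), sms[i],
                   tolerance = 1e-9)
    }
  }
})

test_that("two-column alignments have SMS equal to the total on both columns", {
  set.seed(36)
  Fa <- randomDFM(5); Fb <- randomDFM(5)
  aln <- randomAlignmentFixture(5, 5, 2)
  total <- alignmentScore(Fa, Fb, aln)
  expect_equal(smsProfile(Fa, Fb, aln), rep(total, 2), tolerance = 1e-12)
})

test_that("identity self-alignment has uniform positive SMS", {
  set.seed(37)
  Fa <- randomDFM(6)
  sms <- smsProfile(Fa, Fa, MatchAlignment(1:6, 1:6))
  s0 <- pms(1, 1, ScoreParams())
  expect_equal(sms, rep(5 * s0, 6), tolerance = 1e-9)
  expect_true(all(sms > 0))
})

test_that("scoreAlignment bundles score, SMS and collapsed matrices consistently", {
  set.seed(38)
  Fa <- randomDFM(7); Fb <- randomDFM(9)
  aln <- randomAlignmentFixture(7, 9, 5)
  sc <- scoreAlignment(Fa, Fb, aln)
  expect_s4_class(sc, "ScoredAlignment")
  expect_equal(totalScore(sc), alignmentScore(Fa, Fb, aln))
  expect_equal(smsValues(sc), smsProfile(Fa, Fb, aln))
  expect_equal(sc@collapsedA, extractSubmatrices(Fa, Fb, aln)$a)
  expect_silent(validObject(sc))
})

test_that("ScoreParams validity enforces the sign and positivity contracts", {
  expect_error(ScoreParams(sPlus = -1), "sPlus")
  expect_error(ScoreParams(sMinus = 1), "sMinus")
  expect_error(ScoreParams(cutoff = 0), "cutoff")
  expect_error(ScoreParams(lambda = -2), "lambda")
})
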