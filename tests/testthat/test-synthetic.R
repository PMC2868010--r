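# Closed-form SD of |r + delta| with delta ~ N(0, s^2 I_3): the
# generator-implied pairwise distance SD used as an independent oracle.
impliedDistanceSD <- function(r, s) {
  erf <- function(x) 2 * pnorm(x * sqrt(2)) - 1
  ED <- s * sqrt(2 / pi) * exp(-r^2 / (2 * s^2)) +
    (r + s^2 / r) * erf(r / (s * sqrt(2)))
  sqrt(r^2 + 3 * s^2 - ED^2)
}

test_that("generation is bitwise reproducible under a fixed seed", {
  sp <- SynthSpec(15, 50, seed = 70)
  e1 <- generateEnsemble(sp)
  e2 <- generateEnsemble(sp)
  expect_identical(coords(e1), coords(e2))
  hp1 <- generateHomologPair(SynthSpec(20, 40, seed = 71))
  hp2 <- generateHomologPair(SynthSpec(20, 40, seed = 71))
  expect_identical(coords(hp1$b), coords(hp2$b))
  expect_identical(alignmentPairs(hp1$planted), alignmentPairs(hp2$planted))
})

test_that("near-rigid specs give near-zero fingerprints", {
  sp <- SynthSpec(10, 100, mobility = rep(1e-6, 10), seed = 72)
  d <- computeDFM(generateEnsemble(sp))
  expect_lt(max(dfmMatrix(d)), 1e-4)
})

test_that("mobility contrast shows up as a bimodal fluctuation profile", {
  m <- c(rep(0.2, 15), rep(2.0, 15))
  sp <- SynthSpec(30, 4000, mobility = m, coupling = 0, seed = 73)
  afp <- averageFluctuationProfile(computeDFM(generateEnsemble(sp)))
  # rows of low-mobility residues still contain cross-block entries
  # (dominated by the mobile partner), capping the block-mean ratio near 2;
  # the designed contrast therefore shows as complete separation of the two
  # profile modes rather than an arbitrarily large mean ratio
  expect_gt(min(afp[16:30]), max(afp[1:15]))
  expect_gt(mean(afp[16:30]), 1.5 * mean(afp[1:15]))
})

test_that("empirical distance SDs converge to the generator-implied values", {
  sp <- SynthSpec(10, 10000, coupling = 0.4, seed = 74)
  d <- unname(dfmMatrix(computeDFM(generateEnsemble(sp))))
  imp <- dfmalign:::impliedCovariance(sp)
  K <- imp$K; bb <- imp$backbone
  for (i in 1:9) for (j in (i + 1):10) {
    r <- sqrt(sum((bb[i, ] - bb[j, ])^2))
    s <- sqrt(K[i, i] + K[j, j] - 2 * K[i, j])
    expect_lt(abs(d[i, j] - impliedDistanceSD(r, s)) / impliedDistanceSD(r, s),
              0.05)
  }
})

test_that("AR(1) frame memory keeps the marginal fluctuation scale", {
  m <- rep(1, 12)
  d0 <- computeDFM(generateEnsemble(
    SynthSpec(12, 8000, mobility = m, seed = 75)))
  d1 <- computeDFM(generateEnsemble(
    SynthSpec(12, 8000, mobility = m, ar1 = 0.5, seed = 76)))
  off0 <- mean(dfmMatrix(d0)[upper.tri(dfmMatrix(d0))])
  off1 <- mean(dfmMatrix(d1)[upper.tri(dfmMatrix(d1))])
  expect_lt(abs(off1 - off0) / off0, 0.1)
})

test_that("homolog pairs plant the documented core correspondence", {
  # full core, no indels: the planted alignment is the identity
  hp <- generateHomologPair(SynthSpec(20, 30, seed = 77), coreFraction = 1,
                            nInsertions = 0, perturbation = 0)
  expect_equal(alignmentPairs(hp$planted),
               cbind(a = 1:20, b = 1:20), ignore_attr = TRUE)
  expect_equal(nResidues(hp$b), 20)
  # core_fraction 0.8 on n = 50 plants 40 columns
  hp2 <- generateHomologPair(SynthSpec(50, 30, seed = 78), coreFraction = 0.8)
  expect_equal(alignmentLength(hp2$planted), 40)
  expect_equal(nResidues(hp2$b), 50)  # default insertions restore the length
  expect_silent(validObject(hp2$planted))
  expect_error(generateHomologPair(SynthSpec(20, 30), coreFraction = 0),
               "coreFraction")
  expect_error(generateHomologPair(SynthSpec(20, 30), perturbation = -1),
               "perturbation")
})

test_that("dynamics-based alignment recovers a planted homologous core", {
  hp <- generateHomologPair(SynthSpec(40, 4000, seed = 79),
                            coreFraction = 0.75, perturbation = 0.1)
  Fa <- computeDFM(hp$a); Fb <- computeDFM(hp$b)
  res <- anneal(Fa, Fb, config = SAConfig(seed = 80))
  expect_gte(alignmentRecovery(res, hp$planted), 0.5)
  expect_gt(totalScore(res), 0)
})

test_that("unrelated synthetic pairs are rarely called significant", {
  m <- tinyEVDModel()
  set.seed(81)
  refs <- syntheticReferenceSet(10, nResidues = 12, nFrames = 200, seed = 82)
  ps <- numeric(0)
  for (i in seq(1, 9, by = 2)) {
    r <- anneal(refs[[i]], refs[[i + 1]],
                config = SAConfig(nRestarts = 2, seed = 83 + i))
    ps <- c(ps, suppressWarnings(
      pValue(totalScore(r), 12, 12, m)))
  }
  expect_gte(mean(ps >= 0.05), 0.8)
})

test_that("invalid synthetic specs are rejected", {
  expect_error(SynthSpec(1, 10), "nResidues")
  expect_error(SynthSpec(10, 1), "nFrames")
  expect_error(SynthSpec(10, 10, mobility = rep(-1, 10)), "mobility")
  expect_error(SynthSpec(10, 10, mobility = rep(1, 3)), "one entry per")
  expect_error(SynthSpec(10, 10, ar1 = 1), "ar1")
})
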