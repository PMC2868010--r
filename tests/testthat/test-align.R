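test_that("proposeMove returns a neighbour differing by exactly one column", {
  set.seed(40)
  # empty alignment: only insertions
  for (rep in 1:5) {
    nb <- proposeMove(MatchAlignment(), 3, 3)
    expect_equal(alignmentLength(nb), 1)
  }
  # removal keeps strict monotonicity
  aln <- MatchAlignment(c(1, 3, 5), c(2, 4, 6))
  for (rep in 1:10) {
    nb <- proposeMove(aln, 6, 6)
    expect_true(abs(alignmentLength(nb) - 3) == 1)
    expect_silent(validObject(nb))
  }
})

test_that("feasible insertions match brute-force feasibility over all cells", {
  # the documented case: {(1,1),(3,3)} on 3x3 admits exactly (2,2)
  aln <- MatchAlignment(c(1, 3), c(1, 3))
  expect_equal(feasibleInsertions(aln, 3, 3),
               cbind(2L, 2L), ignore_attr = TRUE)
  # randomized cross-check against explicit validity testing
  set.seed(41)
  for (rep in 1:20) {
    na <- sample(3:6, 1); nb <- sample(3:6, 1)
    k <- sample(0:min(na, nb), 1)
    aln <- randomAlignmentFixture(na, nb, k)
    found <- feasibleInsertions(aln, na, nb)
    brute <- list()
    for (x in seq_len(na)) for (y in seq_len(nb)) {
      ok <- !(x %in% aln@a) && !(y %in% aln@b) &&
        !inherits(try(validObject(
          MatchAlignment(sort(c(aln@a, x)), sort(c(aln@b, y)))),
          silent = TRUE), "try-error")
      # insertion must also go into the same slot in both vectors
      if (ok) {
        slotA <- sum(aln@a < x); slotB <- sum(aln@b < y)
        ok <- slotA == slotB
      }
      if (ok) brute[[length(brute) + 1L]] <- c(x, y)
    }
    brute <- if (length(brute)) do.call(rbind, brute)
             else matrix(integer(0), 0, 2)
    o1 <- found[order(found[, 1], found[, 2]), , drop = FALSE]
    o2 <- brute[order(brute[, 1], brute[, 2]), , drop = FALSE]
    expect_equal(unname(o1), unname(o2))
  }
})

test_that("initial-temperature calibration follows the Johnson rule", {
  expect_equal(t0FromMeanDrop(2, exp(-1)), 2)           # ln(1/chi0) = 1
  expect_equal(t0FromMeanDrop(2, 0.8), 2 / log(1.25))   # ~ 8.963
  expect_equal(t0FromMeanDrop(2, 0.8), 8.963, tolerance = 1e-3)
})

test_that("pilot calibration falls back to T0 = 1 when no move is downhill", {
  # single-residue proteins: every move toggles the lone zero-score column,
  # so the pilot walk never decreases the score
  z <- DFM(matrix(0, 1, 1))
  set.seed(42)
  expect_warning(t0 <- calibrateT0(z, z, pilotSteps = 200), "no score-decreasing")
  expect_equal(t0, 1.0)
})

test_that("exhaustive search enumerates choose(na+nb, na) monotone alignments", {
  set.seed(43)
  Fa <- randomDFM(4); Fb <- randomDFM(4)
  opt <- exhaustiveOptimum(Fa, Fb)
  expect_equal(attr(opt, "nEnumerated"), choose(8, 4))  # Vandermonde
  # single residues admit only the empty alignment
  one <- DFM(matrix(0, 1, 1))
  opt1 <- exhaustiveOptimum(one, one)
  expect_equal(alignmentLength(opt1), 0)
  expect_equal(totalScore(opt1), 0)
  # guard on instance size
  big <- randomDFM(15)
  expect_error(exhaustiveOptimum(big, big, maxAlignments = 1e4), "anneal")
})

test_that("exhaustive optimum of identical fingerprints is the identity alignment", {
  set.seed(44)
  Fa <- randomDFM(4)
  opt <- exhaustiveOptimum(Fa, Fa)
  expect_equal(alignmentPairs(opt), cbind(a = 1:4, b = 1:4),
               ignore_attr = TRUE)
  expect_equal(totalScore(opt), choose(4, 2) * pms(1, 1, ScoreParams()),
               tolerance = 1e-9)
})

test_that("annealing is bitwise reproducible under a fixed seed", {
  set.seed(45)
  Fa <- randomDFM(8); Fb <- randomDFM(8)
  cfg <- SAConfig(nRestarts = 2, seed = 99)
  r1 <- anneal(Fa, Fb, config = cfg)
  r2 <- anneal(Fa, Fb, config = cfg)
  expect_identical(alignmentPairs(r1@best), alignmentPairs(r2@best))
  expect_identical(totalScore(r1), totalScore(r2))
  expect_identical(r1@perRestartScores, r2@perRestartScores)
})

test_that("the incremental chain score agrees with full rescoring", {
  set.seed(46)
  for (rep in 1:5) {
    Fa <- randomDFM(7); Fb <- randomDFM(7)
    r <- anneal(Fa, Fb, config = SAConfig(nRestarts = 2, seed = rep,
                                          pruneNegativeSMS = FALSE))
    rescored <- alignmentScore(Fa, Fb, r@best@alignment)
    expect_equal(totalScore(r), rescored, tolerance = 1e-9)
    expect_equal(max(r@perRestartScores), rescored, tolerance = 1e-9)
  }
})

test_that("annealing attains the exhaustive optimum on small instances", {
  set.seed(47)
  hits <- 0
  for (rep in 1:15) {
    Fa <- randomDFM(5); Fb <- randomDFM(5)
    opt <- totalScore(exhaustiveOptimum(Fa, Fb))
    got <- totalScore(anneal(Fa, Fb, config = SAConfig(seed = rep)))
    expect_lte(got, opt + 1e-9)  # oracle is never exceeded
    if (got >= opt - 1e-9) hits <- hits + 1
  }
  expect_gte(hits, 14)
})

test_that("self-alignment of a heterogeneous fingerprint recovers the identity", {
  f <- computeDFM(generateEnsemble(SynthSpec(10, 800, seed = 48)))
  r <- anneal(f, f, config = SAConfig(seed = 49))
  expect_equal(alignmentPairs(r@best), cbind(a = 1:10, b = 1:10),
               ignore_attr = TRUE)
  expect_equal(totalScore(r), choose(10, 2) * pms(1, 1, ScoreParams()),
               tolerance = 1e-9)
})

test_that("zero-temperature annealing lands on a single-move local optimum", {
  set.seed(50)
  Fa <- randomDFM(6); Fb <- randomDFM(6)
  r <- anneal(Fa, Fb, config = SAConfig(nRestarts = 1, seed = 51,
                                        pruneNegativeSMS = FALSE),
              T0 = 1e-12)
  best <- r@best@alignment
  s <- totalScore(r)
  # no insertion improves
  ins <- feasibleInsertions(best, 6, 6)
  for (i in seq_len(nrow(ins))) {
    aln2 <- MatchAlignment(sort(c(best@a, ins[i, 1])),
                           sort(c(best@b, ins[i, 2])))
    expect_lte(alignmentScore(Fa, Fb, aln2), s + 1e-9)
  }
  # no removal improves
  for (i in seq_len(alignmentLength(best))) {
    aln2 <- MatchAlignment(best@a[-i], best@b[-i])
    expect_lte(alignmentScore(Fa, Fb, aln2), s + 1e-9)
  }
})

test_that("annealed scores dominate greedy (zero-temperature) scores", {
  set.seed(52)
  wins <- 0
  for (rep in 1:10) {
    Fa <- randomDFM(7); Fb <- randomDFM(7)
    cfg <- SAConfig(nRestarts = 2, seed = rep, pruneNegativeSMS = FALSE)
    sa <- totalScore(anneal(Fa, Fb, config = cfg))
    greedy <- totalScore(anneal(Fa, Fb, config = cfg, T0 = 1e-12))
    if (sa >= greedy - 1e-9) wins <- wins + 1
  }
  expect_gte(wins, 9)
})

test_that("negative-SMS pruning leaves only non-negative columns and never lowers the score", {
  set.seed(53)
  for (rep in 1:10) {
    Fa <- randomDFM(8); Fb <- randomDFM(8)
    aln <- randomAlignmentFixture(8, 8, 6)
    pruned <- pruneAlignment(Fa, Fb, aln)
    if (alignmentLength(pruned) >= 2)
      expect_gte(min(smsProfile(Fa, Fb, pruned)), 0)
    expect_gte(alignmentScore(Fa, Fb, pruned),
               alignmentScore(Fa, Fb, aln) - 1e-9)
  }
  # anneal with pruning enabled reports non-negative SMS throughout
  Fa <- randomDFM(8); Fb <- randomDFM(8)
  r <- anneal(Fa, Fb, config = SAConfig(seed = 54))
  if (alignmentLength(r@best) >= 2)
    expect_gte(min(smsValues(r)), 0)
})

test_that("SAConfig validity rejects inconsistent schedules", {
  expect_error(SAConfig(chi0 = 1.2), "chi0")
  expect_error(SAConfig(coolingFactor = 1), "coolingFactor")
  expect_error(SAConfig(stopAcceptance = 0.9), "stopAcceptance")
  expect_error(SAConfig(nRestarts = 0), "nRestarts")
})
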