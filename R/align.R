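#' @useDynLib dfmalign, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Propose a neighbouring alignment
#'
#' Returns an alignment differing from `aln` by exactly one match column:
#' either one column is removed, or one feasible column is inserted
#' (insertions preserve the strict monotonicity of both index vectors and
#' are drawn uniformly over all feasible cells). On an empty alignment only
#' insertions are proposed; when no insertion is feasible only removals.
#' This is the move set of the simulated-annealing search.
#'
#' @param aln a [MatchAlignment-class].
#' @param na,nb lengths of proteins A and B.
#' @return A [MatchAlignment-class] neighbour.
#' @export
proposeMove <- function(aln, na, nb) {
  stopifnot(is(aln, "MatchAlignment"))
  k <- length(aln@a)
  ins <- feasibleInsertions(aln, na, nb)
  canInsert <- nrow(ins) > 0
  canRemove <- k > 0
  if (!canInsert && !canRemove)
    stop("no feasible move: alignment space is empty")
  doInsert <- if (canInsert && canRemove) stats::runif(1) < 0.5 else canInsert
  if (doInsert) {
    cell <- ins[sample.int(nrow(ins), 1L), ]
    MatchAlignment(sort(c(aln@a, cell[1])), sort(c(aln@b, cell[2])))
  } else {
    i <- sample.int(k, 1L)
    MatchAlignment(aln@a[-i], aln@b[-i])
  }
}

#' Enumerate all feasible single-column insertions
#'
#' All cells `(x, y)` whose insertion into `aln` keeps both index vectors
#' strictly increasing.
#'
#' @inheritParams proposeMove
#' @return two-column integer matrix of feasible `(x, y)` cells.
#' @export
feasibleInsertions <- function(aln, na, nb) {
  a <- aln@a; b <- aln@b; k <- length(a)
  out <- vector("list", k + 1L)
  for (s in 0:k) {
    loA <- if (s == 0) 0L else a[s]; hiA <- if (s == k) na + 1L else a[s + 1L]
    loB <- if (s == 0) 0L else b[s]; hiB <- if (s == k) nb + 1L else b[s + 1L]
    xs <- seq_len(hiA - loA - 1L) + loA
    ys <- seq_len(hiB - loB - 1L) + loB
    if (length(xs) && length(ys))
      out[[s + 1L]] <- cbind(rep(xs, each = length(ys)), rep(ys, length(xs)))
  }
  res <- do.call(rbind, out)
  if (is.null(res)) matrix(integer(0), 0, 2) else res
}

# Random monotone initial alignment: k ~ uniform on [0, min(na, nb)/2],
# then a uniform random monotone k-matching (any k-subset of each side
# defines exactly one).
randomInitialAlignment <- function(na, nb) {
  kmax <- floor(min(na, nb) / 2)
  k <- sample.int(kmax + 1L, 1L) - 1L
  MatchAlignment(sort(sample.int(na, k)), sort(sample.int(nb, k)))
}

#' Initial temperature from the mean downhill move
#'
#' Johnson-style calibration: with `meanDrop` the mean magnitude of
#' score-decreasing moves in an accept-everything pilot walk, the starting
#' temperature `T0 = meanDrop / log(1 / chi0)` makes the expected initial
#' acceptance ratio of downhill moves about `chi0`.
#'
#' @param meanDrop mean magnitude of score-decreasing pilot moves.
#' @param chi0 target initial acceptance ratio in (0, 1).
#' @return numeric scalar `T0`.
#' @examples
#' t0FromMeanDrop(2, 0.8)   # 2 / log(1.25)
#' @export
t0FromMeanDrop <- function(meanDrop, chi0) {
  stopifnot(meanDrop >= 0, chi0 > 0, chi0 < 1)
  meanDrop / log(1 / chi0)
}

#' Calibrate the initial annealing temperature
#'
#' Runs a pilot random walk over the alignment space accepting every move,
#' measures the mean magnitude of score-decreasing moves, and converts it
#' to a starting temperature with [t0FromMeanDrop()]. If the pilot never
#' decreases the score (e.g. two identical fingerprints from a very rigid
#' ensemble), falls back to `T0 = 1` with a warning.
#'
#' @param Fa,Fb [DFM-class] objects (or plain symmetric matrices).
#' @param params a [ScoreParams-class].
#' @param config an [SAConfig-class] (only `chi0` is used).
#' @param pilotSteps number of pilot moves.
#' @return numeric scalar `T0`.
#' @export
calibrateT0 <- function(Fa, Fb, params = ScoreParams(), config = SAConfig(),
                        pilotSteps = 1000L) {
  ma <- asDFMMatrix(Fa); mb <- asDFMMatrix(Fb)
  init <- randomInitialAlignment(nrow(ma), nrow(mb))
  deltas <- cpp_pilot_deltas(ma, mb, init@a - 1L, init@b - 1L,
                             as.integer(pilotSteps),
                             params@sPlus, params@sMinus, params@lambda,
                             pmsShift(params),
                             if (params@relDiffMethod == "mean") 0L else 1L)
  neg <- deltas[!is.na(deltas) & deltas < 0]
  if (!length(neg)) {
    warning("pilot walk produced no score-decreasing moves; ",
            "falling back to T0 = 1")
    return(1.0)
  }
  t0FromMeanDrop(mean(-neg), config@chi0)
}

resolvePlateau <- function(config, na, nb) {
  if (is.na(config@plateauMinAccepts)) 50L * min(na, nb)
  else as.integer(config@plateauMinAccepts)
}

#' Dynamics-based alignment by multiple-restart simulated annealing
#'
#' Searches the space of monotone match-column alignments of two DFMs for
#' the maximum total alignment score (the dynamic similarity score). Each
#' restart is a Metropolis MCMC chain: from a random initial alignment,
#' single-column insertions/removals are proposed and accepted with
#' probability `min(1, exp(deltaS / T))`; after `plateauMinAccepts`
#' accepted moves the temperature decays by `coolingFactor`; the chain
#' stops when the per-plateau acceptance ratio falls below
#' `stopAcceptance`. The best alignment ever visited across all restarts is
#' returned; when `pruneNegativeSMS` is set, columns with negative Single
#' Match Score are then removed iteratively (most negative first, SMS
#' recomputed after each removal), which can only raise the score — the
#' optimal alignment contains only non-negative SMS columns.
#'
#' The search is exact on tiny instances only by luck; see
#' [exhaustiveOptimum()] for a brute-force oracle.
#'
#' @param Fa,Fb [DFM-class] objects (or plain symmetric matrices).
#' @param params a [ScoreParams-class].
#' @param config an [SAConfig-class]; `config@seed` (if not `NA`) makes the
#'   whole search bitwise reproducible.
#' @param trace keep a per-plateau `(temperature, score, acceptance)` log.
#' @param T0 optional fixed initial temperature; by default calibrated once
#'   with [calibrateT0()] and shared by all restarts.
#' @return An [AlignResult-class].
#' @examples
#' F1 <- computeDFM(generateEnsemble(SynthSpec(8, 300, seed = 1)))
#' res <- anneal(F1, F1, config = SAConfig(nRestarts = 2, seed = 7))
#' totalScore(res)
#' @export
anneal <- function(Fa, Fb, params = ScoreParams(), config = SAConfig(),
                   trace = FALSE, T0 = NULL) {
  stopifnot(is(params, "ScoreParams"), is(config, "SAConfig"))
  validObject(params); validObject(config)
  ma <- asDFMMatrix(Fa); mb <- asDFMMatrix(Fb)
  na <- nrow(ma); nb <- nrow(mb)
  plateau <- resolvePlateau(config, na, nb)
  relM <- if (params@relDiffMethod == "mean") 0L else 1L
  x0 <- pmsShift(params)

  withSeed(config@seed, {
    if (is.null(T0))
      T0 <- suppressWarnings(calibrateT0(Fa, Fb, params, config))
    restarts <- vector("list", config@nRestarts)
    for (r in seq_len(config@nRestarts)) {
      init <- randomInitialAlignment(na, nb)
      res <- cpp_sa_chain(ma, mb, init@a - 1L, init@b - 1L,
                          params@sPlus, params@sMinus, params@lambda, x0,
                          relM, T0, plateau, config@coolingFactor,
                          config@stopAcceptance,
                          as.integer(config@stallPlateaus),
                          config@maxProposals, trace)
      restarts[[r]] <- res
    }
    scores <- vapply(restarts, function(r) r$score, numeric(1))
    bestIdx <- which.max(scores)
    bestAln <- MatchAlignment(restarts[[bestIdx]]$a + 1L,
                              restarts[[bestIdx]]$b + 1L)
    if (config@pruneNegativeSMS)
      bestAln <- pruneAlignment(ma, mb, bestAln, params)
    scored <- scoreAlignment(ma, mb, bestAln, params)
    tr <- if (trace) {
      do.call(rbind, lapply(seq_along(restarts), function(r)
        cbind(restart = r, restarts[[r]]$trace)))
    } else {
      data.frame(restart = integer(0), temperature = numeric(0),
                 score = numeric(0), acceptance = numeric(0))
    }
    new("AlignResult", best = scored, perRestartScores = scores, trace = tr)
  })
}

#' Remove negative-SMS columns from an alignment
#'
#' Iteratively deletes the match column with the most negative Single
#' Match Score, recomputing the profile after each removal, until all SMS
#' values are non-negative. Each removal raises the total score by the
#' removed (negative) SMS.
#'
#' @inheritParams alignmentScore
#' @return The pruned [MatchAlignment-class].
#' @export
pruneAlignment <- function(Fa, Fb, aln, params = ScoreParams()) {
  ma <- asDFMMatrix(Fa); mb <- asDFMMatrix(Fb)
  repeat {
    if (length(aln@a) == 0) return(aln)
    sms <- smsProfile(ma, mb, aln, params)
    i <- which.min(sms)
    if (sms[i] >= 0) return(aln)
    aln <- MatchAlignment(aln@a[-i], aln@b[-i])
  }
}

#' Exhaustive optimal alignment (brute-force oracle)
#'
#' Enumerates every strictly monotone match-column alignment of the two
#' fingerprints and returns the maximum-scoring one. The number of
#' alignments is `choose(na + nb, na)`; instances beyond `maxAlignments`
#' are refused (use [anneal()] instead — the optimization problem is
#' NP-hard at scale). Ties are broken in favour of more columns, then the
#' lexicographically smallest interleaved pair list.
#'
#' @param Fa,Fb [DFM-class] objects (or plain symmetric matrices).
#' @param params a [ScoreParams-class].
#' @param maxAlignments enumeration guard (default `1e6`).
#' @return A [ScoredAlignment-class] with attribute `"nEnumerated"`, the
#'   number of alignments visited.
#' @export
exhaustiveOptimum <- function(Fa, Fb, params = ScoreParams(),
                              maxAlignments = 1e6) {
  ma <- asDFMMatrix(Fa); mb <- asDFMMatrix(Fb)
  na <- nrow(ma); nb <- nrow(mb)
  total <- choose(na + nb, na)
  if (total > maxAlignments)
    stop("instance admits ", format(total, big.mark = ","),
         " alignments (> ", maxAlignments, "); use anneal() instead")
  pmsCell <- function(x, y, av, bv) {
    # PMS of column (x, y) against all columns already in (av, bv)
    if (!length(av)) return(0)
    sum(pmsFromDiff(relDiff(ma[x, av], mb[y, bv], params@relDiffMethod),
                    params))
  }
  env <- new.env()
  env$bestScore <- 0
  env$bestA <- integer(0); env$bestB <- integer(0)
  env$n <- 0L
  better <- function(score, a, b) {
    eps <- 1e-12 * max(1, abs(score), abs(env$bestScore))
    if (score > env$bestScore + eps) return(TRUE)
    if (score < env$bestScore - eps) return(FALSE)
    # ties at score zero keep the minimal (empty) alignment; positive ties
    # favour the longer alignment
    if (abs(score) <= eps) return(length(a) < length(env$bestA))
    if (length(a) != length(env$bestA)) return(length(a) > length(env$bestA))
    cur <- as.vector(rbind(a, b)); inc <- as.vector(rbind(env$bestA, env$bestB))
    d <- which(cur != inc)
    length(d) > 0 && cur[d[1]] < inc[d[1]]
  }
  rec <- function(av, bv, score) {
    env$n <- env$n + 1L
    if (better(score, av, bv)) {
      env$bestScore <- score; env$bestA <- av; env$bestB <- bv
    }
    lastA <- if (length(av)) av[length(av)] else 0L
    lastB <- if (length(bv)) bv[length(bv)] else 0L
    if (lastA >= na || lastB >= nb) return(invisible())
    for (x in (lastA + 1L):na)
      for (y in (lastB + 1L):nb)
        rec(c(av, x), c(bv, y), score + pmsCell(x, y, av, bv))
    invisible()
  }
  rec(integer(0), integer(0), 0)
  scored <- scoreAlignment(ma, mb, MatchAlignment(env$bestA, env$bestB),
                           params)
  attr(scored, "nEnumerated") <- env$n
  scored
}
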