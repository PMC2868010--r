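#' Generate a synthetic MD-like ensemble
#'
#' Draws an ensemble of correlated Gaussian fluctuations around a reference
#' backbone. An elastic-network-style precision matrix couples residues
#' that are within `contactCutoff` Angstrom of each other on the reference
#' curve (`Q = I + coupling * Lap` with `Lap` the graph Laplacian of the
#' contact graph); its inverse is rescaled so that each residue's per-axis
#' displacement standard deviation equals its `mobility` entry. Frames are
#' i.i.d. by default; `ar1 > 0` adds stationary AR(1) frame memory with the
#' same marginal covariance. A fixed `seed` makes the ensemble bitwise
#' reproducible.
#'
#' This emulates the statistical structure a distance-fluctuation
#' fingerprint consumes — heterogeneous amplitudes and spatially correlated
#' motion giving banded fingerprints — not physical molecular dynamics.
#'
#' @param spec a [SynthSpec-class].
#' @return A [ProteinEnsemble-class].
#' @examples
#' e <- generateEnsemble(SynthSpec(30, 500, seed = 1))
#' computeDFM(e)
#' @export
generateEnsemble <- function(spec) {
  stopifnot(is(spec, "SynthSpec"))
  validObject(spec)
  withSeed(spec@seed, {
    n <- as.integer(spec@nResidues)
    nF <- as.integer(spec@nFrames)
    bb <- backboneCoords(n, spec@backbone)
    R <- fluctuationCholesky(bb, spec@mobility, spec@coupling,
                             spec@contactCutoff)
    co <- array(0, c(nF, n, 3))
    for (ax in 1:3) {
      E <- matrix(stats::rnorm(nF * n), nF, n) %*% R
      if (spec@ar1 > 0) {
        phi <- spec@ar1
        sc <- sqrt(1 - phi^2)
        for (f in 2:nF) E[f, ] <- phi * E[f - 1L, ] + sc * E[f, ]
      }
      co[, , ax] <- rep(bb[, ax], each = nF) + E
    }
    ProteinEnsemble(co)
  })
}

# Reference backbone curve (n x 3, Angstrom).
backboneCoords <- function(n, type) {
  i <- seq_len(n) - 1
  switch(type,
    extended = cbind(3.8 * i, 0, 0),
    helix = cbind(2.3 * cos(i * 100 * pi / 180),
                  2.3 * sin(i * 100 * pi / 180),
                  1.5 * i),
    walk = {
      # fixed 3.8 A steps with mildly persistent random directions
      dirs <- matrix(stats::rnorm(3 * n), n, 3)
      for (k in 2:n) dirs[k, ] <- dirs[k, ] + 1.5 * dirs[k - 1L, ]
      dirs <- dirs / sqrt(rowSums(dirs^2))
      apply(rbind(0, 3.8 * dirs[-1, , drop = FALSE]), 2, cumsum)
    })
}

# Cholesky factor (upper) of the displacement covariance implied by the
# elastic-network precision, rescaled to the requested per-residue
# per-axis standard deviations.
fluctuationCholesky <- function(bb, mobility, coupling, contactCutoff) {
  n <- nrow(bb)
  D <- as.matrix(stats::dist(bb))
  A <- (D <= contactCutoff) & (D > 0)
  Lap <- diag(rowSums(A)) - A
  Q <- diag(n) + coupling * Lap
  K0 <- tryCatch(chol2inv(chol(Q)), error = function(e)
    stop("elastic-network precision is not positive definite: ",
         conditionMessage(e)))
  sc <- mobility / sqrt(diag(K0))
  K <- K0 * tcrossprod(sc)
  tryCatch(chol(K), error = function(e)
    stop("implied covariance is not positive definite: ",
         conditionMessage(e)))
}

# Covariance of the (x-axis) displacement field implied by a spec; used by
# convergence checks to get the generator-implied pairwise distance SD.
impliedCovariance <- function(spec) {
  bb <- backboneCoords(as.integer(spec@nResidues), spec@backbone)
  R <- fluctuationCholesky(bb, spec@mobility, spec@coupling,
                           spec@contactCutoff)
  list(backbone = bb, K = crossprod(R))
}

#' Generate a pair of synthetic homologous ensembles with a planted core
#'
#' Builds two ensembles sharing a dynamically conserved core: protein A has
#' `n` residues with the spec's mobility pattern; the core is the
#' `round(coreFraction * n)` least-mobile residues (the rigid,
#' secondary-structure-like part — what stays alignable in real homologs).
#' Protein B keeps the core residues in order, with each core mobility
#' multiplied by `1 + eps`, `eps ~ N(0, perturbation^2)`, and `nInsertions`
#' extra residues inserted into gaps chosen with probability proportional
#' to the flanking core mobility (insertions happen in loops). Inserted
#' residues take mobilities resampled from A's own loop (non-core)
#' residues. The returned `planted` alignment is the ground-truth monotone
#' correspondence of core residues, the reference for recovery testing.
#'
#' @param spec a [SynthSpec-class] describing protein A (its seed governs
#'   the whole pair).
#' @param coreFraction fraction of A's residues in the conserved core,
#'   in (0, 1].
#' @param nInsertions number of B-specific inserted residues (default:
#'   `n - coreSize`, so both chains have equal length).
#' @param perturbation relative noise on core mobilities (SD of `eps`).
#' @return list with elements `a`, `b` ([ProteinEnsemble-class]) and
#'   `planted` ([MatchAlignment-class]).
#' @examples
#' hp <- generateHomologPair(SynthSpec(30, 300, seed = 1), coreFraction = 0.8)
#' alignmentLength(hp$planted)
#' @export
generateHomologPair <- function(spec, coreFraction = 0.75, nInsertions = NULL,
                                perturbation = 0.1) {
  stopifnot(is(spec, "SynthSpec"))
  if (!(coreFraction > 0 && coreFraction <= 1))
    stop("coreFraction must be in (0, 1]")
  if (perturbation < 0)
    stop("perturbation must be >= 0")
  n <- as.integer(spec@nResidues)
  k <- as.integer(round(coreFraction * n))
  if (k < 2)
    stop("core of ", k, " residues is too small")
  if (is.null(nInsertions)) nInsertions <- n - k
  nInsertions <- as.integer(nInsertions)
  withSeed(spec@seed, {
    m <- spec@mobility
    coreIdx <- sort(order(m)[seq_len(k)])
    dropped <- setdiff(seq_len(n), coreIdx)
    coreMobB <- m[coreIdx] * pmax(1 + stats::rnorm(k, 0, perturbation), 0.05)
    if (nInsertions > 0) {
      insMob <- if (length(dropped))
        sample(m[dropped], nInsertions, replace = TRUE)
      else stats::runif(nInsertions, 0.8, 1.2) * max(m)
      # gap g = 0..k sits before core position g+1; weight by flanking
      # core mobility so insertions land in mobile (loop-like) regions
      w <- pmax(c(coreMobB[1], pmax(coreMobB[-k], coreMobB[-1]), coreMobB[k]),
                1e-6)
      slots <- sample.int(k + 1L, nInsertions, replace = TRUE, prob = w) - 1L
      nByGap <- tabulate(slots + 1L, nbins = k + 1L)
      mB <- numeric(0); corePosB <- integer(k); insUsed <- 0L
      for (g in 0:k) {
        if (nByGap[g + 1L] > 0) {
          take <- insUsed + seq_len(nByGap[g + 1L])
          mB <- c(mB, insMob[take]); insUsed <- insUsed + nByGap[g + 1L]
        }
        if (g < k) {
          mB <- c(mB, coreMobB[g + 1L])
          corePosB[g + 1L] <- length(mB)
        }
      }
    } else {
      mB <- coreMobB
      corePosB <- seq_len(k)
    }
    specA <- spec; specA@seed <- NA_real_
    eA <- generateEnsemble(specA)
    specB <- spec
    specB@seed <- NA_real_
    specB@nResidues <- as.numeric(length(mB))
    specB@mobility <- mB
    eB <- generateEnsemble(specB)
    list(a = eA, b = eB, planted = MatchAlignment(coreIdx, corePosB))
  })
}

#' Fraction of planted match columns recovered
#'
#' @param found the alignment returned by a search ([MatchAlignment-class]
#'   or [ScoredAlignment-class]).
#' @param planted the ground-truth [MatchAlignment-class].
#' @return fraction of `planted` columns present in `found`, in `[0, 1]`.
#' @export
alignmentRecovery <- function(found, planted) {
  if (is(found, "ScoredAlignment")) found <- found@alignment
  if (is(found, "AlignResult")) found <- found@best@alignment
  stopifnot(is(found, "MatchAlignment"), is(planted, "MatchAlignment"))
  if (!length(planted@a)) return(NA_real_)
  mean(paste(planted@a, planted@b) %in% paste(found@a, found@b))
}

#' Synthetic reference set for null calibration
#'
#' Generates fingerprints of mutually unrelated synthetic proteins to
#' stand in as the reference set for [calibrateEVD()]: each reference gets
#' an independent loop/strand mobility pattern (random period, phase and
#' per-residue jitter around the default profile family), so no two share
#' a planted correspondence.
#'
#' @param nRefs number of reference proteins (>= 4).
#' @param nResidues chain length of each reference (must cover the largest
#'   calibration submatrix size).
#' @param nFrames frames per ensemble.
#' @param seed RNG seed.
#' @return list of `nRefs` [DFM-class] objects.
#' @export
syntheticReferenceSet <- function(nRefs = 6, nResidues = 70, nFrames = 1000,
                                  seed = NA) {
  if (nRefs < 4)
    stop("at least 4 reference proteins are required")
  withSeed(seed, {
    lapply(seq_len(nRefs), function(r) {
      period <- stats::runif(1, 8, 14)
      phase <- stats::runif(1, 0, period)
      i <- seq_len(nResidues)
      m <- (0.35 + 1.15 * sin(pi * (i + phase) / period)^4) *
        exp(stats::rnorm(nResidues, 0, 0.15))
      sp <- SynthSpec(nResidues, nFrames, mobility = m)
      dfm <- computeDFM(generateEnsemble(sp))
      dfm@source <- sprintf("synthetic reference %d", r)
      dfm
    })
  })
}
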