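#' @import methods
NULL

## ---------------------------------------------------------------------------
## ProteinEnsemble
## ---------------------------------------------------------------------------

#' Conformational ensemble of one protein chain
#'
#' Holds the C-alpha coordinates of one chain over an ensemble of
#' conformations (trajectory frames or NMR/multi-model PDB models), in
#' Angstrom. This is the raw input from which a Dynamic Fingerprint Matrix
#' is computed; no superposition of frames is required or performed.
#'
#' @slot coords numeric array of dimension `(n_frames, n_residues, 3)`, Angstrom.
#' @slot residueLabels character vector of residue identifiers (residue name
#'   plus author-assigned number), length `n_residues`.
#' @slot frameInterval time between consecutive frames in picoseconds, or
#'   `NA_real_` when unknown (e.g. NMR model sets).
#'
#' @seealso [readEnsemble()], [computeDFM()], [generateEnsemble()]
#' @export
setClass("ProteinEnsemble",
  representation(
    coords = "array",
    residueLabels = "character",
    frameInterval = "numeric"
  ),
  prototype(frameInterval = NA_real_)
)

setValidity("ProteinEnsemble", function(object) {
  d <- dim(object@coords)
  if (length(d) != 3L || d[3] != 3L)
    return("coords must be an (n_frames, n_residues, 3) array")
  if (d[1] < 2L)
    return("an ensemble needs at least 2 frames")
  if (d[2] < 2L)
    return("an ensemble needs at least 2 residues")
  if (!all(is.finite(object@coords)))
    return("all coordinates must be finite")
  if (length(object@residueLabels) != d[2])
    return("residueLabels length must equal the number of residues")
  if (length(object@frameInterval) != 1L)
    return("frameInterval must be a single value (possibly NA)")
  TRUE
})

#' Construct a ProteinEnsemble
#'
#' @param coords `(n_frames, n_residues, 3)` numeric array of C-alpha
#'   coordinates in Angstrom.
#' @param residueLabels optional residue labels; defaults to `R1..Rn`.
#' @param frameInterval optional time between frames (ps).
#' @return A [ProteinEnsemble-class] object.
#' @examples
#' co <- array(rnorm(2 * 3 * 3), c(2, 3, 3))
#' ProteinEnsemble(co)
#' @export
ProteinEnsemble <- function(coords, residueLabels = NULL, frameInterval = NA_real_) {
  coords <- unname(coords)
  if (is.null(residueLabels))
    residueLabels <- paste0("R", seq_len(dim(coords)[2]))
  new("ProteinEnsemble",
      coords = coords,
      residueLabels = as.character(residueLabels),
      frameInterval = as.numeric(frameInterval))
}

## ---------------------------------------------------------------------------
## DFM
## ---------------------------------------------------------------------------

#' Dynamic Fingerprint Matrix
#'
#' The symmetric, non-negative matrix `F` whose `(i, j)` entry is the
#' standard deviation of the C-alpha(i)-C-alpha(j) distance over a
#' conformational ensemble. A DFM characterizes an ensemble the way a
#' distance matrix characterizes a single structure, and is invariant to
#' rigid-body motion of each frame.
#'
#' @slot mat symmetric numeric matrix, zero diagonal, entries in Angstrom.
#' @slot labels residue labels, one per row/column.
#' @slot source free-text provenance string.
#'
#' @seealso [computeDFM()], [readDFM()], [anneal()]
#' @export
setClass("DFM",
  representation(mat = "matrix", labels = "character", source = "character"),
  prototype(source = "")
)

setValidity("DFM", function(object) {
  m <- object@mat
  if (!is.numeric(m) || nrow(m) != ncol(m))
    return("DFM matrix must be square and numeric")
  if (length(object@labels) != nrow(m))
    return("labels length must match matrix dimension")
  if (nrow(m) > 0) {
    if (any(!is.finite(m)))
      return("DFM entries must be finite")
    if (any(m < 0))
      return("DFM entries must be non-negative")
    if (any(abs(diag(m)) > 1e-12))
      return("DFM diagonal must be zero")
    rel <- abs(m - t(m)) / pmax(abs(m) + abs(t(m)), 1e-300)
    if (any(rel > 1e-9 & abs(m - t(m)) > 1e-12))
      return("DFM matrix must be symmetric (1e-9 relative tolerance)")
  }
  TRUE
})

#' Construct a DFM object
#'
#' @param mat square symmetric non-negative matrix with zero diagonal (Angstrom).
#' @param labels optional residue labels (default `R1..Rn`, or the matrix
#'   dimnames when present).
#' @param source provenance string.
#' @return A [DFM-class] object.
#' @export
DFM <- function(mat, labels = NULL, source = "") {
  mat <- as.matrix(mat)
  if (is.null(labels)) {
    labels <- if (!is.null(rownames(mat))) rownames(mat) else
      paste0("R", seq_len(nrow(mat)))
  }
  dimnames(mat) <- NULL
  new("DFM", mat = mat, labels = as.character(labels), source = as.character(source))
}

## ---------------------------------------------------------------------------
## MatchAlignment
## ---------------------------------------------------------------------------

#' Pairwise residue alignment as ordered match columns
#'
#' An alignment of two proteins is the ordered list of its gap-free match
#' columns: column `k` pairs residue `a[k]` of protein A with residue `b[k]`
#' of protein B. Both index vectors are strictly increasing (1-based), i.e.
#' the alignment is monotone, as for the match columns of any gapped
#' pairwise sequence alignment.
#'
#' @slot a strictly increasing integer vector of residue indices in A (1-based).
#' @slot b strictly increasing integer vector of residue indices in B (1-based).
#'
#' @seealso [alignmentScore()], [anneal()], [readAlignment()]
#' @export
setClass("MatchAlignment", representation(a = "integer", b = "integer"))

setValidity("MatchAlignment", function(object) {
  a <- object@a; b <- object@b
  if (length(a) != length(b))
    return("index vectors must have equal length")
  if (length(a)) {
    if (any(a < 1L) || any(b < 1L))
      return("residue indices must be >= 1")
    if (any(diff(a) <= 0L))
      return("indices in A must be strictly increasing")
    if (any(diff(b) <= 0L))
      return("indices in B must be strictly increasing")
  }
  TRUE
})

#' Construct a MatchAlignment
#'
#' @param a,b equal-length strictly increasing integer vectors of 1-based
#'   residue indices in proteins A and B.
#' @return A [MatchAlignment-class] object.
#' @examples
#' MatchAlignment(c(1, 3, 4), c(2, 3, 7))
#' @export
MatchAlignment <- function(a = integer(0), b = integer(0)) {
  new("MatchAlignment", a = as.integer(a), b = as.integer(b))
}

## ---------------------------------------------------------------------------
## ScoreParams
## ---------------------------------------------------------------------------

#' Parameters of the logistic Pairwise Match Score
#'
#' The Pairwise Match Score (PMS) compares one pair of equivalent DFM
#' entries through an S-shaped logistic in their relative difference `d`:
#' highly similar entries score close to `sPlus`, highly dissimilar entries
#' close to `sMinus`, with the zero crossing placed exactly at the cut-off
#' `d = cutoff` and steepness set by `lambda`. All four parameters are
#' dimensionless.
#'
#' @slot sPlus positive score ceiling (`> 0`).
#' @slot sMinus negative score floor (`< 0`).
#' @slot cutoff relative-difference cut-off `t` at which the score turns
#'   negative (`> 0`).
#' @slot lambda logistic steepness (`> 0`).
#' @slot relDiffMethod normalization of the relative difference: `"mean"`
#'   (`|a-b| / ((a+b)/2)`, range `[0, 2]`) or `"max"` (`|a-b| / max(a, b)`,
#'   range `[0, 1]`).
#'
#' @seealso [pms()], [relDiff()], [alignmentScore()]
#' @export
setClass("ScoreParams",
  representation(sPlus = "numeric", sMinus = "numeric", cutoff = "numeric",
                 lambda = "numeric", relDiffMethod = "character"),
  prototype(sPlus = 1, sMinus = -1, cutoff = 0.25, lambda = 40,
            relDiffMethod = "mean")
)

setValidity("ScoreParams", function(object) {
  if (length(object@sPlus) != 1 || length(object@sMinus) != 1 ||
      length(object@cutoff) != 1 || length(object@lambda) != 1)
    return("all score parameters must be scalars")
  if (!(object@sPlus > 0)) return("sPlus must be > 0")
  if (!(object@sMinus < 0)) return("sMinus must be < 0")
  if (!(object@cutoff > 0)) return("cutoff must be > 0")
  if (!(object@lambda > 0)) return("lambda must be > 0")
  if (!object@relDiffMethod %in% c("mean", "max"))
    return("relDiffMethod must be 'mean' or 'max'")
  TRUE
})

#' Construct ScoreParams
#'
#' Defaults (`sPlus = 1`, `sMinus = -1`, `cutoff = 0.25`, `lambda = 40`)
#' treat entry pairs differing by less than 25 percent as similar, with a
#' sharp but smooth transition (`lambda * cutoff = 10`, so identical entries
#' score above 0.999).
#'
#' @param sPlus,sMinus,cutoff,lambda,relDiffMethod see [ScoreParams-class].
#' @return A [ScoreParams-class] object.
#' @export
ScoreParams <- function(sPlus = 1, sMinus = -1, cutoff = 0.25, lambda = 40,
                        relDiffMethod = c("mean", "max")) {
  new("ScoreParams", sPlus = sPlus, sMinus = sMinus, cutoff = cutoff,
      lambda = lambda, relDiffMethod = match.arg(relDiffMethod))
}

## ---------------------------------------------------------------------------
## ScoredAlignment
## ---------------------------------------------------------------------------

#' An alignment together with its dynamic similarity score decomposition
#'
#' @slot alignment the [MatchAlignment-class].
#' @slot totalScore total alignment score, the sum of PMS over all unordered
#'   match-column pairs.
#' @slot sms Single Match Score per column: the sum of PMS of that column
#'   against all others, i.e. exactly the score drop from deleting the column.
#' @slot collapsedA,collapsedB the two `k x k` collapsed DFMs (principal
#'   submatrices restricted to the aligned residues).
#'
#' @seealso [scoreAlignment()], [smsProfile()]
#' @export
setClass("ScoredAlignment",
  representation(alignment = "MatchAlignment", totalScore = "numeric",
                 sms = "numeric", collapsedA = "matrix", collapsedB = "matrix"))

setValidity("ScoredAlignment", function(object) {
  k <- length(object@alignment@a)
  if (length(object@sms) != k)
    return("sms length must equal the number of match columns")
  if (nrow(object@collapsedA) != k || nrow(object@collapsedB) != k)
    return("collapsed matrices must be k x k")
  if (k >= 2) {
    tol <- 1e-9 * max(1, abs(object@totalScore))
    if (abs(object@totalScore - sum(object@sms) / 2) > tol)
      return("totalScore must equal half the sum of SMS values")
  }
  TRUE
})

## ---------------------------------------------------------------------------
## SAConfig
## ---------------------------------------------------------------------------

#' Simulated-annealing configuration
#'
#' Controls the multiple-restart simulated-annealing search for the optimal
#' dynamics-based alignment. Temperatures follow an exponential decay
#' schedule: the chain must accept `plateauMinAccepts` moves at each
#' temperature before it is multiplied by `coolingFactor`; a restart
#' terminates when the acceptance ratio over the last plateau drops below
#' `stopAcceptance`. The initial temperature is calibrated from a pilot
#' random walk so that the initial acceptance ratio of downhill moves is
#' about `chi0`.
#'
#' @slot chi0 target initial acceptance ratio, in (0, 1).
#' @slot coolingFactor multiplicative temperature decay per plateau, in (0, 1).
#' @slot plateauMinAccepts accepted steps required per temperature;
#'   `NA` means the size-scaled default `50 * min(nA, nB)`.
#' @slot stopAcceptance terminal acceptance-ratio threshold, in `[0, chi0)`.
#' @slot stallPlateaus also terminate a restart after this many consecutive
#'   plateaus without improvement of the best score visited (guards against
#'   chains whose acceptance ratio is held up by zero-score shuffle moves).
#' @slot nRestarts number of independent restarts from random initial states.
#' @slot seed RNG seed (`NA` = use the current RNG state).
#' @slot pruneNegativeSMS iteratively remove negative-SMS columns from the
#'   final alignment (the optimal alignment contains only non-negative SMS
#'   columns, so pruning never decreases the score).
#' @slot maxProposals hard cap on proposals per restart (safety bound).
#'
#' @seealso [anneal()], [calibrateT0()]
#' @export
setClass("SAConfig",
  representation(chi0 = "numeric", coolingFactor = "numeric",
                 plateauMinAccepts = "numeric", stopAcceptance = "numeric",
                 stallPlateaus = "numeric", nRestarts = "numeric",
                 seed = "numeric", pruneNegativeSMS = "logical",
                 maxProposals = "numeric"),
  prototype(chi0 = 0.8, coolingFactor = 0.95, plateauMinAccepts = NA_real_,
            stopAcceptance = 0.02, stallPlateaus = 25, nRestarts = 5,
            seed = NA_real_, pruneNegativeSMS = TRUE, maxProposals = 5e6)
)

setValidity("SAConfig", function(object) {
  if (!(object@chi0 > 0 && object@chi0 < 1))
    return("chi0 must be in (0, 1)")
  if (!(object@coolingFactor > 0 && object@coolingFactor < 1))
    return("coolingFactor must be in (0, 1)")
  if (!is.na(object@plateauMinAccepts) && object@plateauMinAccepts < 1)
    return("plateauMinAccepts must be >= 1")
  if (!(object@stopAcceptance >= 0 && object@stopAcceptance < object@chi0))
    return("stopAcceptance must be in [0, chi0)")
  if (object@stallPlateaus < 1)
    return("stallPlateaus must be >= 1")
  if (object@nRestarts < 1)
    return("nRestarts must be >= 1")
  if (object@maxProposals < 1)
    return("maxProposals must be >= 1")
  TRUE
})

#' Construct an SAConfig
#'
#' @param chi0,coolingFactor,plateauMinAccepts,stopAcceptance,stallPlateaus,nRestarts,seed,pruneNegativeSMS,maxProposals
#'   see [SAConfig-class].
#' @return An [SAConfig-class] object.
#' @export
SAConfig <- function(chi0 = 0.8, coolingFactor = 0.95,
                     plateauMinAccepts = NA, stopAcceptance = 0.02,
                     stallPlateaus = 25, nRestarts = 5, seed = NA,
                     pruneNegativeSMS = TRUE, maxProposals = 5e6) {
  new("SAConfig", chi0 = chi0, coolingFactor = coolingFactor,
      plateauMinAccepts = as.numeric(plateauMinAccepts),
      stopAcceptance = stopAcceptance, stallPlateaus = stallPlateaus,
      nRestarts = nRestarts, seed = as.numeric(seed),
      pruneNegativeSMS = pruneNegativeSMS, maxProposals = maxProposals)
}

## ---------------------------------------------------------------------------
## AlignResult
## ---------------------------------------------------------------------------

#' Result of a simulated-annealing alignment search
#'
#' @slot best the best [ScoredAlignment-class] across all restarts (after
#'   optional negative-SMS pruning, which can only raise the score).
#' @slot perRestartScores best-ever raw score visited in each restart.
#' @slot trace per-plateau log (`restart`, `temperature`, `score`,
#'   `acceptance`) when tracing was requested, else a 0-row data frame.
#'
#' @seealso [anneal()]
#' @export
setClass("AlignResult",
  representation(best = "ScoredAlignment", perRestartScores = "numeric",
                 trace = "data.frame"))

setValidity("AlignResult", function(object) {
  if (length(object@perRestartScores) < 1)
    return("perRestartScores must be non-empty")
  tol <- 1e-9 * max(1, abs(object@best@totalScore))
  if (object@best@totalScore < max(object@perRestartScores) - tol)
    return("best score cannot be below the best restart score")
  TRUE
})

## ---------------------------------------------------------------------------
## EVDModel
## ---------------------------------------------------------------------------

#' Size-dependent Gumbel null model of optimal alignment scores
#'
#' The optimal alignment score of two unrelated proteins is a maximum over
#' an exponentially large set of alignments and follows a type I extreme
#' value (Gumbel) distribution. Its location `mu` and scale `sigma` depend
#' on the problem size `L = L_A * L_B` (product of the two chain lengths);
#' this model holds the two regression lines `mu(L)` and `sigma(L)` fitted
#' to per-size-bin Gumbel fits of calibration scores.
#'
#' @slot muCoeffs numeric `(intercept, slope)` of the `mu(L)` regression.
#' @slot sigmaCoeffs numeric `(intercept, slope)` of the `sigma(L)` regression.
#' @slot sizeTransform transform applied to `L` before regression:
#'   `"identity"` or `"log"`.
#' @slot calibrationPoints data frame with columns `L`, `mu`, `sigma`, `n`
#'   (per-bin Gumbel fits and sample sizes).
#'
#' @seealso [calibrateEVD()], [pValue()], [fitGumbel()]
#' @export
setClass("EVDModel",
  representation(muCoeffs = "numeric", sigmaCoeffs = "numeric",
                 sizeTransform = "character", calibrationPoints = "data.frame"))

setValidity("EVDModel", function(object) {
  if (length(object@muCoeffs) != 2 || length(object@sigmaCoeffs) != 2)
    return("muCoeffs and sigmaCoeffs must each be (intercept, slope)")
  if (!object@sizeTransform %in% c("identity", "log"))
    return("sizeTransform must be 'identity' or 'log'")
  cp <- object@calibrationPoints
  if (nrow(cp) == 0)
    return("calibrationPoints must be non-empty")
  if (!all(c("L", "mu", "sigma", "n") %in% names(cp)))
    return("calibrationPoints needs columns L, mu, sigma, n")
  if (any(cp$n < 10))
    return("each calibration point needs n >= 10 scores")
  Lt <- if (object@sizeTransform == "log") log(cp$L) else cp$L
  sig <- object@sigmaCoeffs[1] + object@sigmaCoeffs[2] * Lt
  if (any(sig <= 0))
    return("fitted sigma(L) must be positive over the calibrated range")
  TRUE
})

## ---------------------------------------------------------------------------
## SynthSpec
## ---------------------------------------------------------------------------

#' Specification of a synthetic MD-like ensemble
#'
#' Describes an ensemble of correlated Gaussian fluctuations around a
#' reference backbone: per-residue displacement amplitudes (`mobility`),
#' an elastic-network-style coupling of spatial neighbours (`coupling`
#' scales the stiffness between residues within `contactCutoff` Angstrom of
#' each other on the reference backbone), and an optional AR(1) frame
#' memory. This generator reproduces the statistical structure the DFM
#' method consumes (heterogeneous, spatially correlated fluctuations giving
#' banded fingerprint matrices), not physical MD.
#'
#' @slot nResidues chain length.
#' @slot nFrames ensemble size (`>= 2`).
#' @slot backbone reference curve: `"helix"` (ideal alpha-helix geometry),
#'   `"extended"` (3.8 A steps along one axis) or `"walk"` (random walk with
#'   fixed 3.8 A step).
#' @slot mobility per-residue displacement standard deviation per axis (A, `> 0`).
#' @slot coupling off-diagonal stiffness of the elastic-network precision
#'   (`>= 0`; larger couples neighbours more strongly).
#' @slot contactCutoff neighbour cutoff on the reference backbone (A).
#' @slot ar1 AR(1) frame-memory coefficient in `[0, 1)`; 0 = i.i.d. frames.
#' @slot seed RNG seed (`NA` = current RNG state).
#'
#' @seealso [generateEnsemble()], [generateHomologPair()]
#' @export
setClass("SynthSpec",
  representation(nResidues = "numeric", nFrames = "numeric",
                 backbone = "character", mobility = "numeric",
                 coupling = "numeric", contactCutoff = "numeric",
                 ar1 = "numeric", seed = "numeric"),
  prototype(backbone = "helix", coupling = 0.5, contactCutoff = 10,
            ar1 = 0, seed = NA_real_)
)

setValidity("SynthSpec", function(object) {
  if (object@nResidues < 2) return("nResidues must be >= 2")
  if (object@nFrames < 2) return("nFrames must be >= 2")
  if (!object@backbone %in% c("helix", "extended", "walk"))
    return("backbone must be 'helix', 'extended' or 'walk'")
  if (length(object@mobility) != object@nResidues)
    return("mobility must have one entry per residue")
  if (any(object@mobility <= 0))
    return("mobility entries must be > 0")
  if (object@coupling < 0) return("coupling must be >= 0")
  if (!(object@ar1 >= 0 && object@ar1 < 1)) return("ar1 must be in [0, 1)")
  TRUE
})

#' Construct a SynthSpec
#'
#' The default mobility profile alternates rigid, secondary-structure-like
#' stretches (about 0.35 A) with mobile loop-like peaks (up to 1.5 A) on a
#' ten-residue period: `0.35 + 1.15 * sin(pi * i / 10)^4`. This
#' heterogeneity is what makes synthetic fingerprints identifiable in
#' alignment tests.
#'
#' @param nResidues,nFrames,backbone,mobility,coupling,contactCutoff,ar1,seed
#'   see [SynthSpec-class]; `mobility = NULL` selects the default profile.
#' @return A [SynthSpec-class] object.
#' @export
SynthSpec <- function(nResidues, nFrames, backbone = c("helix", "extended", "walk"),
                      mobility = NULL, coupling = 0.5, contactCutoff = 10,
                      ar1 = 0, seed = NA) {
  backbone <- match.arg(backbone)
  if (is.null(mobility))
    mobility <- defaultMobilityProfile(nResidues)
  new("SynthSpec", nResidues = as.numeric(nResidues),
      nFrames = as.numeric(nFrames), backbone = backbone,
      mobility = as.numeric(mobility), coupling = coupling,
      contactCutoff = contactCutoff, ar1 = ar1, seed = as.numeric(seed))
}

#' Default per-residue mobility profile
#'
#' Secondary-structure-like alternation of rigid stretches and mobile loops:
#' `0.35 + 1.15 * sin(pi * i / 10)^4` Angstrom (per-axis displacement SD).
#'
#' @param n chain length.
#' @return numeric vector of length `n`.
#' @export
defaultMobilityProfile <- function(n) {
  i <- seq_len(n)
  0.35 + 1.15 * sin(pi * i / 10)^4
}
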