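#' Relative difference of two fluctuation values
#'
#' Symmetric, dimensionless dissimilarity of two non-negative DFM entries.
#' Under the default `"mean"` normalization, `d = |a - b| / ((a + b) / 2)`,
#' bounded in `[0, 2]`; under `"max"`, `d = |a - b| / max(a, b)`, bounded
#' in `[0, 1]`. The degenerate case `a = b = 0` is defined as `d = 0`.
#'
#' @param a,b non-negative fluctuation values (Angstrom); vectorized.
#' @param method `"mean"` (default) or `"max"`.
#' @return numeric vector of relative differences.
#' @examples
#' relDiff(1, 3)   # 1
#' relDiff(0, 0)   # 0
#' @export
relDiff <- function(a, b, method = c("mean", "max")) {
  method <- match.arg(method)
  if (any(a < 0) || any(b < 0))
    stop("fluctuation values must be non-negative")
  denom <- if (method == "mean") (a + b) / 2 else pmax(a, b)
  d <- abs(a - b) / denom
  d[denom == 0] <- 0
  d
}

# Logistic shift making the score cross zero exactly at d = cutoff.
pmsShift <- function(p) p@cutoff - log(p@sPlus / (-p@sMinus)) / p@lambda

# PMS as a function of the relative difference d (vectorized).
pmsFromDiff <- function(d, p) {
  p@sMinus + (p@sPlus - p@sMinus) / (1 + exp(p@lambda * (d - pmsShift(p))))
}

#' Pairwise Match Score
#'
#' The S-shaped logistic score of one pair of equivalent DFM entries:
#' `s = sMinus + (sPlus - sMinus) / (1 + exp(lambda * (d - x0)))` with
#' `d = relDiff(a, b)` and the shift `x0` solved in closed form so that the
#' score is exactly zero at the cut-off, `s(d = cutoff) = 0`
#' (`x0 = cutoff - log(sPlus / -sMinus) / lambda`). The score is strictly
#' decreasing in `d`, positive iff `d < cutoff`, and bounded in
#' `(sMinus, sPlus)`.
#'
#' @param a,b non-negative fluctuation values (Angstrom); vectorized.
#' @param params a [ScoreParams-class].
#' @return numeric vector of scores.
#' @examples
#' p <- ScoreParams()
#' pms(1, 1, p)            # ~ sPlus
#' pms(1, 1 + 2 * 0.25 / (2 - 0.25), p)  # d = cutoff -> 0
#' @export
pms <- function(a, b, params = ScoreParams()) {
  stopifnot(is(params, "ScoreParams"))
  pmsFromDiff(relDiff(a, b, params@relDiffMethod), params)
}

#' Collapsed DFMs under an alignment
#'
#' Restricts each fingerprint to its aligned residues: with match columns
#' `(a_k, b_k)`, `collapsedA[i, j] = Fa[a_i, a_j]` and
#' `collapsedB[i, j] = Fb[b_i, b_j]`, both `k x k`. Equivalent entries of
#' the two collapsed matrices describe fluctuations of equivalent residue
#' pairs.
#'
#' @param Fa,Fb [DFM-class] objects (or plain symmetric matrices).
#' @param aln a [MatchAlignment-class].
#' @return list with elements `a` and `b`, the two collapsed matrices.
#' @export
extractSubmatrices <- function(Fa, Fb, aln) {
  ma <- asDFMMatrix(Fa); mb <- asDFMMatrix(Fb)
  stopifnot(is(aln, "MatchAlignment"))
  checkAlignmentBounds(aln, nrow(ma), nrow(mb))
  list(a = ma[aln@a, aln@a, drop = FALSE],
       b = mb[aln@b, aln@b, drop = FALSE])
}

checkAlignmentBounds <- function(aln, na, nb) {
  if (length(aln@a) && (max(aln@a) > na || max(aln@b) > nb))
    stop("alignment indices exceed DFM dimensions (", na, ", ", nb, ")")
  invisible(TRUE)
}

# k x k matrix of PMS values of the collapsed entry pairs (diagonal is the
# score of the zero-zero diagonal pair; callers exclude it).
pmsMatrix <- function(sub, params) {
  pmsFromDiff(relDiff(sub$a, sub$b, params@relDiffMethod), params)
}

#' Total dynamic similarity score of an alignment
#'
#' Sum of the Pairwise Match Scores over all unordered match-column pairs
#' `{i, j}`, `i < j` (diagonal pairs are excluded: both entries are
#' identically zero and would only add a constant). Alignments with fewer
#' than two columns score 0. At the optimum over all monotone alignments
#' this total is the dynamic similarity score of the two proteins.
#'
#' @param Fa,Fb [DFM-class] objects (or plain symmetric matrices).
#' @param aln a [MatchAlignment-class].
#' @param params a [ScoreParams-class].
#' @return numeric scalar.
#' @export
alignmentScore <- function(Fa, Fb, aln, params = ScoreParams()) {
  k <- length(aln@a)
  if (k < 2) {
    checkAlignmentBounds(aln, nrow(asDFMMatrix(Fa)), nrow(asDFMMatrix(Fb)))
    return(0)
  }
  P <- pmsMatrix(extractSubmatrices(Fa, Fb, aln), params)
  sum(P[upper.tri(P)])
}

#' Single Match Score profile
#'
#' `sms[i]` is the sum of PMS of column `i` against all other match
#' columns; equivalently, exactly the amount by which the total alignment
#' score drops when column `i` is removed. The SMS profile is the
#' per-position confidence in an alignment; the total score equals half the
#' sum of the SMS values.
#'
#' @inheritParams alignmentScore
#' @return numeric vector of length `alignmentLength(aln)`.
#' @export
smsProfile <- function(Fa, Fb, aln, params = ScoreParams()) {
  k <- length(aln@a)
  if (k == 0) return(numeric(0))
  if (k == 1) {
    checkAlignmentBounds(aln, nrow(asDFMMatrix(Fa)), nrow(asDFMMatrix(Fb)))
    return(0)
  }
  P <- pmsMatrix(extractSubmatrices(Fa, Fb, aln), params)
  rowSums(P) - diag(P)
}

#' Score an alignment with full decomposition
#'
#' Bundles the total score, the SMS profile and the two collapsed DFMs
#' into a [ScoredAlignment-class].
#'
#' @inheritParams alignmentScore
#' @return A [ScoredAlignment-class].
#' @export
scoreAlignment <- function(Fa, Fb, aln, params = ScoreParams()) {
  sub <- extractSubmatrices(Fa, Fb, aln)
  k <- length(aln@a)
  if (k < 2) {
    total <- 0
    sms <- rep(0, k)
  } else {
    P <- pmsFromDiff(relDiff(sub$a, sub$b, params@relDiffMethod), params)
    sms <- rowSums(P) - diag(P)
    total <- sum(P[upper.tri(P)])
  }
  new("ScoredAlignment", alignment = aln, totalScore = total, sms = sms,
      collapsedA = sub$a, collapsedB = sub$b)
}
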