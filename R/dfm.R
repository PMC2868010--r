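#' @describeIn computeDFM Dynamic Fingerprint Matrix of an ensemble
#'
#' Entry `(i, j)` of the fingerprint is the standard deviation of the
#' C-alpha(i)-C-alpha(j) Euclidean distance over the frames of the
#' ensemble; the diagonal is exactly zero and the matrix symmetric by
#' construction. Because pairwise distances are invariant to rigid motion
#' of a frame, no superposition onto a reference structure is needed.
#'
#' The `"population"` convention (divide by the number of frames) treats
#' the ensemble itself as the distribution whose spread is measured;
#' `"sample"` divides by `n - 1`.
#'
#' @param varianceConvention `"population"` (default) or `"sample"`.
#' @examples
#' e <- generateEnsemble(SynthSpec(20, 200, seed = 1))
#' computeDFM(e)
#' @export
setMethod("computeDFM", "ProteinEnsemble",
          function(x, varianceConvention = c("population", "sample")) {
  varianceConvention <- match.arg(varianceConvention)
  co <- x@coords
  nF <- dim(co)[1]; n <- dim(co)[2]
  denom <- if (varianceConvention == "population") nF else nF - 1L
  X <- co[, , 1]; Y <- co[, , 2]; Z <- co[, , 3]
  F <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    dx <- X[, (i + 1L):n, drop = FALSE] - X[, i]
    dy <- Y[, (i + 1L):n, drop = FALSE] - Y[, i]
    dz <- Z[, (i + 1L):n, drop = FALSE] - Z[, i]
    d <- sqrt(dx * dx + dy * dy + dz * dz)
    mu <- colMeans(d)
    v <- colSums((d - rep(mu, each = nF))^2) / denom
    s <- sqrt(pmax(v, 0))
    F[i, (i + 1L):n] <- s
    F[(i + 1L):n, i] <- s
  }
  DFM(F, labels = x@residueLabels,
      source = sprintf("computeDFM(%d frames, %s variance)", nF,
                       varianceConvention))
})

#' Dynamic profile of a residue
#'
#' Row `k` of the fingerprint: how every residue fluctuates relative to
#' residue `k`. Entry `k` is zero (the diagonal).
#'
#' @param dfm a [DFM-class].
#' @param k residue index (1-based).
#' @return numeric vector of length `nResidues(dfm)`.
#' @export
dynamicProfile <- function(dfm, k) {
  stopifnot(is(dfm, "DFM"))
  n <- nrow(dfm@mat)
  if (length(k) != 1 || is.na(k) || k < 1 || k > n)
    stop("residue index k out of range [1, ", n, "]")
  dfm@mat[k, ]
}

#' Average fluctuation profile
#'
#' The per-residue mean of the fingerprint rows: an RMSF-like flexibility
#' measure that needs no reference structure. By default the mean runs over
#' the full row including the zero diagonal (divide by `n`); excluding the
#' diagonal (divide by `n - 1`) only rescales the profile and is available
#' via `includeDiagonal = FALSE`.
#'
#' @param dfm a [DFM-class].
#' @param includeDiagonal include the zero diagonal in the row mean
#'   (default `TRUE`).
#' @return numeric vector of length `nResidues(dfm)`.
#' @export
averageFluctuationProfile <- function(dfm, includeDiagonal = TRUE) {
  stopifnot(is(dfm, "DFM"))
  n <- nrow(dfm@mat)
  rowSums(dfm@mat) / if (includeDiagonal) n else n - 1L
}

#' Per-residue root mean square fluctuation
#'
#' RMSF of each C-alpha about its mean position over the frames. With
#' `fit = TRUE` (the conventional protocol) all frames are first
#' least-squares superposed onto the mean structure, iterating fit and mean
#' to convergence; with `fit = FALSE` raw coordinates are used. The
#' fingerprint itself never requires this superposition; RMSF is provided
#' for comparison with the average fluctuation profile, to which it is
#' strongly correlated on typical ensembles.
#'
#' @param e a [ProteinEnsemble-class].
#' @param fit superpose frames onto the mean structure first (default `TRUE`).
#' @param maxIter,tol iteration control of the fit-to-mean loop.
#' @return numeric vector of per-residue RMSF (Angstrom).
#' @export
rmsf <- function(e, fit = TRUE, maxIter = 20L, tol = 1e-8) {
  stopifnot(is(e, "ProteinEnsemble"))
  nF <- dim(e@coords)[1]; n <- dim(e@coords)[2]
  # frames x 3n coordinate matrix in bio3d xyz order (x1 y1 z1 x2 ...)
  X <- matrix(aperm(e@coords, c(3, 2, 1)), nrow = nF, byrow = TRUE)
  if (fit) {
    m <- colMeans(X)
    for (it in seq_len(maxIter)) {
      X <- suppressWarnings(bio3d::fit.xyz(fixed = m, mobile = X))
      m2 <- colMeans(X)
      if (max(abs(m2 - m)) < tol) { m <- m2; break }
      m <- m2
    }
  }
  m <- colMeans(X)
  dev2 <- sweep(X, 2, m)^2
  perAtom <- matrix(colMeans(dev2), nrow = 3)  # x, y, z rows per residue
  sqrt(colSums(perAtom))
}
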