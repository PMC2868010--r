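# Fixture builders and independent oracles used across the suite.

# Random ensemble: n residues spread on a line plus Gaussian jitter.
randomEnsemble <- function(nFrames, nResidues, sd = 0.5) {
  base <- cbind(3.8 * seq_len(nResidues), 0, 0)
  co <- array(0, c(nFrames, nResidues, 3))
  for (f in seq_len(nFrames))
    co[f, , ] <- base + matrix(rnorm(nResidues * 3, sd = sd), nResidues, 3)
  ProteinEnsemble(co)
}

# Random valid DFM: symmetric, non-negative, zero diagonal.
randomDFM <- function(n, scale = 1) {
  m <- matrix(abs(rnorm(n * n, sd = scale)), n, n)
  m <- (m + t(m)) / 2
  diag(m) <- 0
  DFM(m)
}

# Random strictly monotone alignment with k columns.
randomAlignmentFixture <- function(na, nb, k) {
  MatchAlignment(sort(sample.int(na, k)), sort(sample.int(nb, k)))
}

# Naive double-loop DFM: materializes every pairwise distance series.
naiveDFM <- function(e, convention = "population") {
  co <- coords(e)
  nF <- dim(co)[1]; n <- dim(co)[2]
  F <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    d <- numeric(nF)
    for (f in seq_len(nF))
      d[f] <- sqrt(sum((co[f, i, ] - co[f, j, ])^2))
    v <- if (convention == "population") mean((d - mean(d))^2) else var(d)
    F[i, j] <- sqrt(v)
  }
  F
}

# Naive O(k^2) alignment score: explicit double loop over column pairs.
naiveAlignmentScore <- function(Fa, Fb, aln, params = ScoreParams()) {
  ma <- dfmMatrix(Fa); mb <- dfmMatrix(Fb)
  p <- alignmentPairs(aln)
  k <- nrow(p)
  s <- 0
  if (k >= 2)
    for (i in seq_len(k - 1)) for (j in (i + 1):k)
      s <- s + pms(ma[p[i, 1], p[j, 1]], mb[p[i, 2], p[j, 2]], params)
  s
}

# Random 3D rotation matrix (QR of a Gaussian matrix, det +1).
randomRotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# Apply an independent random rigid motion to every frame.
rigidlyPerturb <- function(e) {
  co <- coords(e)
  for (f in seq_len(dim(co)[1])) {
    R <- randomRotation()
    tr <- rnorm(3, sd = 10)
    co[f, , ] <- sweep(co[f, , ] %*% t(R), 2, -tr)
  }
  ProteinEnsemble(co, residueLabels(e))
}

# Multi-model PDB text for given coordinates (frames x residues x 3).
pdbText <- function(co, resids = NULL) {
  nF <- dim(co)[1]; n <- dim(co)[2]
  if (is.null(resids)) resids <- rep("ALA", n)
  lines <- character(0)
  for (f in seq_len(nF)) {
    lines <- c(lines, sprintf("MODEL     %4d", f))
    for (i in seq_len(n))
      lines <- c(lines, sprintf(
        "ATOM  %5d  CA  %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
        i, resids[i], i, co[f, i, 1], co[f, i, 2], co[f, i, 3]))
    lines <- c(lines, "ENDMDL")
  }
  c(lines, "END")
}

# Tiny calibrated EVD model for p-value tests (shared, built once).
tinyEVDModel <- function() {
  if (!is.null(.fixtureCache$evd)) return(.fixtureCache$evd)
  refs <- syntheticReferenceSet(5, nResidues = 24, nFrames = 200, seed = 401)
  m <- calibrateEVD(refs, config = SAConfig(nRestarts = 2),
                    subSizes = c(10, 16), seed = 402)
  .fixtureCache$evd <- m
  m
}

.fixtureCache <- new.env()
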