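test_that("multi-model PDB files parse into frame x residue x 3 coordinates", {
  set.seed(1)
  co <- round(array(rnorm(3 * 4 * 3, sd = 5), c(3, 4, 3)), 3)
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(pdbText(co), f)
  e <- readEnsemble(f)
  expect_s4_class(e, "ProteinEnsemble")
  expect_equal(dim(coords(e)), c(3, 4, 3))
  expect_equal(coords(e), co, tolerance = 1e-12)
  expect_equal(residueLabels(e), paste0("ALA", 1:4))
})

test_that("residues lacking a C-alpha are dropped with a warning", {
  set.seed(2)
  co <- round(array(rnorm(2 * 3 * 3, sd = 5), c(2, 3, 3)), 3)
  txt <- pdbText(co)
  # demote residue 2's CA to a CB in every model
  txt <- sub("^(ATOM  .....)  CA  (ALA A   2.*)$", "\\1  CB  \\2", txt)
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(txt, f)
  expect_warning(e <- readEnsemble(f), "dropped")
  expect_equal(nResidues(e), 2)
  expect_equal(residueLabels(e), c("ALA1", "ALA3"))
})

test_that("plain-text ensemble tables round-trip exactly", {
  set.seed(3)
  e <- randomEnsemble(4, 6)
  f <- withr::local_tempfile(fileext = ".txt")
  writeEnsembleText(e, f)
  e2 <- readEnsemble(f)
  expect_identical(coords(e2), coords(e))
  # reader is order-preserving
  expect_equal(residueLabels(e2), paste0("R", 1:6))
})

test_that("degenerate ensembles are rejected with validation errors", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("#frames=1 residues=3", rep("0 0 0", 3)), f)
  expect_error(readEnsemble(f), "at least 2")
  writeLines(c("#frames=2 residues=1", rep("0 0 0", 2)), f)
  expect_error(readEnsemble(f), "at least 2")
  writeLines(c("#frames=2 residues=2", rep("0 0 0", 3)), f)
  expect_error(readEnsemble(f), "expected 12 coordinate values")
  writeLines("not an ensemble", f)
  expect_error(readEnsemble(f), "plain-text ensemble")
})

test_that("DFM TSV round-trips preserve values and labels", {
  set.seed(4)
  d <- randomDFM(9)
  d@labels <- paste0("GLY", 1:9)
  f <- withr::local_tempfile(fileext = ".tsv")
  writeDFM(d, f)
  d2 <- readDFM(f)
  expect_equal(dfmMatrix(d2), dfmMatrix(d), tolerance = 1e-12)
  expect_equal(residueLabels(d2), residueLabels(d))
  # zero matrix round-trips exactly
  z <- DFM(matrix(0, 3, 3))
  writeDFM(z, f)
  expect_identical(unname(dfmMatrix(readDFM(f))), matrix(0, 3, 3))
})

test_that("invalid DFM files and matrices are rejected", {
  m <- matrix(c(0, 1, 2, 0), 2, 2)  # asymmetric
  expect_error(DFM(m), "symmetric")
  expect_error(DFM(matrix(c(0, -1, -1, 0), 2, 2)), "non-negative")
  expect_error(DFM(matrix(c(1, 2, 2, 1), 2, 2)), "diagonal")
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("\tA\tB", "A\t0\t1", "B\t2\t0"), f)
  expect_error(readDFM(f), "symmetric")
  writeLines(c("\tA\tB", "A\t0\t1"), f)
  expect_error(readDFM(f), "square")
})

test_that("alignment files round-trip with 0-based on-disk indices", {
  aln <- MatchAlignment(c(1, 3, 7), c(2, 4, 5))
  f <- withr::local_tempfile(fileext = ".tsv")
  writeAlignment(aln, f)
  raw <- read.table(f, header = TRUE, sep = "\t")
  expect_equal(raw$res_a, c(0, 2, 6))  # 0-based externally
  aln2 <- readAlignment(f)
  expect_equal(alignmentPairs(aln2), alignmentPairs(aln))
  # scored alignment carries its SMS column
  Fa <- randomDFM(8); Fb <- randomDFM(8)
  sc <- scoreAlignment(Fa, Fb, aln)
  writeAlignment(sc, f)
  aln3 <- readAlignment(f)
  expect_equal(attr(aln3, "pms_sum"), sc@sms, tolerance = 1e-12)
})

test_that("gapped pairwise sequence text yields the monotone match columns", {
  aln <- readPairwiseAlignmentText("AC-DE", "AKL-E")
  expect_equal(alignmentPairs(aln),
               cbind(a = c(1L, 2L, 4L), b = c(1L, 2L, 4L)))
  expect_error(readPairwiseAlignmentText("AB", "ABC"), "equal length")
})

test_that("MatchAlignment enforces strict monotonicity", {
  expect_error(MatchAlignment(c(1, 1), c(2, 3)), "strictly increasing")
  expect_error(MatchAlignment(c(1, 2), c(3, 3)), "strictly increasing")
  expect_error(MatchAlignment(c(2, 1), c(1, 2)), "strictly increasing")
  expect_silent(MatchAlignment(integer(0), integer(0)))
})
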