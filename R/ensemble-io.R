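#' Read a conformational ensemble
#'
#' Reads multi-frame C-alpha coordinates of one protein chain from a
#' multi-model PDB file (`MODEL`/`ENDMDL` records), a DCD trajectory (with a
#' PDB topology file), or the package's plain-text ensemble table. One
#' coordinate triple per residue per frame is returned, in file order.
#' Residues lacking a C-alpha are dropped with a warning; for duplicated
#' alternate locations the first wins. Frames are never superposed: the
#' fingerprint computed downstream is invariant to per-frame rigid motion
#' and needs no reference structure.
#'
#' The plain-text dialect is a header line `#frames=<F> residues=<N>`
#' followed by `F` blocks of `N` whitespace-separated `x y z` lines
#' (Angstrom). See [writeEnsembleText()].
#'
#' @param path input file.
#' @param topology PDB structure file providing the topology for a DCD
#'   trajectory; ignored for other formats.
#' @param selection bio3d atom-selection keyword used on structure formats
#'   (default `"calpha"`; the fingerprint is defined on C-alpha distances
#'   but finer selections are accepted).
#' @param format one of `"auto"`, `"pdb"`, `"dcd"`, `"text"`; `"auto"`
#'   infers from the file extension (falling back to the text dialect).
#' @param frameInterval optional time between frames (ps), stored as
#'   metadata.
#' @return A [ProteinEnsemble-class].
#' @examples
#' f <- tempfile(fileext = ".txt")
#' e <- generateEnsemble(SynthSpec(5, 10, seed = 1))
#' writeEnsembleText(e, f)
#' readEnsemble(f)
#' @export
readEnsemble <- function(path, topology = NULL, selection = "calpha",
                         format = c("auto", "pdb", "dcd", "text"),
                         frameInterval = NA_real_) {
  format <- match.arg(format)
  if (!file.exists(path))
    stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, pdb = "pdb", ent = "pdb", dcd = "dcd", "text")
  }
  switch(format,
    pdb = readEnsemblePDB(path, selection, frameInterval),
    dcd = readEnsembleDCD(path, topology, selection, frameInterval),
    text = readEnsembleText(path, frameInterval)
  )
}

readEnsemblePDB <- function(path, selection, frameInterval) {
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)),
    error = function(e)
      stop("cannot parse multi-model PDB '", path,
           "' (models with inconsistent residue sets?): ",
           conditionMessage(e), call. = FALSE))
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  sel <- bio3d::atom.select(pdb, selection, verbose = FALSE)
  at <- pdb$atom[sel$atom, , drop = FALSE]
  if (nrow(at) == 0)
    stop("no atoms match selection '", selection, "' in ", path)
  # first alternate location wins
  key <- paste(at$chain, at$resno, at$insert, sep = "|")
  keep <- !duplicated(key)
  at <- at[keep, , drop = FALSE]
  atomIdx <- sel$atom[keep]
  # warn about residues present in the file but lacking a selected atom
  allKey <- unique(paste(pdb$atom$chain, pdb$atom$resno, pdb$atom$insert,
                         sep = "|"))
  missing <- setdiff(allKey, unique(key))
  if (length(missing))
    warning(length(missing), " residue(s) without a '", selection,
            "' atom were dropped")
  cols <- as.vector(t(outer(atomIdx, 1:3, function(a, k) 3 * (a - 1) + k)))
  co <- xyz[, cols, drop = FALSE]
  nF <- nrow(co); nR <- nrow(at)
  arr <- aperm(array(t(co), c(3, nR, nF)), c(3, 2, 1))
  labels <- paste0(at$resid, at$resno)
  validateFrames(nF, nR, path)
  ProteinEnsemble(arr, labels, frameInterval)
}

readEnsembleDCD <- function(path, topology, selection, frameInterval) {
  if (is.null(topology))
    stop("a PDB topology file is required to read a DCD trajectory")
  top <- bio3d::read.pdb(topology, verbose = FALSE)
  sel <- bio3d::atom.select(top, selection, verbose = FALSE)
  at <- top$atom[sel$atom, , drop = FALSE]
  key <- paste(at$chain, at$resno, at$insert, sep = "|")
  keep <- !duplicated(key)
  at <- at[keep, , drop = FALSE]
  atomIdx <- sel$atom[keep]
  xyz <- bio3d::read.dcd(path, verbose = FALSE)
  cols <- as.vector(t(outer(atomIdx, 1:3, function(a, k) 3 * (a - 1) + k)))
  if (max(cols) > ncol(xyz))
    stop("topology '", topology, "' has more atoms than trajectory '",
         path, "'")
  co <- xyz[, cols, drop = FALSE]
  nF <- nrow(co); nR <- nrow(at)
  arr <- aperm(array(t(co), c(3, nR, nF)), c(3, 2, 1))
  validateFrames(nF, nR, path)
  ProteinEnsemble(arr, paste0(at$resid, at$resno), frameInterval)
}

readEnsembleText <- function(path, frameInterval = NA_real_) {
  hdr <- readLines(path, n = 1L)
  m <- regmatches(hdr,
    regexec("^#frames=([0-9]+)\\s+residues=([0-9]+)\\s*$", hdr))[[1]]
  if (length(m) != 3)
    stop("not a plain-text ensemble table (expected header ",
         "'#frames=<F> residues=<N>'): ", path)
  nF <- as.integer(m[2]); nR <- as.integer(m[3])
  validateFrames(nF, nR, path)
  vals <- scan(path, what = numeric(), skip = 1, quiet = TRUE)
  if (length(vals) != nF * nR * 3)
    stop("expected ", nF * nR * 3, " coordinate values, found ",
         length(vals), " in ", path)
  # file layout: frame-major blocks of nR rows x 3 columns
  arr <- aperm(array(vals, c(3, nR, nF)), c(3, 2, 1))
  ProteinEnsemble(arr, frameInterval = frameInterval)
}

validateFrames <- function(nF, nR, path) {
  if (nF < 2)
    stop("ensemble '", path, "' has ", nF,
         " frame(s); at least 2 are required")
  if (nR < 2)
    stop("ensemble '", path, "' has ", nR,
         " residue(s) after selection; at least 2 are required")
  invisible(TRUE)
}

#' Write an ensemble as a plain-text table
#'
#' Writes the package's plain-text ensemble dialect: a header line
#' `#frames=<F> residues=<N>` followed by `F` blocks of `N` lines `x y z`
#' (Angstrom, full double precision so that a read/write round trip is
#' exact).
#'
#' @param e a [ProteinEnsemble-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeEnsembleText <- function(e, path) {
  stopifnot(is(e, "ProteinEnsemble"))
  d <- dim(e@coords)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#frames=%d residues=%d", d[1], d[2]), con)
  for (f in seq_len(d[1])) {
    block <- e@coords[f, , , drop = TRUE]
    writeLines(sprintf("%.17g %.17g %.17g",
                       block[, 1], block[, 2], block[, 3]), con)
  }
  invisible(path)
}

#' Write / read a DFM as TSV
#'
#' The DFM file is tab-separated with residue labels as the first row and
#' first column and the symmetric matrix as body, written at full double
#' precision (round trips reproduce the matrix to at least 12 significant
#' digits). On read, squareness, symmetry (1e-9 relative tolerance),
#' non-negativity and the zero diagonal are re-validated.
#'
#' @param dfm a [DFM-class].
#' @param path file path.
#' @return `writeDFM` returns `path` invisibly; `readDFM` returns a
#'   [DFM-class].
#' @export
writeDFM <- function(dfm, path) {
  stopifnot(is(dfm, "DFM"))
  m <- dfm@mat
  lab <- dfm@labels
  body <- apply(m, 1, function(r) paste(sprintf("%.17g", r), collapse = "\t"))
  lines <- c(paste(c("", lab), collapse = "\t"),
             paste(lab, body, sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname writeDFM
#' @export
readDFM <- function(path) {
  if (!file.exists(path))
    stop("file not found: ", path)
  tb <- utils::read.table(path, sep = "\t", header = TRUE, row.names = 1,
                          check.names = FALSE, colClasses = "character")
  m <- apply(as.matrix(tb), c(1, 2), as.numeric)
  if (nrow(m) != ncol(m))
    stop("DFM file is not square: ", path)
  if (any(is.na(m)))
    stop("DFM file contains non-numeric entries: ", path)
  DFM(m, labels = rownames(tb), source = path)  # constructor validates
}

#' Write / read an alignment as TSV
#'
#' Columns are `col_index`, `res_a`, `res_b` (all 0-based, for
#' interoperability), `label_a`, `label_b`, and optionally `pms_sum` (the
#' SMS of each column when a [ScoredAlignment-class] is given).
#'
#' @param aln a [MatchAlignment-class] or [ScoredAlignment-class].
#' @param path file path.
#' @param labelsA,labelsB residue labels of the two proteins (defaults to
#'   generic `R<i>` labels).
#' @return `writeAlignment` returns `path` invisibly; `readAlignment`
#'   returns a [MatchAlignment-class] (any `pms_sum` column is attached as
#'   attribute `"pms_sum"`).
#' @export
writeAlignment <- function(aln, path, labelsA = NULL, labelsB = NULL) {
  sms <- NULL
  if (is(aln, "ScoredAlignment")) {
    sms <- aln@sms
    aln <- aln@alignment
  }
  stopifnot(is(aln, "MatchAlignment"))
  k <- length(aln@a)
  la <- if (is.null(labelsA)) paste0("R", aln@a) else labelsA[aln@a]
  lb <- if (is.null(labelsB)) paste0("R", aln@b) else labelsB[aln@b]
  df <- data.frame(col_index = seq_len(k) - 1L,
                   res_a = aln@a - 1L, res_b = aln@b - 1L,
                   label_a = la, label_b = lb)
  if (!is.null(sms)) df$pms_sum <- sms
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeAlignment
#' @export
readAlignment <- function(path) {
  if (!file.exists(path))
    stop("file not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE)
  if (!all(c("res_a", "res_b") %in% names(df)))
    stop("alignment file needs columns res_a and res_b: ", path)
  aln <- MatchAlignment(df$res_a + 1L, df$res_b + 1L)
  if ("pms_sum" %in% names(df))
    attr(aln, "pms_sum") <- df$pms_sum
  aln
}

#' Match columns of a gapped pairwise alignment text
#'
#' Parses two gapped sequences of equal length (gap character `-`) into the
#' monotone match-column alignment of their residues: column `k` pairs the
#' i-th non-gap position of A with the j-th non-gap position of B wherever
#' both rows are non-gap. This is how prior sequence or structure
#' alignments enter the scoring machinery.
#'
#' @param seqA,seqB gapped sequence strings of equal length.
#' @return A [MatchAlignment-class].
#' @examples
#' readPairwiseAlignmentText("AC-DE", "AKL-E")
#' @export
readPairwiseAlignmentText <- function(seqA, seqB) {
  ca <- strsplit(seqA, "")[[1]]
  cb <- strsplit(seqB, "")[[1]]
  if (length(ca) != length(cb))
    stop("gapped sequences must have equal length")
  ia <- cumsum(ca != "-")
  ib <- cumsum(cb != "-")
  keep <- ca != "-" & cb != "-"
  MatchAlignment(ia[keep], ib[keep])
}
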