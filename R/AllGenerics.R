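#' Number of frames in an ensemble
#' @param x a [ProteinEnsemble-class].
#' @return integer scalar.
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' Number of residues
#' @param x a [ProteinEnsemble-class] or [DFM-class].
#' @return integer scalar.
#' @export
setGeneric("nResidues", function(x) standardGeneric("nResidues"))

#' Residue labels
#' @param x a [ProteinEnsemble-class] or [DFM-class].
#' @return character vector.
#' @export
setGeneric("residueLabels", function(x) standardGeneric("residueLabels"))

#' Coordinate array of an ensemble
#' @param x a [ProteinEnsemble-class].
#' @return `(n_frames, n_residues, 3)` array, Angstrom.
#' @export
setGeneric("coords", function(x) standardGeneric("coords"))

#' Underlying matrix of a DFM
#' @param x a [DFM-class].
#' @return square numeric matrix (Angstrom).
#' @export
setGeneric("dfmMatrix", function(x) standardGeneric("dfmMatrix"))

#' Compute the Dynamic Fingerprint Matrix of an ensemble
#' @param x a [ProteinEnsemble-class].
#' @param ... passed to methods.
#' @return a [DFM-class].
#' @export
setGeneric("computeDFM", function(x, ...) standardGeneric("computeDFM"))

#' Match columns of an alignment
#' @param x a [MatchAlignment-class] or [ScoredAlignment-class].
#' @return two-column integer matrix (1-based indices in A and B).
#' @export
setGeneric("alignmentPairs", function(x) standardGeneric("alignmentPairs"))

#' Number of match columns
#' @param x a [MatchAlignment-class] or [ScoredAlignment-class].
#' @return integer scalar.
#' @export
setGeneric("alignmentLength", function(x) standardGeneric("alignmentLength"))

#' Total alignment score
#' @param x a [ScoredAlignment-class] or [AlignResult-class].
#' @return numeric scalar.
#' @export
setGeneric("totalScore", function(x) standardGeneric("totalScore"))

#' Single Match Score values
#' @param x a [ScoredAlignment-class] or [AlignResult-class].
#' @return numeric vector, one value per match column.
#' @export
setGeneric("smsValues", function(x) standardGeneric("smsValues"))

#' Best scored alignment of a search
#' @param x an [AlignResult-class].
#' @return a [ScoredAlignment-class].
#' @export
setGeneric("bestAlignment", function(x) standardGeneric("bestAlignment"))
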