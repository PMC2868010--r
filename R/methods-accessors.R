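#' @describeIn ProteinEnsemble number of frames
#' @param x,object a `ProteinEnsemble`.
#' @aliases nFrames,ProteinEnsemble-method
#' @export
setMethod("nFrames", "ProteinEnsemble", function(x) dim(x@coords)[1])

#' @describeIn ProteinEnsemble number of residues
#' @export
setMethod("nResidues", "ProteinEnsemble", function(x) dim(x@coords)[2])

#' @describeIn ProteinEnsemble residue labels
#' @export
setMethod("residueLabels", "ProteinEnsemble", function(x) x@residueLabels)

#' @describeIn ProteinEnsemble coordinate array
#' @export
setMethod("coords", "ProteinEnsemble", function(x) x@coords)

setMethod("show", "ProteinEnsemble", function(object) {
  cat("ProteinEnsemble:", dim(object@coords)[1], "frames x",
      dim(object@coords)[2], "residues (C-alpha)\n")
  if (!is.na(object@frameInterval))
    cat("  frame interval:", object@frameInterval, "ps\n")
  cat("  residues:", paste(utils::head(object@residueLabels, 4), collapse = " "),
      if (length(object@residueLabels) > 4) "..." else "", "\n")
})

#' @describeIn DFM matrix dimension
#' @param x,object a `DFM`.
#' @export
setMethod("nResidues", "DFM", function(x) nrow(x@mat))

#' @describeIn DFM residue labels
#' @export
setMethod("residueLabels", "DFM", function(x) x@labels)

#' @describeIn DFM underlying matrix
#' @export
setMethod("dfmMatrix", "DFM", function(x) {
  m <- x@mat
  dimnames(m) <- list(x@labels, x@labels)
  m
})

setMethod("show", "DFM", function(object) {
  n <- nrow(object@mat)
  cat("DFM:", n, "x", n, "distance-fluctuation matrix (Angstrom)\n")
  if (n > 0) {
    off <- object@mat[upper.tri(object@mat)]
    if (length(off))
      cat(sprintf("  off-diagonal range: [%.4g, %.4g], mean %.4g\n",
                  min(off), max(off), mean(off)))
  }
  if (nzchar(object@source)) cat("  source:", object@source, "\n")
})

#' @describeIn MatchAlignment the match columns
#' @param x,object a `MatchAlignment`.
#' @export
setMethod("alignmentPairs", "MatchAlignment", function(x)
  cbind(a = x@a, b = x@b))

#' @describeIn MatchAlignment number of match columns
#' @export
setMethod("alignmentLength", "MatchAlignment", function(x) length(x@a))

setMethod("show", "MatchAlignment", function(object) {
  k <- length(object@a)
  cat("MatchAlignment with", k, "match columns\n")
  if (k) {
    sh <- min(k, 6)
    cat("  ", paste(sprintf("(%d,%d)", object@a[1:sh], object@b[1:sh]),
                    collapse = " "), if (k > sh) "..." else "", "\n")
  }
})

#' @describeIn ScoredAlignment the alignment
#' @param x,object a `ScoredAlignment`.
#' @export
setMethod("alignmentPairs", "ScoredAlignment", function(x)
  alignmentPairs(x@alignment))

#' @describeIn ScoredAlignment number of match columns
#' @export
setMethod("alignmentLength", "ScoredAlignment", function(x)
  length(x@alignment@a))

#' @describeIn ScoredAlignment total score
#' @export
setMethod("totalScore", "ScoredAlignment", function(x) x@totalScore)

#' @describeIn ScoredAlignment per-column SMS
#' @export
setMethod("smsValues", "ScoredAlignment", function(x) x@sms)

setMethod("show", "ScoredAlignment", function(object) {
  k <- length(object@alignment@a)
  cat(sprintf("ScoredAlignment: %d columns, total score %.4f\n",
              k, object@totalScore))
  if (k)
    cat(sprintf("  SMS range: [%.4f, %.4f]\n", min(object@sms), max(object@sms)))
})

#' @describeIn AlignResult best scored alignment
#' @param x,object an `AlignResult`.
#' @export
setMethod("bestAlignment", "AlignResult", function(x) x@best)

#' @describeIn AlignResult total score of the best alignment
#' @export
setMethod("totalScore", "AlignResult", function(x) x@best@totalScore)

#' @describeIn AlignResult SMS values of the best alignment
#' @export
setMethod("smsValues", "AlignResult", function(x) x@best@sms)

setMethod("show", "AlignResult", function(object) {
  cat(sprintf("AlignResult: best score %.4f over %d restart(s)\n",
              object@best@totalScore, length(object@perRestartScores)))
  cat("  per-restart best scores:",
      paste(sprintf("%.3f", object@perRestartScores), collapse = ", "), "\n")
  cat(sprintf("  best alignment: %d columns\n", length(object@best@alignment@a)))
})

setMethod("show", "ScoreParams", function(object) {
  cat(sprintf(
    "ScoreParams: s+ = %g, s- = %g, cutoff t = %g, lambda = %g (relDiff: %s)\n",
    object@sPlus, object@sMinus, object@cutoff, object@lambda,
    object@relDiffMethod))
})

setMethod("show", "SAConfig", function(object) {
  pl <- if (is.na(object@plateauMinAccepts)) "auto (50 * min(nA, nB))"
        else format(object@plateauMinAccepts)
  cat("SAConfig:\n")
  cat("  chi0:", object@chi0, " cooling:", object@coolingFactor,
      " stop acceptance:", object@stopAcceptance, "\n")
  cat("  plateau accepts:", pl, " stall plateaus:", object@stallPlateaus,
      "\n")
  cat("  restarts:", object@nRestarts,
      " prune negative SMS:", object@pruneNegativeSMS, "\n")
})

setMethod("show", "EVDModel", function(object) {
  cat("EVDModel (Gumbel null of optimal alignment scores)\n")
  cat(sprintf("  mu(L)    = %.6g + %.6g * %s\n", object@muCoeffs[1],
              object@muCoeffs[2],
              if (object@sizeTransform == "log") "log(L)" else "L"))
  cat(sprintf("  sigma(L) = %.6g + %.6g * %s\n", object@sigmaCoeffs[1],
              object@sigmaCoeffs[2],
              if (object@sizeTransform == "log") "log(L)" else "L"))
  cat("  calibration points:", nrow(object@calibrationPoints),
      " L range: [", min(object@calibrationPoints$L), ",",
      max(object@calibrationPoints$L), "]\n")
})

setMethod("show", "SynthSpec", function(object) {
  cat("SynthSpec:", object@nResidues, "residues x", object@nFrames,
      "frames,", object@backbone, "backbone\n")
  cat(sprintf("  mobility: [%.3g, %.3g] A, coupling %.3g, cutoff %.3g A, ar1 %.3g\n",
              min(object@mobility), max(object@mobility), object@coupling,
              object@contactCutoff, object@ar1))
})
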