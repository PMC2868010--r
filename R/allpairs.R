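#' All-versus-all dynamic similarity of a set of proteins
#'
#' Aligns every unordered pair of fingerprints with [anneal()], converts
#' each optimal score to a p-value under the calibrated Gumbel null, and
#' returns the score matrix, the p-value matrix (both lower-triangular)
#' and the edge list of the dynamic-similarity graph, in which two
#' proteins are connected iff their dynamics are significantly similar
#' (`p < threshold`). Pairs are processed in sorted-lexicographic name
#' order with a per-pair seed derived from `seed` and the pair names, so
#' runs are reproducible and restartable and the reported value of a pair
#' does not depend on input order.
#'
#' @param dfms named list of [DFM-class] objects, or a character vector of
#'   DFM TSV paths (names default to basenames). An unreadable file is
#'   reported in the `failures` element and the run continues.
#' @param params a [ScoreParams-class].
#' @param config an [SAConfig-class] (its `seed` slot is ignored; use
#'   `seed`).
#' @param model an [EVDModel-class] from [calibrateEVD()].
#' @param threshold significance threshold on the p-value (default 0.05).
#' @param seed master seed for the batch.
#' @return list with elements `scores` (lower-triangular matrix), `pvalues`
#'   (lower-triangular matrix), `edges` (data frame `a`, `b`, `score`,
#'   `p`), and `failures` (character vector of unreadable inputs).
#' @examples
#' refs <- syntheticReferenceSet(4, nResidues = 20, nFrames = 150, seed = 1)
#' names(refs) <- paste0("p", 1:4)
#' @export
runAllVsAll <- function(dfms, params = ScoreParams(), config = SAConfig(),
                        model, threshold = 0.05, seed = 1) {
  failures <- character(0)
  if (is.character(dfms)) {
    paths <- dfms
    nm <- if (!is.null(names(paths))) names(paths) else basename(paths)
    dfms <- list()
    for (i in seq_along(paths)) {
      d <- tryCatch(readDFM(paths[i]), error = function(e) {
        warning("skipping unreadable DFM '", paths[i], "': ",
                conditionMessage(e))
        NULL
      })
      if (is.null(d)) failures <- c(failures, paths[i])
      else dfms[[nm[i]]] <- d
    }
  }
  if (length(dfms) < 2)
    stop("at least 2 readable DFMs are required")
  if (is.null(names(dfms)) || any(!nzchar(names(dfms))))
    names(dfms) <- paste0("protein", seq_along(dfms))
  ord <- order(names(dfms))
  dfms <- dfms[ord]
  nm <- names(dfms)
  n <- length(dfms)
  scores <- matrix(NA_real_, n, n, dimnames = list(nm, nm))
  pvals <- matrix(NA_real_, n, n, dimnames = list(nm, nm))
  edges <- list()
  for (j in seq_len(n - 1L)) for (i in (j + 1L):n) {
    cfg <- config
    cfg@seed <- deriveSeed(seed, paste(nm[j], nm[i], sep = "|"))
    res <- anneal(dfms[[j]], dfms[[i]], params, cfg)
    s <- res@best@totalScore
    p <- suppressWarnings(
      pValue(s, nResidues(dfms[[j]]), nResidues(dfms[[i]]), model))
    scores[i, j] <- s
    pvals[i, j] <- p
    if (isSignificant(p, threshold))
      edges[[length(edges) + 1L]] <-
        data.frame(a = nm[j], b = nm[i], score = s, p = p)
  }
  edges <- if (length(edges)) do.call(rbind, edges)
           else data.frame(a = character(0), b = character(0),
                           score = numeric(0), p = numeric(0))
  list(scores = scores, pvalues = pvals, edges = edges, failures = failures)
}

#' Write the dynamic-similarity graph
#'
#' Writes the significant-pair edge list as TSV and, optionally, as a
#' Graphviz DOT file.
#'
#' @param result the list returned by [runAllVsAll()].
#' @param path output path (TSV); a DOT file is written alongside with
#'   extension `.gv` when `dot = TRUE`.
#' @param dot also write Graphviz DOT (default `TRUE`).
#' @return `path`, invisibly.
#' @export
writeSimilarityGraph <- function(result, path, dot = TRUE) {
  utils::write.table(result$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (dot) {
    nodes <- rownames(result$scores)
    lines <- c("graph dynamic_similarity {",
               paste0("  \"", nodes, "\";"),
               sprintf("  \"%s\" -- \"%s\" [label=\"p=%.2g\"];",
                       result$edges$a, result$edges$b, result$edges$p),
               "}")
    writeLines(lines, sub("\\.[^.]*$", "", path) %+% ".gv")
  }
  invisible(path)
}

`%+%` <- function(x, y) paste0(x, y)
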