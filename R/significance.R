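EULER_GAMMA <- 0.57721566490153286

#' Maximum-likelihood Gumbel fit
#'
#' Fits a type I extreme value distribution for maxima,
#' `P(X <= x) = exp(-exp(-(x - mu) / sigma))`, to a sample of optimal
#' alignment scores. Starting values come from the method of moments
#' (`sigma0 = sd * sqrt(6) / pi`, `mu0 = mean - gamma * sigma0` with
#' Euler-Mascheroni `gamma`), refined by BFGS on the negative
#' log-likelihood with `sigma` parameterized on the log scale.
#'
#' @param scores numeric vector of at least 10 finite scores.
#' @return named numeric vector `c(mu = , sigma = )`.
#' @examples
#' x <- 5 - 2 * log(-log(runif(1000)))  # Gumbel(5, 2) draws
#' fitGumbel(x)
#' @export
fitGumbel <- function(scores) {
  scores <- as.numeric(scores)
  if (length(scores) < 10 || any(!is.finite(scores)))
    stop("fitGumbel needs >= 10 finite scores")
  s0 <- stats::sd(scores)
  if (s0 == 0)
    stop("degenerate sample: all scores are equal")
  sigma0 <- s0 * sqrt(6) / pi
  mu0 <- mean(scores) - EULER_GAMMA * sigma0
  nll <- function(par) {
    mu <- par[1]; sigma <- exp(par[2])
    z <- (scores - mu) / sigma
    length(scores) * log(sigma) + sum(z) + sum(exp(-z))
  }
  fit <- stats::optim(c(mu0, log(sigma0)), nll, method = "BFGS")
  c(mu = fit$par[1], sigma = exp(fit$par[2]))
}

# Draw from Gumbel(mu, sigma) via inverse CDF.
rGumbel <- function(n, mu, sigma) mu - sigma * log(-log(stats::runif(n)))

evdParamsAt <- function(model, L) {
  Lt <- if (model@sizeTransform == "log") log(L) else L
  list(mu = model@muCoeffs[1] + model@muCoeffs[2] * Lt,
       sigma = model@sigmaCoeffs[1] + model@sigmaCoeffs[2] * Lt)
}

#' Calibrate the size-dependent Gumbel null model
#'
#' Measures the background distribution of optimal dynamic similarity
#' scores between unrelated reference proteins. For every unordered pair of
#' reference DFMs and every requested submatrix size `s`, a random
#' contiguous principal submatrix of each fingerprint is extracted
#' (contiguity preserves the banded near-diagonal texture of real
#' fingerprints) and aligned with [anneal()]; each optimal score is
#' recorded at `L = s^2`. Scores are binned by `L`, a Gumbel is fitted per
#' bin with [fitGumbel()], and ordinary least squares lines for `mu(L)` and
#' `sigma(L)` are fitted through the per-bin estimates.
#'
#' @param referenceDFMs list of at least 4 [DFM-class] objects of unrelated
#'   proteins, each at least as large as `max(subSizes)` residues (e.g.
#'   from [syntheticReferenceSet()], or user-supplied real fingerprints).
#' @param params a [ScoreParams-class].
#' @param config an [SAConfig-class] used for each alignment (its `seed` is
#'   ignored; use `seed`).
#' @param subSizes integer vector of submatrix sizes to calibrate at.
#' @param seed RNG seed for submatrix placement and annealing.
#' @param sizeTransform regress on `L` (`"identity"`, default) or `log(L)`.
#' @param minPerBin minimum scores required per size bin (default 10).
#' @return An [EVDModel-class].
#' @seealso [pValue()], [syntheticReferenceSet()]
#' @export
calibrateEVD <- function(referenceDFMs, params = ScoreParams(),
                         config = SAConfig(), subSizes = c(20, 40, 60),
                         seed = NA, sizeTransform = c("identity", "log"),
                         minPerBin = 10L) {
  sizeTransform <- match.arg(sizeTransform)
  nref <- length(referenceDFMs)
  if (nref < 4)
    stop("at least 4 reference DFMs are required")
  sizes <- vapply(referenceDFMs, nResidues, numeric(1))
  withSeed(seed, {
    recs <- list()
    for (s in sort(subSizes)) {
      for (i in seq_len(nref - 1L)) for (j in (i + 1L):nref) {
        if (sizes[i] < s || sizes[j] < s) next
        subA <- randomPrincipalSubmatrix(referenceDFMs[[i]], s)
        subB <- randomPrincipalSubmatrix(referenceDFMs[[j]], s)
        cfg <- config; cfg@seed <- NA_real_  # stay on the ambient stream
        res <- anneal(subA, subB, params, cfg)
        recs[[length(recs) + 1L]] <-
          data.frame(L = s * s, size = s, score = res@best@totalScore)
      }
    }
    df <- do.call(rbind, recs)
    pts <- lapply(split(df, df$L), function(bin) {
      if (nrow(bin) < minPerBin)
        stop("size bin L = ", bin$L[1], " has only ", nrow(bin),
             " scores (need >= ", minPerBin, ")")
      g <- fitGumbel(bin$score)
      data.frame(L = bin$L[1], mu = g[["mu"]], sigma = g[["sigma"]],
                 n = nrow(bin))
    })
    cp <- do.call(rbind, pts)
    rownames(cp) <- NULL
    Lt <- if (sizeTransform == "log") log(cp$L) else cp$L
    if (nrow(cp) > 1) {
      muCo <- unname(stats::coef(stats::lm(cp$mu ~ Lt)))
      sigmaCo <- unname(stats::coef(stats::lm(cp$sigma ~ Lt)))
    } else {
      # single size bin: constant model (no size dependence estimable)
      muCo <- c(cp$mu[1], 0)
      sigmaCo <- c(cp$sigma[1], 0)
    }
    model <- new("EVDModel",
                 muCoeffs = muCo,
                 sigmaCoeffs = sigmaCo,
                 sizeTransform = sizeTransform,
                 calibrationPoints = cp)
    if (any(diff(cp$mu[order(cp$L)]) < 0))
      warning("fitted mu(L) is not non-decreasing over the calibrated range")
    model
  })
}

# Random contiguous principal submatrix of size s (random start offset).
randomPrincipalSubmatrix <- function(dfm, s) {
  m <- asDFMMatrix(dfm)
  n <- nrow(m)
  if (s > n)
    stop("submatrix size ", s, " exceeds DFM size ", n)
  start <- sample.int(n - s + 1L, 1L)
  idx <- start:(start + s - 1L)
  DFM(m[idx, idx, drop = FALSE], labels = dfmLabelsOf(dfm)[idx])
}

#' p-value of a dynamic similarity score
#'
#' Upper-tail Gumbel probability of observing a score at least `S` between
#' two unrelated proteins of lengths `La` and `Lb`:
#' `p = 1 - exp(-exp(-(S - mu(L)) / sigma(L)))` with `L = La * Lb` and
#' `mu`, `sigma` from the calibrated null model. Requesting an `L` outside
#' the calibrated range triggers an extrapolation warning (not an error).
#'
#' @param S raw optimal alignment score (vectorized).
#' @param La,Lb lengths of the two proteins (residues).
#' @param model an [EVDModel-class].
#' @return p-value(s) in `[0, 1]`, strictly decreasing in `S`.
#' @export
pValue <- function(S, La, Lb, model) {
  stopifnot(is(model, "EVDModel"), La >= 1, Lb >= 1)
  L <- La * Lb
  rng <- range(model@calibrationPoints$L)
  if (L < rng[1] || L > rng[2])
    warning("L = ", L, " is outside the calibrated range [", rng[1], ", ",
            rng[2], "]; extrapolating")
  par <- evdParamsAt(model, L)
  if (par$sigma <= 0)
    stop("model gives non-positive sigma(L) at L = ", L,
         "; outside usable model range")
  p <- 1 - exp(-exp(-(S - par$mu) / par$sigma))
  pmin(pmax(p, 0), 1)
}

#' Significance call
#'
#' @param p p-value(s) in `[0, 1]`.
#' @param threshold significance threshold (default 0.05).
#' @return logical: `TRUE` iff `p < threshold` (strict).
#' @examples
#' isSignificant(c(0.049, 0.05, 0.34))
#' @export
isSignificant <- function(p, threshold = 0.05) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  p < threshold
}

#' Serialize / load an EVD null model as JSON
#'
#' Coefficients are written at full double precision so that reloading the
#' model reproduces p-values bitwise.
#'
#' @param model an [EVDModel-class].
#' @param path file path.
#' @return `writeEVDModel` returns `path` invisibly; `readEVDModel` returns
#'   the [EVDModel-class].
#' @export
writeEVDModel <- function(model, path) {
  stopifnot(is(model, "EVDModel"))
  obj <- list(mu_coeffs = model@muCoeffs,
              sigma_coeffs = model@sigmaCoeffs,
              size_transform = model@sizeTransform,
              calibration_points = model@calibrationPoints)
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeEVDModel
#' @export
readEVDModel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("EVDModel",
      muCoeffs = as.numeric(obj$mu_coeffs),
      sigmaCoeffs = as.numeric(obj$sigma_coeffs),
      sizeTransform = obj$size_transform,
      calibrationPoints = as.data.frame(obj$calibration_points))
}
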