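#' Fit the sigmoidal contrast-response function
#'
#' Least-squares fit of `f(x) = a * (1 / (1 + exp(k * x)) - 0.5)` to
#' response-versus-contrast data; `f(0) = 0` for any parameters. Under this
#' sign convention responses that increase with contrast are fitted with
#' `k < 0`; use `abs(k)` when comparing steepness. For fixed `k` the model is
#' linear in `a`, so `a` is profiled out and the optimizer works on `k`
#' alone, multi-started at k in \{+-1, +-5, +-20\}. The model is invariant
#' under the simultaneous sign flip `(a, k) -> (-a, -k)`; fits are
#' canonicalized to `a >= 0` so that parameter distributions are unimodal.
#'
#' @param contrasts contrast values (>= 3 distinct).
#' @param responses responses (same length).
#' @return list: `a`, `k`, `loss` (residual sum of squares), `converged`
#'   (FALSE when `k` is unidentifiable, e.g. all-zero responses).
#' @export
fitContrastSigmoid <- function(contrasts, responses) {
  stopifnot(length(contrasts) == length(responses))
  if (length(unique(contrasts)) < 3L)
    stop("need at least 3 distinct contrast values")
  x <- as.numeric(contrasts); y <- as.numeric(responses)
  if (all(y == 0))
    return(list(a = 0, k = NA_real_, loss = 0, converged = FALSE))
  profileA <- function(k) {
    g <- 1 / (1 + exp(k * x)) - 0.5
    s2 <- sum(g^2)
    if (s2 < 1e-14) return(list(a = 0, loss = sum(y^2)))
    a <- sum(g * y) / s2
    list(a = a, loss = sum((y - a * g)^2))
  }
  lossK <- function(k) profileA(k)$loss
  best <- NULL
  for (k0 in c(-20, -5, -1, 1, 5, 20)) {
    fit <- suppressWarnings(stats::optim(k0, lossK, method = "BFGS",
                                         control = list(reltol = 1e-14)))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  pa <- profileA(best$par)
  a <- pa$a; k <- best$par
  if (a < 0) { a <- -a; k <- -k }   # canonical branch of the sign symmetry
  list(a = a, k = k, loss = pa$loss, converged = best$convergence == 0)
}

#' Bootstrap the sigmoid fit over resampling units
#'
#' Resamples units (flies or ROIs) with replacement `nBoot` times, refitting
#' [fitContrastSigmoid()] on the pooled observations of each resample, to
#' obtain the distribution of the fit parameters `(a, k)`.
#'
#' @param contrasts,responses observations (pooled over units).
#' @param units unit label per observation (>= 2 distinct units; a single
#'   unit triggers a degenerate-bootstrap warning).
#' @param nBoot number of resamples (50 by convention).
#' @param seed RNG seed.
#' @return a [SigmoidFit-class] object.
#' @export
bootstrapSigmoid <- function(contrasts, responses, units, nBoot = 50L,
                             seed = 1L) {
  stopifnot(length(units) == length(contrasts))
  uu <- unique(units)
  if (length(uu) < 2L)
    warning("degenerate bootstrap: only one resampling unit")
  point <- fitContrastSigmoid(contrasts, responses)
  byUnit <- split(seq_along(units), units)
  bootA <- numeric(nBoot); bootK <- numeric(nBoot)
  withSeed(seed, for (b in seq_len(nBoot)) {
    idx <- unlist(byUnit[sample.int(length(byUnit), replace = TRUE)],
                  use.names = FALSE)
    fit <- fitContrastSigmoid(contrasts[idx], responses[idx])
    bootA[b] <- fit$a; bootK[b] <- fit$k
  })
  new("SigmoidFit", a = point$a, k = point$k, loss = point$loss,
      bootA = bootA, bootK = bootK, nBoot = as.integer(nBoot),
      converged = point$converged, seed = as.integer(seed))
}

setMethod("show", "SigmoidFit", function(object) {
  cat(sprintf("SigmoidFit: a = %.4g, k = %.4g (RSS %.4g)%s\n", object@a,
              object@k, object@loss,
              if (!object@converged) " [not converged]" else ""))
  if (object@nBoot > 0)
    cat(sprintf("  %d bootstrap resamples: a in [%.4g, %.4g], k in [%.4g, %.4g]\n",
                object@nBoot, min(object@bootA), max(object@bootA),
                min(object@bootK), max(object@bootK)))
})

## plug-in discrete mutual information (base 2) from a contingency table
plugInMi <- function(tab) {
  p <- tab / sum(tab)
  px <- rowSums(p); py <- colSums(p)
  nz <- p > 0
  sum(p[nz] * log2(p[nz] / outer(px, py)[nz]))
}

equalOccupancyBins <- function(values, nBins) {
  r <- rank(values, ties.method = "average")
  pmin(pmax(ceiling(r * nBins / length(values)), 1L), nBins)
}

#' Mutual information between luminance level and response
#'
#' Plug-in discrete mutual information (bits) between the stimulus level and
#' the response binned into equal-occupancy bins (as many bins as levels by
#' default). Optionally a shuffle-based bias estimate (mean MI over label
#' permutations) is subtracted; the corrected value is clamped at 0.
#'
#' @param labels discrete stimulus levels (one per sample).
#' @param responses sustained response values (one per sample).
#' @param nBins number of response bins (default: number of levels).
#' @param shuffleCorrect subtract the shuffle bias estimate.
#' @param nShuffle number of label shuffles for the bias estimate.
#' @param seed RNG seed for the shuffles.
#' @return mutual information in bits (>= 0).
#' @export
mutualInformation <- function(labels, responses, nBins = NULL,
                              shuffleCorrect = FALSE, nShuffle = 20L,
                              seed = 1L) {
  stopifnot(length(labels) == length(responses))
  labels <- factor(labels)
  if (nlevels(labels) < 2L) {
    warning("single stimulus level: mutual information is 0")
    return(0)
  }
  if (is.null(nBins)) nBins <- nlevels(labels)
  bins <- equalOccupancyBins(responses, nBins)
  mi <- plugInMi(table(labels, factor(bins, levels = seq_len(nBins))))
  if (shuffleCorrect) {
    bias <- withSeed(seed, mean(vapply(seq_len(nShuffle), function(s) {
      plugInMi(table(sample(labels), factor(bins, levels = seq_len(nBins))))
    }, numeric(1))))
    mi <- max(mi - bias, 0)
  }
  mi
}

#' Non-linearity index of a luminance-response relation
#'
#' Pearson correlation minus Spearman rank correlation between luminance and
#' response, bounded in `[-2, 2]`. Exactly zero for strictly linear
#' relationships; deviates from zero when the relation is monotone but
#' curved (|index| grows with curvature).
#'
#' @param luminance,responses paired values (>= 3 points, non-constant).
#' @return dimensionless index.
#' @export
nonlinearityIndex <- function(luminance, responses) {
  stopifnot(length(luminance) == length(responses))
  if (length(luminance) < 3L) stop("need at least 3 points")
  if (sd(luminance) == 0 || sd(responses) == 0)
    stop("undefined correlation: constant input")
  cor(luminance, responses, method = "pearson") -
    cor(luminance, responses, method = "spearman")
}

#' Straight-line fit of response against log luminance
#'
#' Least squares fit of `V = a * log(luminance) + b` (natural log by
#' default; the base only rescales `a`). With `normalize = TRUE` the
#' responses are min-max scaled to `[0, 1]` before fitting, the convention
#' for comparing slopes across modalities.
#'
#' @param x luminances (> 0, >= 2 distinct).
#' @param y responses.
#' @param normalize min-max scale `y` first.
#' @param base logarithm base.
#' @return named vector `c(a = slope, b = intercept)` with attribute
#'   `logBase`.
#' @export
fitLogSlope <- function(x, y, normalize = FALSE, base = exp(1)) {
  if (any(x <= 0)) stop("luminances must be positive")
  if (length(unique(x)) < 2L) stop("need >= 2 distinct luminances")
  if (normalize) {
    rng <- range(y)
    y <- if (diff(rng) == 0) rep(0, length(y)) else (y - rng[1]) / diff(rng)
  }
  fit <- lm(y ~ log(x, base = base))
  out <- c(a = unname(coef(fit)[2]), b = unname(coef(fit)[1]))
  attr(out, "logBase") <- base
  out
}
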