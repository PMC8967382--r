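#' Phenomenological lamina-neuron response parameters
#'
#' Point-model of an L1/L2/L3 axon terminal: the response drive is a transient
#' contrast component (exponentially decaying impulses at luminance
#' transitions, amplitude proportional to the signed Weber contrast of the
#' transition) plus a sustained luminance component
#' `S = 1 - (1 - I/I_max)^gamma` (increasing in luminance; `gamma > 1`
#' amplifies differences between dim levels), multiplied by `polarity` and
#' convolved with a normalized exponential calcium-indicator kernel.
#' Polarity -1 (the lamina default) hyperpolarizes to light: dF/F correlates
#' negatively with luminance and dim stimuli give the largest signal.
#'
#' Presets are qualitative, not measured quantities: `L1` transient plus
#' linear sustained component, `L2` transient-only, `L3` weakly transient
#' with a strongly dim-amplifying sustained component (`gamma = 3`).
#'
#' @param cellType "L1", "L2", "L3" or "custom".
#' @param polarity -1 (hyperpolarize to ON, the lamina default) or +1.
#' @param wC transient (contrast) gain.
#' @param tauT transient decay time constant (s).
#' @param wL sustained (luminance) gain.
#' @param gamma sustained nonlinearity exponent (>= 1).
#' @param tauCa calcium kernel time constant (s).
#' @param noiseSd additive white trace noise (response units).
#' @param pOffscreen fraction of ROIs generated with inverted polarity
#'   (receptive field off the stimulation screen), in `[0, 0.5)`.
#' @param satContrast tanh saturation scale for the transition contrast:
#'   amplitudes follow `satContrast * tanh(C_W / satContrast)` (near-linear
#'   in Weber contrast below the scale, compressive above it, as real
#'   lamina transients are; steps out of darkness would otherwise produce
#'   unbounded amplitudes). `NULL` for strictly linear amplitudes.
#' @return an object of class `LmcParams`.
#' @export
lmcParams <- function(cellType = c("L1", "L2", "L3", "custom"),
                      polarity = -1, wC = NULL, tauT = 0.25, wL = NULL,
                      gamma = NULL, tauCa = 0.3, noiseSd = 0.05,
                      pOffscreen = 0.1, satContrast = 4) {
  cellType <- match.arg(cellType)
  preset <- switch(cellType,
    L1 = list(wC = 1.0, wL = 0.8, gamma = 1),
    L2 = list(wC = 1.2, wL = 0.0, gamma = 1),
    L3 = list(wC = 0.3, wL = 1.0, gamma = 3),
    custom = list(wC = 1.0, wL = 0.5, gamma = 1))
  if (is.null(wC)) wC <- preset$wC
  if (is.null(wL)) wL <- preset$wL
  if (is.null(gamma)) gamma <- preset$gamma
  stopifnot(tauT > 0, tauCa > 0, noiseSd >= 0,
            pOffscreen >= 0, pOffscreen < 0.5, polarity %in% c(-1, 1))
  structure(list(cellType = cellType, polarity = polarity, wC = wC,
                 tauT = tauT, wL = wL, gamma = gamma, tauCa = tauCa,
                 noiseSd = noiseSd, pOffscreen = pOffscreen,
                 satContrast = satContrast),
            class = "LmcParams")
}

## recursive exponential smoothing == convolution with a normalized
## discrete exponential kernel of time constant tau; initialized at the
## first sample so a constant input stays constant (no warm-up transient)
expKernelSmooth <- function(x, tau, dt) {
  a <- exp(-dt / tau)
  as.numeric(stats::filter((1 - a) * x, a, method = "recursive",
                           init = x[1]))
}

## transient drive: decaying impulses at luminance transitions, amplitude =
## signed Weber contrast with a dark-adaptation floor on the denominator
transientDrive <- function(lum, dt, tauT, imax, epsFrac = 0.05,
                           satContrast = NULL) {
  imp <- numeric(length(lum))
  dI <- diff(lum)
  jump <- which(dI != 0)
  if (length(jump)) {
    amp <- dI[jump] / pmax(lum[jump], epsFrac * imax)
    if (!is.null(satContrast)) amp <- satContrast * tanh(amp / satContrast)
    imp[jump + 1L] <- amp
  }
  as.numeric(stats::filter(imp, exp(-dt / tauT), method = "recursive"))
}

## noiseless drive of one ROI for a given luminance series (response units,
## before the calcium kernel)
lmcDrive <- function(params, lum, imax) {
  s <- 1 - (1 - lum / imax)^params$gamma
  params$wL * s
}

#' Construct an RoiTraceSet
#'
#' @param raw ROI x time matrix of raw fluorescence.
#' @param time acquisition times (s), strictly increasing.
#' @param roiData per-ROI metadata (`fly`, `roi`, ...).
#' @param sampleRate Hz.
#' @param clean optional noise-free response matrix (ground truth).
#' @param extra list merged into `metadata()`.
#' @return a [RoiTraceSet-class] object.
#' @export
roiTraceSet <- function(raw, time, roiData, sampleRate, clean = NULL,
                        extra = list()) {
  assays <- list(raw = raw)
  if (!is.null(clean)) assays$clean <- clean
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = assays,
    rowData = S4Vectors::DataFrame(roiData),
    colData = S4Vectors::DataFrame(time = time))
  md <- c(list(sampleRate = sampleRate), extra)
  obj <- new("RoiTraceSet", se)
  S4Vectors::metadata(obj) <- md
  validObject(obj)
  obj
}

#' Accessors for RoiTraceSet objects
#' @param x an [RoiTraceSet-class] object.
#' @return `rawTraces`/`dffTraces`/`cleanTraces`: ROI x time matrices
#'   (`dffTraces` errors before [computeDff()]); `traceTime`: acquisition
#'   times; `roiInfo`: per-ROI metadata as a data.frame; `traceSampleRate`:
#'   Hz.
#' @export
rawTraces <- function(x) SummarizedExperiment::assay(x, "raw")

#' @rdname rawTraces
#' @export
dffTraces <- function(x) {
  if (!"dff" %in% SummarizedExperiment::assayNames(x))
    stop("dF/F not computed yet; run computeDff() first")
  SummarizedExperiment::assay(x, "dff")
}

#' @rdname rawTraces
#' @export
cleanTraces <- function(x) SummarizedExperiment::assay(x, "clean")

#' @rdname rawTraces
#' @export
traceTime <- function(x) x$time

#' @rdname rawTraces
#' @export
roiInfo <- function(x) as.data.frame(SummarizedExperiment::rowData(x))

#' @rdname rawTraces
#' @export
traceSampleRate <- function(x) S4Vectors::metadata(x)$sampleRate

#' Simulate calcium recordings of model lamina neurons
#'
#' Generates raw fluorescence traces of `nFlies * roisPerFly` model ROIs
#' responding to a stimulus protocol. Each ROI's drive is
#' `polarity * (wC * T(t) + wL * S(t))` convolved with a normalized
#' exponential calcium kernel (see [lmcParams()]), scaled by mild lognormal
#' fly- and ROI-level gain variability, embedded in an arbitrary fluorescence
#' baseline, and corrupted by additive white noise. A fraction `pOffscreen`
#' of ROIs receives inverted polarity (off-screen receptive fields). For
#' edge-motion protocols each ROI sees the luminance at its own random
#' azimuth; full-field protocols are seen identically by all ROIs.
#'
#' @param params an `LmcParams` object from [lmcParams()].
#' @param protocol a [StimulusProtocol-class] object.
#' @param nFlies,roisPerFly cohort size (roisPerFly >= 1).
#' @param seed RNG seed; output is bitwise reproducible.
#' @param sampleRate acquisition rate (Hz; two-photon range ~10-15).
#' @param flyGainSd,roiGainSd lognormal sd of fly/ROI gain variability.
#' @return a [RoiTraceSet-class] with assays `raw` and `clean` (noise-free
#'   response in response units) and ground-truth `rowData` columns
#'   (`offscreen`, `gain`, `rfAzimuth`, `baseF`).
#' @export
simulateLmc <- function(params, protocol, nFlies = 5L, roisPerFly = 10L,
                        seed = 1L, sampleRate = 12, flyGainSd = 0.1,
                        roiGainSd = 0.1) {
  stopifnot(inherits(params, "LmcParams"))
  if (roisPerFly < 1L) stop("roisPerFly must be >= 1")
  dt <- 1 / sampleRate
  total <- totalDuration(protocol)
  times <- seq(0, total - dt, by = dt)
  imax <- iMax(protocol@calibration)
  hasEdges <- any(protocol@epochs$kind == "edge_motion")
  lumShared <- if (!hasEdges) sessionLuminance(protocol, times) else NULL

  nRoi <- nFlies * roisPerFly
  withSeed(seed, {
    flyGain <- exp(rnorm(nFlies, 0, flyGainSd))
    roiGain <- exp(rnorm(nRoi, 0, roiGainSd))
    offscreen <- runif(nRoi) < params$pOffscreen
    rfAz <- runif(nRoi, 0, protocol@arenaSpan * 0.999)
    baseF <- runif(nRoi, 80, 120)
    raw <- matrix(0, nRoi, length(times))
    clean <- matrix(0, nRoi, length(times))
    for (i in seq_len(nRoi)) {
      fly <- (i - 1L) %/% roisPerFly + 1L
      lum <- if (hasEdges) rfLuminance(protocol, rfAz[i], sampleRate)$luminance
             else lumShared
      drive <- params$wC *
        transientDrive(lum, dt, params$tauT, imax,
                       satContrast = params$satContrast) +
        lmcDrive(params, lum, imax)
      pol <- params$polarity * if (offscreen[i]) -1 else 1
      resp <- expKernelSmooth(pol * drive, params$tauCa, dt) *
        flyGain[fly] * roiGain[i]
      clean[i, ] <- resp
      raw[i, ] <- baseF[i] *
        (1 + resp + rnorm(length(times), 0, params$noiseSd))
    }
    roiData <- data.frame(
      fly = rep(seq_len(nFlies), each = roisPerFly),
      roi = seq_len(nRoi),
      cellType = params$cellType,
      offscreen = offscreen,
      gain = roiGain * flyGain[rep(seq_len(nFlies), each = roisPerFly)],
      rfAzimuth = rfAz, baseF = baseF)
    roiTraceSet(raw, times, roiData, sampleRate, clean = clean,
                extra = list(params = params, seed = seed,
                             protocolType = protocol@meta$type))
  })
}

setMethod("show", "RoiTraceSet", function(object) {
  ri <- roiInfo(object)
  cat(sprintf("RoiTraceSet: %d ROIs from %d flies, %d time points @ %g Hz\n",
              nrow(object), length(unique(ri$fly)), ncol(object),
              traceSampleRate(object)))
  cat("  assays:", paste(SummarizedExperiment::assayNames(object),
                         collapse = ", "), "\n")
})
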