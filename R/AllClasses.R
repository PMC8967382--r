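#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment assay assay<- assayNames rowData colData
#' @importFrom S4Vectors metadata metadata<- DataFrame
#' @importFrom stats approx cor lm coef median optimize quantile rnorm runif sd
#'   setNames aov anova pairwise.t.test t.test wilcox.test p.adjust complete.cases
#' @importFrom utils head tail write.csv
NULL

## ---------------------------------------------------------------------------
## Photometric calibration
## ---------------------------------------------------------------------------

#' Photometric calibration of a stimulation device
#'
#' Anchors the linear transform between measured luminance (cd/m^2) and photon
#' incidence per photoreceptor per second, together with the neutral-density
#' attenuation in the light path and the number of linearly spaced intensity
#' levels the device can display.
#'
#' @slot cdAtNativeMax luminance (cd/m^2) measured at the brightest native level.
#' @slot photonsAtNativeMax photon flux (photons s^-1 photoreceptor^-1) at that level.
#' @slot ndAttenuation dimensionless attenuation factor in (0, 1] applied by
#'   neutral-density filtering.
#' @slot nLedLevels integer count of linearly spaced intensity levels (>= 2).
#' @exportClass Calibration
setClass("Calibration",
  representation(
    cdAtNativeMax = "numeric",
    photonsAtNativeMax = "numeric",
    ndAttenuation = "numeric",
    nLedLevels = "integer"
  )
)

setValidity("Calibration", function(object) {
  msg <- character()
  if (length(object@cdAtNativeMax) != 1L || !is.finite(object@cdAtNativeMax) ||
      object@cdAtNativeMax <= 0)
    msg <- c(msg, "cdAtNativeMax must be a single positive number")
  if (length(object@photonsAtNativeMax) != 1L ||
      !is.finite(object@photonsAtNativeMax) || object@photonsAtNativeMax <= 0)
    msg <- c(msg, "photonsAtNativeMax must be a single positive number")
  if (length(object@ndAttenuation) != 1L || !is.finite(object@ndAttenuation) ||
      object@ndAttenuation <= 0 || object@ndAttenuation > 1)
    msg <- c(msg, "ndAttenuation must lie in (0, 1]")
  if (length(object@nLedLevels) != 1L || is.na(object@nLedLevels) ||
      object@nLedLevels < 2L)
    msg <- c(msg, "nLedLevels must be an integer >= 2")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Stimulus protocol
## ---------------------------------------------------------------------------

#' An ordered visual stimulation protocol
#'
#' The single source of truth for stimulus/response alignment. `epochs` is a
#' table of the distinct epochs (one row each) with columns `label`, `kind`
#' (one of static, edge_motion, flash, step, interval), `duration` (s),
#' `lumBg`, `lumFg` (photon fluxes; `lumFg` is the edge/step/flash level,
#' `lumBg` the background, `NA` where not applicable), `direction` (+1, -1 or
#' 0) and `speed` (deg/s, `NA` for non-motion epochs). `presentation` is the
#' full ordered sequence of epoch row indices actually shown; epoch intervals
#' on the session time axis are half-open `[t_start, t_end)`.
#'
#' @slot epochs data.frame of distinct epochs (see description).
#' @slot presentation integer vector of epoch indices in presentation order.
#' @slot calibration a [Calibration-class] object.
#' @slot arenaSpan azimuthal span of the display (degrees).
#' @slot nEdges number of simultaneous edges for edge protocols.
#' @slot seed integer seed used for any randomized ordering (NA if none).
#' @slot meta list of free-form protocol metadata (type tag, level fractions...).
#' @exportClass StimulusProtocol
setClass("StimulusProtocol",
  representation(
    epochs = "data.frame",
    presentation = "integer",
    calibration = "Calibration",
    arenaSpan = "numeric",
    nEdges = "integer",
    seed = "integer",
    meta = "list"
  )
)

setValidity("StimulusProtocol", function(object) {
  msg <- character()
  need <- c("label", "kind", "duration", "lumBg", "lumFg", "direction", "speed")
  if (!all(need %in% names(object@epochs)))
    msg <- c(msg, paste("epochs must have columns:", paste(need, collapse = ", ")))
  else {
    if (anyDuplicated(object@epochs$label))
      msg <- c(msg, "epoch labels must be unique")
    if (any(object@epochs$duration <= 0))
      msg <- c(msg, "all epoch durations must be > 0")
    bad <- !object@epochs$kind %in% c("static", "edge_motion", "flash", "step", "interval")
    if (any(bad)) msg <- c(msg, "unknown epoch kind")
    mot <- object@epochs$kind == "edge_motion"
    if (any(mot & (is.na(object@epochs$speed) | object@epochs$direction == 0)))
      msg <- c(msg, "edge_motion epochs must carry a speed and a direction")
    imax <- iMax(object@calibration)
    lum <- c(object@epochs$lumBg, object@epochs$lumFg)
    lum <- lum[!is.na(lum)]
    if (any(lum < 0) || any(lum > imax * (1 + 1e-9)))
      msg <- c(msg, "epoch luminances must lie in [0, iMax(calibration)]")
  }
  if (length(object@presentation) &&
      (min(object@presentation) < 1L || max(object@presentation) > nrow(object@epochs)))
    msg <- c(msg, "presentation indexes epochs out of range")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## ROI traces (SummarizedExperiment-backed)
## ---------------------------------------------------------------------------

#' Per-fly, per-ROI fluorescence time series
#'
#' A [SummarizedExperiment::SummarizedExperiment] with ROIs as rows and time
#' points as columns. Assay `"raw"` holds background-subtracted fluorescence;
#' assay `"dff"` (present after [computeDff()]) holds dF/F0. `rowData` carries
#' per-ROI metadata (`fly`, `roi`, `cellType`, and for synthetic data the
#' ground-truth `offscreen` flag); `colData$time` is the strictly increasing
#' acquisition time in seconds.
#'
#' @exportClass RoiTraceSet
setClass("RoiTraceSet", contains = "SummarizedExperiment")

setValidity("RoiTraceSet", function(object) {
  msg <- character()
  if (!"raw" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'raw' is required")
  if (!"time" %in% colnames(SummarizedExperiment::colData(object)))
    msg <- c(msg, "colData must contain 'time'")
  else {
    tt <- object$time
    if (any(diff(tt) <= 0)) msg <- c(msg, "time must be strictly increasing")
  }
  if (!all(c("fly", "roi") %in% colnames(SummarizedExperiment::rowData(object))))
    msg <- c(msg, "rowData must contain 'fly' and 'roi'")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Trial-averaged responses
## ---------------------------------------------------------------------------

#' Trial-averaged, epoch-aligned responses at 10 Hz
#'
#' One mean trace per ROI per distinct epoch label, on an epoch-onset-aligned
#' time grid (default 10 Hz). `traces[[label]]` is an ROI x time matrix;
#' `stim[[label]]` is the aligned stimulus luminance series on the same grid.
#'
#' @slot epochs the epochs table of the protocol the averages refer to.
#' @slot order integer vector: canonical presentation order of one repeat
#'   (epoch indices), used to resolve "previous epoch" windows.
#' @slot traces named list of ROI x time matrices (one per epoch label).
#' @slot stim named list of numeric stimulus-luminance series.
#' @slot nTrials named integer: repetitions averaged per label.
#' @slot rate target sampling rate (Hz).
#' @slot roiData per-ROI metadata (same rows as each trace matrix).
#' @exportClass TrialAverage
setClass("TrialAverage",
  representation(
    epochs = "data.frame",
    order = "integer",
    traces = "list",
    stim = "list",
    nTrials = "integer",
    rate = "numeric",
    roiData = "data.frame"
  )
)

setValidity("TrialAverage", function(object) {
  msg <- character()
  if (!identical(sort(names(object@traces)), sort(names(object@stim))))
    msg <- c(msg, "traces and stim must cover the same epoch labels")
  if (length(object@rate) != 1L || object@rate <= 0)
    msg <- c(msg, "rate must be a single positive number")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Image stacks and ROI masks
## ---------------------------------------------------------------------------

#' A T x H x W imaging stack
#'
#' @slot frames numeric array, time x height x width, finite intensities.
#' @slot frameRate acquisition rate (Hz).
#' @exportClass ImageStack
setClass("ImageStack",
  representation(frames = "array", frameRate = "numeric"))

setValidity("ImageStack", function(object) {
  msg <- character()
  if (length(dim(object@frames)) != 3L || dim(object@frames)[1] < 1L)
    msg <- c(msg, "frames must be a T x H x W array with T >= 1")
  if (!all(is.finite(object@frames)))
    msg <- c(msg, "frame intensities must be finite")
  if (length(object@frameRate) != 1L || object@frameRate <= 0)
    msg <- c(msg, "frameRate must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' ROI pixel masks plus one background mask
#'
#' @slot rois list of logical H x W matrices, one per ROI, pairwise disjoint.
#' @slot background logical H x W matrix, the background pixel set.
#' @exportClass RoiMaskSet
setClass("RoiMaskSet",
  representation(rois = "list", background = "matrix"))

setValidity("RoiMaskSet", function(object) {
  msg <- character()
  if (!length(object@rois)) msg <- c(msg, "at least one ROI mask required")
  dims <- unique(lapply(c(object@rois, list(object@background)), dim))
  if (length(dims) != 1L) msg <- c(msg, "all masks must share one frame shape")
  if (any(!vapply(object@rois, function(m) any(m), logical(1))))
    msg <- c(msg, "ROI masks must be non-empty")
  if (!any(object@background)) msg <- c(msg, "background mask must be non-empty")
  if (length(dims) == 1L && length(object@rois) > 1L) {
    tot <- Reduce(`+`, lapply(object@rois, function(m) m * 1L))
    if (max(tot) > 1L) msg <- c(msg, "ROI masks must be pairwise disjoint")
  }
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Behavior containers
## ---------------------------------------------------------------------------

#' Trial-aligned yaw velocity snippets from trackball sessions
#'
#' Each row of `yaw` is one trial of one fly, on the common time axis `time`
#' (seconds relative to motion onset; negative times cover the preceding
#' inter-trial interval and static pattern). Positive yaw means turning in the
#' stimulus direction for direction +1 trials (sign is as recorded, i.e. not
#' yet mirrored).
#'
#' @slot time numeric time axis (s, motion onset at 0).
#' @slot yaw trials x time matrix of yaw velocity (rad/s).
#' @slot trials data.frame: `fly`, `trial`, `label` (direction-free epoch tag),
#'   `direction`, `contrast`, `lumFg`.
#' @slot flies data.frame: `fly`, `genotype`, `forwardSpeed` (mm/s, baseline).
#' @slot sampleRate Hz.
#' @exportClass VelocityTraceSet
setClass("VelocityTraceSet",
  representation(
    time = "numeric", yaw = "matrix", trials = "data.frame",
    flies = "data.frame", sampleRate = "numeric"
  )
)

setValidity("VelocityTraceSet", function(object) {
  msg <- character()
  if (nrow(object@yaw) != nrow(object@trials))
    msg <- c(msg, "one trials row per yaw row required")
  if (ncol(object@yaw) != length(object@time))
    msg <- c(msg, "yaw columns must match time axis")
  if (!all(c("fly", "label", "direction") %in% names(object@trials)))
    msg <- c(msg, "trials must have fly, label, direction")
  if (length(msg)) msg else TRUE
})

#' Per-fly, per-epoch mirrored-mean turning responses
#'
#' @slot time numeric time axis shared with the source trials.
#' @slot traces (fly x epoch) x time matrix of mirror-aggregated mean yaw.
#' @slot info data.frame, one row per trace row: `fly`, `label`, `contrast`,
#'   `lumFg`, `nTrials`, and after [peakVelocity()] also `baseline` and `peak`.
#' @slot flies per-fly metadata incl. baseline forward speed.
#' @exportClass TurningResponse
setClass("TurningResponse",
  representation(
    time = "numeric", traces = "matrix", info = "data.frame",
    flies = "data.frame"
  )
)

## ---------------------------------------------------------------------------
## Fit and test results
## ---------------------------------------------------------------------------

#' Sigmoidal contrast-response fit with bootstrap distribution
#'
#' Parameters of `f(x) = a * (1/(1 + exp(k*x)) - 0.5)`: `a` scales the
#' response range, `k` sets the slope at zero contrast (responses increasing
#' with contrast have k < 0 under this sign convention; use `abs(k)` for
#' steepness comparisons).
#'
#' @slot a,k point estimates.
#' @slot loss residual sum of squares at the point estimate.
#' @slot bootA,bootK bootstrap samples of the two parameters.
#' @slot nBoot number of bootstrap resamples.
#' @slot converged logical flag from the optimizer.
#' @slot seed seed used for resampling (NA when not bootstrapped).
#' @exportClass SigmoidFit
setClass("SigmoidFit",
  representation(
    a = "numeric", k = "numeric", loss = "numeric",
    bootA = "numeric", bootK = "numeric", nBoot = "integer",
    converged = "logical", seed = "integer"
  )
)

setValidity("SigmoidFit", function(object) {
  msg <- character()
  if (length(object@bootA) != length(object@bootK))
    msg <- c(msg, "bootA and bootK must have equal length")
  if (length(object@bootA) != object@nBoot)
    msg <- c(msg, "bootstrap sample count must equal nBoot")
  if (length(object@loss) == 1L && is.finite(object@loss) && object@loss < 0)
    msg <- c(msg, "loss must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Per-fly log-luminance slope fits
#'
#' Straight-line fits `V = a * log(luminance) + b` per fly, with the mean
#' slope +/- SEM across flies (the fly is the statistical unit).
#'
#' @slot perFly data.frame: `fly`, `a`, `b`.
#' @slot meanSlope,semSlope mean and SEM of `a` across flies.
#' @slot logBase base of the logarithm used (affects the scale of `a` only).
#' @exportClass SlopeFit
setClass("SlopeFit",
  representation(
    perFly = "data.frame", meanSlope = "numeric", semSlope = "numeric",
    logBase = "numeric"
  )
)

#' Rescue-efficiency comparison with permutation null
#'
#' @slot luminances stimulus luminances the efficiencies refer to.
#' @slot eA,eB observed rescue efficiencies of the two rescue genotypes.
#' @slot diff observed eA - eB per luminance.
#' @slot nullDiff nPerm x nLuminance matrix of shuffled differences.
#' @slot p two-tailed permutation p-values (add-one convention).
#' @slot significant logical per luminance, after Bonferroni over luminances.
#' @slot alpha family-wise level; @slot seed permutation seed.
#' @exportClass EfficiencyResult
setClass("EfficiencyResult",
  representation(
    luminances = "numeric", eA = "numeric", eB = "numeric", diff = "numeric",
    nullDiff = "matrix", p = "numeric", significant = "logical",
    alpha = "numeric", seed = "integer"
  )
)

setValidity("EfficiencyResult", function(object) {
  if (any(object@p < 0 | object@p > 1)) "p-values must lie in [0, 1]" else TRUE
})

#' Result of comparing an experimental group against two genetic controls
#'
#' @slot test character: "t" or "wilcoxon" (or "anova" for omnibus harnesses).
#' @slot comparisons data.frame: `pair`, `pRaw`, `pCorrected`.
#' @slot correction the multiple-comparison correction applied.
#' @slot significantVsBoth TRUE only when the experimental group differs from
#'   BOTH controls at the corrected level.
#' @slot alpha significance level.
#' @slot details list (normality p-values, omnibus F/p, flags).
#' @exportClass GroupComparison
setClass("GroupComparison",
  representation(
    test = "character", comparisons = "data.frame", correction = "character",
    significantVsBoth = "logical", alpha = "numeric", details = "list"
  )
)

setValidity("GroupComparison", function(object) {
  cmp <- object@comparisons
  if (nrow(cmp) && any(cmp$pCorrected < cmp$pRaw - 1e-12))
    "corrected p-values must be >= raw p-values" else TRUE
})
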