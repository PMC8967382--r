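#' Construct an ImageStack / RoiMaskSet
#'
#' @param frames T x H x W numeric array.
#' @param frameRate acquisition rate (Hz).
#' @return an [ImageStack-class] object.
#' @export
imageStack <- function(frames, frameRate = 12) {
  if (is.null(dim(frames)) || length(dim(frames)) != 3L)
    stop("frames must be a T x H x W array")
  new("ImageStack", frames = frames, frameRate = as.numeric(frameRate))
}

#' @rdname imageStack
#' @param rois list of logical H x W matrices (pairwise disjoint, non-empty).
#' @param background logical H x W matrix of background pixels.
#' @return an [RoiMaskSet-class] object.
#' @export
roiMaskSet <- function(rois, background) {
  new("RoiMaskSet", rois = rois, background = background)
}

#' @export
setMethod("dim", "ImageStack", function(x) dim(x@frames))

## integer translation with constant fill
translateFrame <- function(m, dy, dx, fill = 0) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(fill, h, w)
  ys <- max(1, 1 + dy):min(h, h + dy)
  xs <- max(1, 1 + dx):min(w, w + dx)
  if (length(ys) && length(xs))
    out[ys, xs] <- m[ys - dy, xs - dx]
  out
}

#' Synthesize a calcium imaging movie with ground truth
#'
#' Each frame is a static baseline image plus, for every ROI, its mask scaled
#' by the ROI's response value at that frame, translated by a per-frame
#' integer shift and corrupted by white pixel noise. Serves as a test fixture
#' whose planted shifts and traces are known exactly.
#'
#' @param traces ROI x T matrix of response values (e.g. `cleanTraces()` of a
#'   simulated [RoiTraceSet-class]).
#' @param masks an [RoiMaskSet-class]; ROI count must match `traces` rows.
#' @param shifts T x 2 integer matrix of per-frame `(dy, dx)` displacements
#'   (default all zero).
#' @param noiseSd white pixel-noise sd.
#' @param seed RNG seed for baseline texture and noise.
#' @param frameRate Hz.
#' @param baseLevel,respScale fluorescence offset and response scaling.
#' @param anatomyGain static fluorescence of the ROI structures, in units of
#'   `respScale` (labeled neurons are bright at rest, so the anatomy
#'   dominates the response modulation and frames stay registrable).
#' @return list with `stack` ([ImageStack-class]) and ground truth
#'   (`shifts`, `traces`, `masks`, `baseline` image).
#' @export
simulateMovie <- function(traces, masks, shifts = NULL, noiseSd = 0,
                          seed = 1L, frameRate = 12, baseLevel = 100,
                          respScale = 50, anatomyGain = 5) {
  stopifnot(is(masks, "RoiMaskSet"))
  nRoi <- length(masks@rois)
  if (nrow(traces) != nRoi) stop("one trace row per ROI mask required")
  h <- nrow(masks@background); w <- ncol(masks@background)
  nT <- ncol(traces)
  if (is.null(shifts)) shifts <- matrix(0L, nT, 2L)
  if (nrow(shifts) != nT) stop("one (dy, dx) shift per frame required")
  withSeed(seed, {
    baseline <- baseLevel + 20 * matrix(runif(h * w), h, w) +
      outer(seq_len(h), seq_len(w), function(y, x) 0.1 * (x + y))
    for (i in seq_len(nRoi))
      baseline[masks@rois[[i]]] <- baseline[masks@rois[[i]]] +
        respScale * anatomyGain
    frames <- array(0, c(nT, h, w))
    for (t in seq_len(nT)) {
      f <- baseline
      for (i in seq_len(nRoi))
        f[masks@rois[[i]]] <- f[masks@rois[[i]]] + respScale * traces[i, t]
      f <- translateFrame(f, shifts[t, 1], shifts[t, 2], fill = baseLevel)
      if (noiseSd > 0) f <- f + matrix(rnorm(h * w, 0, noiseSd), h, w)
      frames[t, , ] <- f
    }
    list(stack = imageStack(frames, frameRate), shifts = shifts,
         traces = traces, masks = masks, baseline = baseline)
  })
}

corOrNeg <- function(a, b) {
  if (sd(a) == 0 || sd(b) == 0) return(-Inf)
  cor(a, b)
}

#' Register an image stack to its early-frame reference
#'
#' The reference is the pixelwise maximum-intensity projection of the first
#' 30 frames (all frames when fewer are available). Every frame is then
#' translated by the integer shift (within `maxShift` pixels) that maximizes
#' the normalized cross-correlation with the reference over the overlapping
#' region; candidate shifts are scanned from small to large displacement, so
#' ties resolve to the smallest motion.
#'
#' @param stack an [ImageStack-class] object.
#' @param maxShift shift search radius (pixels).
#' @return list with `stack` (aligned [ImageStack-class]) and `shifts`
#'   (T x 2 integer matrix of detected `(dy, dx)` frame displacements; the
#'   applied correction is their negation).
#' @export
registerStack <- function(stack, maxShift = 10L) {
  fr <- stack@frames
  nT <- dim(fr)[1]
  if (nT < 1L) stop("empty stack")
  nRef <- min(30L, nT)
  ref <- apply(fr[seq_len(nRef), , , drop = FALSE], c(2, 3), max)
  h <- dim(fr)[2]; w <- dim(fr)[3]
  cand <- expand.grid(dy = -maxShift:maxShift, dx = -maxShift:maxShift)
  cand <- cand[order(abs(cand$dy) + abs(cand$dx), abs(cand$dy)), ]
  shifts <- matrix(0L, nT, 2L)
  aligned <- array(0, dim(fr))
  for (t in seq_len(nT)) {
    f <- fr[t, , ]
    best <- -Inf; bdy <- 0L; bdx <- 0L
    for (r in seq_len(nrow(cand))) {
      dy <- cand$dy[r]; dx <- cand$dx[r]
      ys <- max(1, 1 + dy):min(h, h + dy)
      xs <- max(1, 1 + dx):min(w, w + dx)
      cc <- corOrNeg(as.vector(f[ys, xs]),
                     as.vector(ref[ys - dy, xs - dx]))
      if (cc > best + 1e-12) { best <- cc; bdy <- dy; bdx <- dx }
    }
    shifts[t, ] <- c(bdy, bdx)
    aligned[t, , ] <- translateFrame(f, -bdy, -bdx, fill = median(f))
  }
  list(stack = imageStack(aligned, stack@frameRate), shifts = shifts)
}

#' Extract background-subtracted ROI traces from a stack
#'
#' `raw_f(t)` = mean intensity over the ROI's pixels minus the mean over the
#' background pixels, per frame.
#'
#' @param stack an [ImageStack-class] object.
#' @param masks an [RoiMaskSet-class] object matching the frame shape.
#' @param roiData optional per-ROI metadata (default: one fly, sequential
#'   ROI ids).
#' @return an [RoiTraceSet-class] with assay `raw`.
#' @export
extractTraces <- function(stack, masks, roiData = NULL) {
  stopifnot(is(masks, "RoiMaskSet"))
  if (!identical(dim(masks@background), dim(stack@frames)[2:3]))
    stop("mask shape does not match frame shape")
  nT <- dim(stack@frames)[1]
  flat <- matrix(stack@frames, nrow = nT)   # frames as rows, pixels as cols
  pick <- function(mask) rowMeans(flat[, as.vector(mask), drop = FALSE])
  bg <- pick(masks@background)
  raw <- t(vapply(masks@rois, function(m) pick(m) - bg, numeric(nT)))
  if (is.null(roiData))
    roiData <- data.frame(fly = 1L, roi = seq_along(masks@rois))
  roiTraceSet(raw, time = (seq_len(nT) - 1L) / stack@frameRate,
              roiData = roiData, sampleRate = stack@frameRate)
}

#' Compute dF/F0 for every ROI trace
#'
#' `dff = (raw_f - F0) / F0`. With `f0Mode = "whole_trace_mean"` F0 is the
#' mean of the whole trace; with `"adaptation_mean"` it is the mean over the
#' time window `window` (seconds, default the first 30 s, the convention for
#' the adapted A/B step protocol).
#'
#' @param x an [RoiTraceSet-class] object.
#' @param f0Mode baseline mode, see above.
#' @param window `c(start, end)` seconds for `"adaptation_mean"`.
#' @return `x` with assay `dff` added.
#' @export
computeDff <- function(x, f0Mode = c("whole_trace_mean", "adaptation_mean"),
                       window = c(0, 30)) {
  f0Mode <- match.arg(f0Mode)
  raw <- rawTraces(x)
  f0 <- if (f0Mode == "whole_trace_mean") rowMeans(raw)
  else {
    sel <- x$time >= window[1] & x$time < window[2]
    if (!any(sel)) stop("adaptation window contains no samples")
    rowMeans(raw[, sel, drop = FALSE])
  }
  if (any(f0 == 0)) stop("degenerate baseline: F0 = 0 for some ROI")
  SummarizedExperiment::assay(x, "dff") <- sweep(raw, 1, f0, "-") / f0
  S4Vectors::metadata(x)$f0Mode <- f0Mode
  x
}

#' Keep only ROIs negatively correlated with the stimulus
#'
#' Computes the frame-wise stimulus luminance ([sessionLuminance()]) at the
#' trace sampling times and Spearman's rank correlation between each ROI's
#' dF/F and that series. ROIs with rho < 0 are kept; zero, positive or
#' undefined correlations (constant traces) are rejected.
#'
#' @param x an [RoiTraceSet-class] with a `dff` assay.
#' @param protocol the [StimulusProtocol-class] the traces were recorded under.
#' @return list: `kept` (subset [RoiTraceSet-class]), `rho` (all
#'   correlations, NA where undefined), `nRejected`, `rejectedRois` (row
#'   indices).
#' @export
filterRois <- function(x, protocol) {
  lum <- sessionLuminance(protocol, times = x$time)
  dff <- dffTraces(x)
  rho <- apply(dff, 1, function(tr) {
    if (sd(tr) == 0 || sd(lum) == 0) NA_real_
    else cor(tr, lum, method = "spearman")
  })
  keep <- !is.na(rho) & rho < 0
  list(kept = x[keep, ], rho = rho, nRejected = sum(!keep),
       rejectedRois = which(!keep))
}

## interpolate all ROI rows of `mat` (columns at `time`) onto `at`
interpRows <- function(mat, time, at) {
  at <- pmin(pmax(at, time[1]), time[length(time)])
  idx <- findInterval(at, time, rightmost.closed = TRUE)
  idx <- pmin(idx, length(time) - 1L)
  w <- (at - time[idx]) / (time[idx + 1L] - time[idx])
  mat[, idx, drop = FALSE] * rep(1 - w, each = nrow(mat)) +
    mat[, idx + 1L, drop = FALSE] * rep(w, each = nrow(mat))
}

#' Trial-average responses on an epoch-aligned 10 Hz grid
#'
#' For every distinct epoch label, the dF/F of each ROI is linearly
#' interpolated onto an epoch-onset-aligned grid at `targetRate` and averaged
#' across all presentations of that label. The aligned stimulus luminance is
#' interpolated the same way.
#'
#' @param x an [RoiTraceSet-class] with a `dff` assay.
#' @param protocol the [StimulusProtocol-class] defining the alignment.
#' @param targetRate grid rate (Hz, 10 by default).
#' @return a [TrialAverage-class] object.
#' @export
trialAverage <- function(x, protocol, targetRate = 10) {
  dff <- dffTraces(x)
  tt <- x$time
  tl <- protocolTimeline(protocol)
  ep <- protocol@epochs
  labels <- unique(tl$label)
  traces <- list(); stim <- list(); nTrials <- integer(0)
  lumAll <- NULL
  for (lab in labels) {
    rows <- which(tl$label == lab)
    dur <- ep$duration[ep$label == lab]
    tau <- seq(0, dur - 1e-9, by = 1 / targetRate)
    acc <- matrix(0, nrow(dff), length(tau))
    for (r in rows)
      acc <- acc + interpRows(dff, tt, tl$tStart[r] + tau)
    traces[[lab]] <- acc / length(rows)
    stim[[lab]] <- sessionLuminance(protocol, times = tl$tStart[rows[1]] + tau)
    nTrials[lab] <- length(rows)
  }
  new("TrialAverage", epochs = ep, order = protocol@presentation,
      traces = traces, stim = stim, nTrials = nTrials,
      rate = targetRate, roiData = roiInfo(x))
}

setMethod("show", "TrialAverage", function(object) {
  cat(sprintf("TrialAverage: %d epoch labels x %d ROIs @ %g Hz\n",
              length(object@traces), nrow(object@roiData), object@rate))
})

setMethod("show", "ImageStack", function(object) {
  d <- dim(object@frames)
  cat(sprintf("ImageStack: %d frames of %d x %d px @ %g Hz\n",
              d[1], d[2], d[3], object@frameRate))
})
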