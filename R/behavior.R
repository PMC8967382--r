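#' Recover rotation velocities from two-sensor trackball samples
#'
#' Inverts the sensor geometry of [composeBallSensors()]: yaw is the mean of
#' the two horizontal displacement rates divided by the ball radius; the two
#' vertical rates are mapped back to the horizontal rotation components by
#' inverting the 2 x 2 sensor-geometry matrix. Forward translation (mm/s) is
#' the ball radius times the rotation rate about the fly's left-right axis
#' (pitch).
#'
#' @param samples data.frame with columns `time, s1_h, s1_v, s2_h, s2_v`
#'   (displacement rates in mm/s).
#' @param kin a `BallKinematics` object (see [ballKinematics()]).
#' @return data.frame: `time`, `yaw` (rad/s), `forward` (mm/s), `pitch`,
#'   `roll` (rad/s).
#' @export
velocitiesFromSensors <- function(samples, kin = ballKinematics()) {
  need <- c("s1_h", "s1_v", "s2_h", "s2_v")
  stopifnot(all(need %in% names(samples)))
  th <- kin$sensorAzimuths * pi / 180
  M <- rbind(c(sin(th[1]), -cos(th[1])),
             c(sin(th[2]), -cos(th[2])))
  if (abs(det(M)) < 1e-9)
    stop("degenerate geometry: sensor azimuths coincide modulo 180 degrees")
  R <- kin$radius
  w <- t(solve(M, t(cbind(samples$s1_v, samples$s2_v)) / R))
  data.frame(time = samples$time,
             yaw = (samples$s1_h + samples$s2_h) / (2 * R),
             forward = R * w[, 1], pitch = w[, 1], roll = w[, 2])
}

#' Mirror-aggregate turning trials into per-fly epoch means
#'
#' Yaw traces of leftward-moving (direction -1) trials are negated and
#' averaged together with rightward trials of the same epoch, so that any
#' direction-independent turning bias cancels exactly when trial counts are
#' balanced. Epochs for which a fly saw only one direction yield a one-sided
#' mean with a warning.
#'
#' @param vts a [VelocityTraceSet-class] object.
#' @return a [TurningResponse-class]: one mirrored mean trace per fly per
#'   epoch.
#' @export
aggregateMirrored <- function(vts) {
  tr <- vts@trials
  key <- interaction(tr$fly, tr$label, drop = TRUE)
  groups <- split(seq_len(nrow(tr)), key)
  oneSided <- FALSE
  traces <- matrix(0, length(groups), length(vts@time))
  info <- data.frame(fly = integer(length(groups)),
                     label = character(length(groups)),
                     contrast = numeric(length(groups)),
                     lumFg = numeric(length(groups)),
                     nTrials = integer(length(groups)),
                     stringsAsFactors = FALSE)
  for (g in seq_along(groups)) {
    idx <- groups[[g]]
    if (length(unique(tr$direction[idx])) < 2L) oneSided <- TRUE
    mirrored <- vts@yaw[idx, , drop = FALSE] * tr$direction[idx]
    traces[g, ] <- colMeans(mirrored)
    info$fly[g] <- tr$fly[idx[1]]
    info$label[g] <- tr$label[idx[1]]
    info$contrast[g] <- tr$contrast[idx[1]]
    info$lumFg[g] <- tr$lumFg[idx[1]]
    info$nTrials[g] <- length(idx)
  }
  if (oneSided)
    warning("some fly x epoch groups contain only one motion direction; ",
            "their means are one-sided")
  new("TurningResponse", time = vts@time, traces = traces, info = info,
      flies = vts@flies)
}

#' Baseline and peak turning velocity per fly and epoch
#'
#' The baseline is the mean yaw over the last `baselineDur` seconds of the
#' inter-trial interval preceding the static pattern; the peak is the
#' maximum of (yaw - baseline) over the motion window shifted by `delay`
#' (response latency), i.e. `[delay, motionDur + delay]` relative to motion
#' onset.
#'
#' @param tr a [TurningResponse-class] from [aggregateMirrored()].
#' @param protocol the [StimulusProtocol-class] (supplies static and motion
#'   durations); pass `NULL` to use `staticDur`/`motionDur` directly.
#' @param delay response delay (s).
#' @param baselineDur baseline window length (s).
#' @param staticDur,motionDur fallback epoch durations (s).
#' @return `tr` with `baseline` and `peak` columns added to its `info`.
#' @export
peakVelocity <- function(tr, protocol = NULL, delay = 0.1, baselineDur = 0.2,
                         staticDur = 0.5, motionDur = 0.75) {
  if (!is.null(protocol)) {
    ep <- protocol@epochs
    if (any(ep$kind == "static")) staticDur <- ep$duration[ep$kind == "static"][1]
    if (any(ep$kind == "edge_motion"))
      motionDur <- ep$duration[ep$kind == "edge_motion"][1]
  }
  tt <- tr@time
  bSel <- tt >= -staticDur - baselineDur & tt < -staticDur
  pSel <- tt >= delay & tt <= motionDur + delay
  if (!any(bSel) || tt[length(tt)] < motionDur + delay - 1e-9)
    stop("trace does not cover the baseline or peak window")
  baseline <- rowMeans(tr@traces[, bSel, drop = FALSE])
  peak <- apply(tr@traces[, pSel, drop = FALSE] - baseline, 1, max)
  tr@info$baseline <- baseline
  tr@info$peak <- peak
  tr
}

#' Discard slow-walking flies
#'
#' Flies with a baseline forward walking speed below `threshold` (strictly
#' less than 2 mm/s by convention) are removed from the analysis.
#'
#' @param tr a [TurningResponse-class] object.
#' @param threshold rejection threshold (mm/s).
#' @return list: `kept` ([TurningResponse-class]), `rejectedFlies` (ids),
#'   `rejectedFraction`.
#' @export
rejectSlowFlies <- function(tr, threshold = 2) {
  keepFly <- tr@flies$fly[tr@flies$forwardSpeed >= threshold]
  sel <- tr@info$fly %in% keepFly
  kept <- new("TurningResponse", time = tr@time,
              traces = tr@traces[sel, , drop = FALSE],
              info = tr@info[sel, , drop = FALSE],
              flies = tr@flies[tr@flies$fly %in% keepFly, , drop = FALSE])
  rejected <- setdiff(tr@flies$fly, keepFly)
  list(kept = kept, rejectedFlies = rejected,
       rejectedFraction = length(rejected) / nrow(tr@flies))
}

#' Fit per-fly turning slopes against log luminance
#'
#' Fits `V = a * log(luminance) + b` to the peak velocities of each fly
#' (via [fitLogSlope()]) and summarizes the slope as mean +/- SEM across
#' flies.
#'
#' @param peaks data.frame with columns `fly`, `lum`, `peak`.
#' @param normalize min-max normalize each fly's peaks before fitting.
#' @param base logarithm base (natural by default).
#' @return a [SlopeFit-class] object.
#' @export
fitTurnSlope <- function(peaks, normalize = FALSE, base = exp(1)) {
  stopifnot(all(c("fly", "lum", "peak") %in% names(peaks)))
  perFly <- do.call(rbind, lapply(split(peaks, peaks$fly), function(d) {
    ab <- fitLogSlope(d$lum, d$peak, normalize = normalize, base = base)
    data.frame(fly = d$fly[1], a = ab["a"], b = ab["b"], row.names = NULL)
  }))
  n <- nrow(perFly)
  new("SlopeFit", perFly = perFly, meanSlope = mean(perFly$a),
      semSlope = if (n > 1) sd(perFly$a) / sqrt(n) else NA_real_,
      logBase = base)
}

setMethod("show", "SlopeFit", function(object) {
  cat(sprintf("SlopeFit: mean slope %.4g +/- %.4g SEM across %d flies (log base %.4g)\n",
              object@meanSlope, object@semSlope, nrow(object@perFly),
              object@logBase))
})

asPeakMatrix <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(all(c("fly", "lum", "peak") %in% names(x)))
    lum <- sort(unique(x$lum))
    flies <- unique(x$fly)
    m <- matrix(NA_real_, length(flies), length(lum),
                dimnames = list(NULL, as.character(lum)))
    for (i in seq_along(flies)) {
      d <- x[x$fly == flies[i], ]
      m[i, as.character(d$lum)] <- d$peak
    }
    if (anyNA(m)) stop("every fly needs a peak at every luminance")
    m
  } else as.matrix(x)
}

#' Fractional rescue efficiency per luminance
#'
#' `E = (mean(rescue) - mean(control-)) / (mean(control+) - mean(control-))`
#' on peak turning velocities, computed per luminance: 0 when the rescue
#' matches the transmission-deficient negative control, 1 when it matches
#' the heterozygous positive control.
#'
#' @param rescue,ctrlNeg,ctrlPos per-fly peak velocities: either fly x
#'   luminance matrices (shared luminance columns) or data.frames with
#'   `fly`, `lum`, `peak`.
#' @return named numeric vector of efficiencies per luminance.
#' @export
rescueEfficiency <- function(rescue, ctrlNeg, ctrlPos) {
  rescue <- asPeakMatrix(rescue); ctrlNeg <- asPeakMatrix(ctrlNeg)
  ctrlPos <- asPeakMatrix(ctrlPos)
  denom <- colMeans(ctrlPos) - colMeans(ctrlNeg)
  if (any(abs(denom) < .Machine$double.eps))
    stop("undefined efficiency: positive and negative controls coincide")
  (colMeans(rescue) - colMeans(ctrlNeg)) / denom
}

#' Permutation test for rescue-efficiency differences
#'
#' Tests, per luminance, whether the rescue efficiencies of two rescue
#' genotypes differ: flies of the two groups are shuffled `nPerm` times and
#' the efficiency difference recomputed each time, giving a null
#' distribution. Two-tailed p-values use the add-one convention
#' `(b + 1) / (nPerm + 1)`; significance requires the observed difference to
#' fall in the outer tails after Bonferroni correction over luminances.
#'
#' @param groupA,groupB per-fly peak velocities of the two rescue genotypes
#'   (fly x luminance matrices or `fly`/`lum`/`peak` data.frames).
#' @param ctrlNeg,ctrlPos the two control groups (shared by both).
#' @param nPerm number of label shuffles (>= 1).
#' @param alpha family-wise two-tailed level.
#' @param seed RNG seed.
#' @return an [EfficiencyResult-class] object.
#' @export
permutationEfficiencyTest <- function(groupA, groupB, ctrlNeg, ctrlPos,
                                      nPerm = 1000L, alpha = 0.05,
                                      seed = 1L) {
  if (nPerm < 1L) stop("nPerm must be >= 1")
  A <- asPeakMatrix(groupA); B <- asPeakMatrix(groupB)
  Np <- asPeakMatrix(ctrlPos); Nn <- asPeakMatrix(ctrlNeg)
  if (nrow(A) < 2L || nrow(B) < 2L) stop("both groups need >= 2 flies")
  denom <- colMeans(Np) - colMeans(Nn)
  if (any(abs(denom) < .Machine$double.eps))
    stop("undefined efficiency: positive and negative controls coincide")
  negMean <- colMeans(Nn)
  effOf <- function(m) (colMeans(m) - negMean) / denom
  eA <- effOf(A); eB <- effOf(B)
  obs <- eA - eB
  pooled <- rbind(A, B)
  nA <- nrow(A); nTot <- nrow(pooled)
  nullDiff <- withSeed(seed, {
    t(vapply(seq_len(nPerm), function(b) {
      idx <- sample.int(nTot)
      effOf(pooled[idx[seq_len(nA)], , drop = FALSE]) -
        effOf(pooled[idx[-seq_len(nA)], , drop = FALSE])
    }, numeric(length(obs))))
  })
  p <- vapply(seq_along(obs), function(j)
    (1 + sum(abs(nullDiff[, j]) >= abs(obs[j]))) / (nPerm + 1), numeric(1))
  lum <- suppressWarnings(as.numeric(colnames(A)))
  if (anyNA(lum)) lum <- seq_along(obs)
  new("EfficiencyResult", luminances = lum, eA = eA, eB = eB, diff = obs,
      nullDiff = nullDiff, p = p,
      significant = p < alpha / length(obs),
      alpha = alpha, seed = as.integer(seed))
}

setMethod("show", "EfficiencyResult", function(object) {
  cat(sprintf("EfficiencyResult: %d luminances, %d permutations, alpha = %g (Bonferroni)\n",
              length(object@diff), nrow(object@nullDiff), object@alpha))
  print(data.frame(luminance = object@luminances, eA = object@eA,
                   eB = object@eB, diff = object@diff, p = object@p,
                   significant = object@significant))
})
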