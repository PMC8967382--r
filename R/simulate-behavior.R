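#' Model-fly turning-response parameters
#'
#' Peak optomotor turning of a model fly is the product of a saturating
#' contrast drive `tanh(contrastSat * |C|) / tanh(contrastSat)` and a
#' multiplicative luminance gain `(I_edge / I_max)^lumBeta`, scaled by a
#' per-fly lognormal amplitude. Genotype presets set `lumBeta`:
#' `"control"` -0.05 (luminance-invariant behavior with slightly larger
#' responses to dim edges), `"no_luminance_gain"` 0 (flat), and
#' `"dim_underestimating"` +0.25 (turning positively correlated with
#' luminance, as when the luminance-encoding inputs L1 and L3 are removed).
#' Presets are qualitative, not measured quantities.
#'
#' @param genotype preset name.
#' @param amplitude peak yaw at full contrast and full luminance (rad/s).
#' @param contrastSat saturation scale of the contrast drive.
#' @param lumBeta exponent of the luminance gain (overrides the preset).
#' @param flySd lognormal sd of between-fly amplitude variability.
#' @param trialSd within-fly yaw noise sd (rad/s, smoothed).
#' @param biasSd sd of the per-fly direction-independent turning bias (rad/s).
#' @param forwardSpeedMean,forwardSpeedSd baseline forward walking speed of
#'   normal walkers (mm/s).
#' @param pSlow fraction of slow walkers (below the 2 mm/s rejection
#'   threshold), in `[0, 1)`.
#' @param bumpDur,bumpPeak duration and peak time (s) of the half-sine
#'   turning bump inside the motion window.
#' @return an object of class `BehaviorParams`.
#' @export
behaviorParams <- function(genotype = c("control", "no_luminance_gain",
                                        "dim_underestimating"),
                           amplitude = 1.0, contrastSat = 2, lumBeta = NULL,
                           flySd = 0.2, trialSd = 0.3, biasSd = 0.05,
                           forwardSpeedMean = 7, forwardSpeedSd = 2,
                           pSlow = 0.25, bumpDur = 0.6, bumpPeak = 0.3) {
  genotype <- match.arg(genotype)
  if (is.null(lumBeta))
    lumBeta <- switch(genotype, control = -0.05, no_luminance_gain = 0,
                      dim_underestimating = 0.25)
  stopifnot(amplitude >= 0, contrastSat > 0, flySd >= 0, trialSd >= 0,
            pSlow >= 0, pSlow < 1, bumpDur > 0)
  structure(list(genotype = genotype, amplitude = amplitude,
                 contrastSat = contrastSat, lumBeta = lumBeta, flySd = flySd,
                 trialSd = trialSd, biasSd = biasSd,
                 forwardSpeedMean = forwardSpeedMean,
                 forwardSpeedSd = forwardSpeedSd, pSlow = pSlow,
                 bumpDur = bumpDur, bumpPeak = bumpPeak),
            class = "BehaviorParams")
}

#' Contrast drive and luminance gain of a behavior preset
#'
#' The noiseless expected peak yaw for an epoch of Michelson contrast `C`
#' and edge luminance `I`: `amplitude * drive(|C|) * gain(I)`.
#'
#' @param params a `BehaviorParams` object.
#' @param contrast Michelson contrast(s).
#' @param lum edge luminance(s) (photon flux).
#' @param imax calibration maximum the gain is referenced to.
#' @return expected peak yaw velocity (rad/s).
#' @export
expectedPeak <- function(params, contrast, lum, imax) {
  drive <- tanh(params$contrastSat * abs(contrast)) / tanh(params$contrastSat)
  gain <- (pmax(lum, 1e-6 * imax) / imax)^params$lumBeta
  params$amplitude * drive * gain
}

#' Trackball geometry
#'
#' @param radius ball radius (mm; 6 mm diameter ball by default).
#' @param sensorAzimuths equatorial azimuths (deg) of the two optical
#'   sensors, 90 degrees apart by default; must be distinct modulo 180.
#' @param sampleRate sensor sampling rate (Hz).
#' @return an object of class `BallKinematics`.
#' @export
ballKinematics <- function(radius = 3, sensorAzimuths = c(0, 90),
                           sampleRate = 120) {
  stopifnot(radius > 0, length(sensorAzimuths) == 2L)
  if (abs(sin((sensorAzimuths[1] - sensorAzimuths[2]) * pi / 180)) < 1e-9)
    stop("degenerate geometry: sensor azimuths coincide modulo 180 degrees")
  structure(list(radius = radius, sensorAzimuths = sensorAzimuths,
                 sampleRate = sampleRate), class = "BallKinematics")
}

#' Forward model of the two-sensor trackball readout
#'
#' A sensor looking at the ball's equator at azimuth `theta` reads a
#' horizontal surface displacement rate `R * w_yaw` (identical at any
#' azimuth) and a vertical rate `R * (w_x * sin(theta) - w_y * cos(theta))`,
#' where `w_x` is rotation about the fly's left-right axis (pitch, encoding
#' forward translation) and `w_y` rotation about its body axis (roll).
#' This linear map is exactly inverted by [velocitiesFromSensors()].
#'
#' @param yaw,pitch,roll equal-length rotation-rate series (rad/s).
#' @param kin a `BallKinematics` object.
#' @return data.frame `time, s1_h, s1_v, s2_h, s2_v` (displacement rates,
#'   mm/s, sampled at `kin$sampleRate`).
#' @export
composeBallSensors <- function(yaw, pitch, roll, kin = ballKinematics()) {
  n <- length(yaw)
  if (length(pitch) != n || length(roll) != n)
    stop("yaw, pitch and roll series must have equal length")
  th <- kin$sensorAzimuths * pi / 180
  R <- kin$radius
  data.frame(
    time = (seq_len(n) - 1L) / kin$sampleRate,
    s1_h = R * yaw, s1_v = R * (pitch * sin(th[1]) - roll * cos(th[1])),
    s2_h = R * yaw, s2_v = R * (pitch * sin(th[2]) - roll * cos(th[2])))
}

## smooth (exponentially filtered) gaussian noise with stationary sd `sd`
smoothNoise <- function(n, sd, tau, dt) {
  if (sd == 0) return(numeric(n))
  a <- exp(-dt / tau)
  x <- as.numeric(stats::filter(rnorm(n), a, method = "recursive"))
  x * sd * sqrt(1 - a^2)
}

#' Simulate trackball turning sessions of model flies
#'
#' For every presented motion epoch of `protocol`, each fly contributes one
#' trial-aligned yaw snippet: a half-sine turning bump of expected amplitude
#' [expectedPeak()] in the stimulus direction, plus a per-fly
#' direction-independent bias and smoothed trial noise. Snippets cover the
#' last part of the preceding inter-trial interval (for the baseline
#' window), the static pattern, the motion window and 250 ms beyond motion
#' offset; motion onset is at time 0. Baseline forward speed is drawn per
#' fly (a fraction `pSlow` walks below 2 mm/s).
#'
#' @param params a `BehaviorParams` object from [behaviorParams()].
#' @param protocol a [StimulusProtocol-class] with edge-motion epochs.
#' @param nFlies cohort size.
#' @param seed RNG seed (bitwise reproducible output).
#' @param sampleRate snippet sampling rate (Hz).
#' @return a [VelocityTraceSet-class] object.
#' @export
simulateTurning <- function(params, protocol, nFlies = 10L, seed = 1L,
                            sampleRate = 60) {
  stopifnot(inherits(params, "BehaviorParams"))
  ep <- protocol@epochs
  motIdx <- which(ep$kind == "edge_motion")
  if (!length(motIdx)) stop("protocol contains no motion epochs")
  motionDur <- ep$duration[motIdx[1]]
  staticDur <- if (any(ep$kind == "static")) ep$duration[ep$kind == "static"][1] else 0.5
  dt <- 1 / sampleRate
  tAxis <- seq(-(staticDur + 0.3), motionDur + 0.25, by = dt)
  bump <- ifelse(tAxis >= 0 & tAxis <= params$bumpDur,
                 sin(pi * tAxis / params$bumpDur), 0)
  imax <- iMax(protocol@calibration)

  occ <- protocol@presentation[protocol@presentation %in% motIdx]
  nOcc <- length(occ)
  withSeed(seed, {
    flyAmp <- params$amplitude * exp(rnorm(nFlies, 0, params$flySd))
    flyBias <- rnorm(nFlies, 0, params$biasSd)
    slow <- runif(nFlies) < params$pSlow
    fwd <- numeric(nFlies)
    for (f in seq_len(nFlies)) {
      if (slow[f]) fwd[f] <- runif(1, 0.2, 1.9)
      else {
        repeat {
          v <- rnorm(1, params$forwardSpeedMean, params$forwardSpeedSd)
          if (v >= 2) break
        }
        fwd[f] <- v
      }
    }
    nRow <- nFlies * nOcc
    yaw <- matrix(0, nRow, length(tAxis))
    trials <- data.frame(
      fly = rep(seq_len(nFlies), each = nOcc),
      trial = rep(seq_len(nOcc), nFlies),
      label = rep(sub("_[RL]$", "", ep$label[occ]), nFlies),
      direction = rep(ep$direction[occ], nFlies),
      contrast = rep(michelsonContrast(ep$lumFg[occ], ep$lumBg[occ]), nFlies),
      lumFg = rep(ep$lumFg[occ], nFlies))
    amp <- flyAmp[trials$fly] *
      expectedPeak(behaviorParams(params$genotype, amplitude = 1,
                                  contrastSat = params$contrastSat,
                                  lumBeta = params$lumBeta),
                   trials$contrast, trials$lumFg, imax)
    for (r in seq_len(nRow)) {
      yaw[r, ] <- trials$direction[r] * amp[r] * bump +
        flyBias[trials$fly[r]] +
        smoothNoise(length(tAxis), params$trialSd, 0.2, dt)
    }
    flies <- data.frame(fly = seq_len(nFlies), genotype = params$genotype,
                        forwardSpeed = fwd, amplitude = flyAmp,
                        bias = flyBias)
    new("VelocityTraceSet", time = tAxis, yaw = yaw, trials = trials,
        flies = flies, sampleRate = sampleRate)
  })
}

setMethod("show", "VelocityTraceSet", function(object) {
  cat(sprintf("VelocityTraceSet: %d trials from %d flies, t in [%.2f, %.2f] s @ %g Hz\n",
              nrow(object@trials), nrow(object@flies), min(object@time),
              max(object@time), object@sampleRate))
  cat("  epochs:", paste(unique(object@trials$label), collapse = ", "), "\n")
})
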