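## Stimulus protocol builders. Epoch timing follows the arena conventions:
## 500 ms static pattern, 750 ms edge motion at 160 deg/s, 1 s inter-trial
## interval; four simultaneous edges each covering arenaSpan/nEdges degrees,
## with the pattern resetting after every traversal so the edge virtually
## moves continuously within the motion window.

## Evaluate expr with a temporary RNG state seeded by `seed`.
withSeed <- function(seed, expr) {
  if (!is.null(seed) && !is.na(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

newEpochs <- function(label, kind, duration, lumBg, lumFg, direction, speed) {
  data.frame(label = label, kind = kind, duration = duration,
             lumBg = lumBg, lumFg = lumFg, direction = direction,
             speed = speed, stringsAsFactors = FALSE)
}

newProtocol <- function(epochs, presentation, cal, arenaSpan, nEdges, seed, meta) {
  new("StimulusProtocol", epochs = epochs,
      presentation = as.integer(presentation), calibration = cal,
      arenaSpan = as.numeric(arenaSpan), nEdges = as.integer(nEdges),
      seed = as.integer(if (is.null(seed)) NA else seed), meta = meta)
}

#' Accessors for StimulusProtocol objects
#'
#' `epochTable` returns the distinct-epoch table, `presentationOrder` the
#' ordered epoch indices actually shown, `totalDuration` the summed duration
#' of all presented epochs, and `protocolTimeline` the expanded schedule with
#' half-open `[tStart, tEnd)` intervals per presented epoch.
#'
#' @param protocol a [StimulusProtocol-class] object.
#' @return see description.
#' @export
epochTable <- function(protocol) protocol@epochs

#' @rdname epochTable
#' @export
presentationOrder <- function(protocol) protocol@presentation

#' @rdname epochTable
#' @export
totalDuration <- function(protocol)
  sum(protocol@epochs$duration[protocol@presentation])

#' @rdname epochTable
#' @export
protocolTimeline <- function(protocol) {
  ep <- protocol@epochs[protocol@presentation, , drop = FALSE]
  tEnd <- cumsum(ep$duration)
  data.frame(idx = protocol@presentation, label = ep$label, kind = ep$kind,
             tStart = c(0, head(tEnd, -1L)), tEnd = tEnd,
             row.names = NULL, stringsAsFactors = FALSE)
}

## interleave trial sub-sequences (list of integer vectors) in shuffled order
shuffleTrials <- function(trialSeqs, seed) {
  ord <- withSeed(seed, sample.int(length(trialSeqs)))
  unlist(trialSeqs[ord], use.names = FALSE)
}

#' Build a moving-edge stimulus protocol
#'
#' Each trial shows a 500 ms static first frame, then `motionDuration` of edge
#' motion, then an inter-trial interval. Epochs are randomly interleaved and
#' mirrored (every level appears equally often moving left and right).
#' Variants:
#' * `"ON"` — five 100% Michelson contrast ON edges of luminances
#'   \{1,2,4,8,15\}/15 of I_max on a dark background, dark inter-trial screen.
#' * `"OFF"` — a single dark OFF edge over five lit backgrounds
#'   (\{1,2,4,8,15\}/15 of I_max), dark inter-trial screen.
#' * `"mixed"` — constant edge at 10/15 of I_max over seven backgrounds
#'   \{8,6,5,4,2,1,0\}/15, giving Michelson contrasts of roughly
#'   \{11,25,33,43,67,82,100\}%; inter-trial screen as bright as the edge.
#' * `"ON_imaging"` — six ON edge luminances on the projector rig
#'   (\{0.16,0.31,0.62,1.2,1.8,2.4\}e5 photons/s/receptor) on darkness, with a
#'   4 s dark inter-stimulus interval.
#'
#' @param kind protocol variant, see above.
#' @param levelFractions optional override of the varied LED level fractions
#'   (snapped to the display grid); for `"ON_imaging"` absolute photon fluxes.
#' @param cal calibration; defaults to the rig matching `kind`.
#' @param nTrials presentations per distinct epoch (split evenly across the
#'   two motion directions; must be even).
#' @param staticDuration,motionDuration,itiDuration epoch timing (s).
#' @param speed edge angular speed (deg/s).
#' @param nEdges simultaneous edges; each covers `arenaSpan/nEdges` degrees.
#' @param arenaSpan azimuthal display span (deg).
#' @param seed seed for the interleaving order.
#' @return a [StimulusProtocol-class] object.
#' @export
buildEdgeProtocol <- function(kind = c("ON", "OFF", "mixed", "ON_imaging"),
                              levelFractions = NULL, cal = NULL,
                              nTrials = 60L,
                              staticDuration = 0.5, motionDuration = 0.75,
                              itiDuration = NULL, speed = 160, nEdges = NULL,
                              arenaSpan = NULL, seed = 1L) {
  kind <- match.arg(kind)
  if (nTrials %% 2L != 0L)
    stop("nTrials must be even so both motion directions appear equally often")
  if (is.null(cal))
    cal <- defaultCalibration(if (kind == "ON_imaging") "imaging_edges" else "behavior")
  imax <- iMax(cal)
  if (is.null(arenaSpan)) arenaSpan <- if (kind == "ON_imaging") 80 else 192
  if (is.null(nEdges)) nEdges <- if (kind == "ON_imaging") 1L else 4L
  if (is.null(itiDuration)) itiDuration <- if (kind == "ON_imaging") 4 else 1

  if (kind == "ON") {
    fr <- if (is.null(levelFractions)) c(1, 2, 4, 8, 15) / 15 else levelFractions
    fr <- ledFraction(fr, cal)
    edge <- fr * imax; bg <- rep(0, length(edge)); itiLum <- 0
  } else if (kind == "OFF") {
    fr <- if (is.null(levelFractions)) c(1, 2, 4, 8, 15) / 15 else levelFractions
    fr <- ledFraction(fr, cal)
    bg <- fr * imax; edge <- rep(0, length(bg)); itiLum <- 0
  } else if (kind == "mixed") {
    edgeFr <- ledFraction(10 / 15, cal)
    fr <- if (is.null(levelFractions)) c(8, 6, 5, 4, 2, 1, 0) / 15 else levelFractions
    fr <- ledFraction(fr, cal)
    bg <- fr * imax; edge <- rep(edgeFr * imax, length(bg)); itiLum <- edgeFr * imax
  } else { # ON_imaging: absolute projector luminances
    edge <- if (is.null(levelFractions))
      c(0.16, 0.31, 0.62, 1.2, 1.8, 2.4) * 1e5 else levelFractions
    bg <- rep(0, length(edge)); itiLum <- 0; fr <- edge / imax
  }
  nLev <- length(edge)

  statics <- newEpochs(sprintf("static_%d", seq_len(nLev)), "static",
                       staticDuration, bg, NA_real_, 0L, NA_real_)
  motions <- do.call(rbind, lapply(c(1L, -1L), function(d)
    newEpochs(sprintf("edge_%d_%s", seq_len(nLev), ifelse(d > 0, "R", "L")),
              "edge_motion", motionDuration, bg, edge, d, speed)))
  iti <- newEpochs("iti", "interval", itiDuration, itiLum, NA_real_, 0L, NA_real_)
  ep <- rbind(statics, motions, iti)

  itiIdx <- nrow(ep)
  perDir <- nTrials %/% 2L
  trialSeqs <- list()
  for (i in seq_len(nLev)) for (d in 0:1) {
    motIdx <- nLev + d * nLev + i   # d = 0 -> R block, 1 -> L block
    trialSeqs <- c(trialSeqs,
                   replicate(perDir, c(i, motIdx, itiIdx), simplify = FALSE))
  }
  pres <- shuffleTrials(trialSeqs, seed)
  newProtocol(ep, pres, cal, arenaSpan, nEdges, seed,
              list(type = paste0("edge_", kind), levelFractions = fr,
                   edgeLum = edge, bgLum = bg, nTrials = nTrials))
}

#' Build the luminance staircase protocol
#'
#' Full-field luminance steps through `levels * iMax(cal)` first in
#' increasing order (darkness to full brightness) then decreasing, repeated
#' `nRepeats` times. The down-transitions expose OFF steps of Weber
#' magnitudes \{0.25, 1/3, 0.5, 1\} for the default levels.
#'
#' @param cal calibration (projector rig by default, I_max = 2.17e5).
#' @param levels ascending fractions of I_max.
#' @param stepDuration seconds per luminance epoch.
#' @param nRepeats staircase repetitions.
#' @return a [StimulusProtocol-class] object.
#' @export
buildStaircase <- function(cal = defaultCalibration("imaging"),
                           levels = c(0, 0.25, 0.5, 0.75, 1),
                           stepDuration = 10, nRepeats = 4L) {
  if (is.unsorted(levels, strictly = FALSE))
    stop("levels must be sorted ascending")
  imax <- iMax(cal)
  up <- levels * imax
  down <- rev(levels)[-1L] * imax
  ep <- rbind(
    newEpochs(sprintf("stair_up_%d", seq_along(up)), "step", stepDuration,
              NA_real_, up, 0L, NA_real_),
    newEpochs(sprintf("stair_down_%d", seq_along(down)), "step", stepDuration,
              NA_real_, down, 0L, NA_real_))
  pres <- rep(seq_len(nrow(ep)), nRepeats)
  newProtocol(ep, pres, cal, 60, 0L, NA_integer_,
              list(type = "staircase", levels = levels, nRepeats = nRepeats))
}

#' Build the randomized full-field flash protocol
#'
#' 10 s full-field flashes of five luminances (0, 0.25, 0.5, 0.75 and 1 times
#' I_max), pseudo-randomized: the sequence is drawn as consecutive shuffled
#' blocks of all levels, so every level appears at least once whenever
#' `totalDuration >= length(levels) * flashDuration`, and level frequencies
#' stay near-uniform over long sequences.
#'
#' @param cal calibration (projector rig by default).
#' @param levels fractions of I_max.
#' @param flashDuration seconds per flash.
#' @param totalDuration total stimulus time (s).
#' @param seed randomization seed.
#' @return a [StimulusProtocol-class] object.
#' @export
buildRandomFlashes <- function(cal = defaultCalibration("imaging"),
                               levels = c(0, 0.25, 0.5, 0.75, 1),
                               flashDuration = 10, totalDuration = 300,
                               seed = 1L) {
  if (totalDuration < flashDuration)
    stop("totalDuration must be >= flashDuration")
  imax <- iMax(cal)
  ep <- newEpochs(sprintf("flash_%d", seq_along(levels)), "flash",
                  flashDuration, NA_real_, levels * imax, 0L, NA_real_)
  nFlash <- floor(totalDuration / flashDuration)
  nBlocks <- ceiling(nFlash / length(levels))
  pres <- withSeed(seed, unlist(replicate(nBlocks,
    sample.int(length(levels)), simplify = FALSE)))[seq_len(nFlash)]
  newProtocol(ep, pres, cal, 60, 0L, seed,
              list(type = "random_flashes", levels = levels))
}

#' Build the adapted A/B contrast-step protocol
#'
#' Each trial shows `adaptDuration` seconds of bright adapting background,
#' then two consecutive OFF steps of `stepDuration` seconds: the A step to one
#' of seven decreasing luminances, and the B step at a fixed Weber contrast
#' relative to its A step (`I_B = I_A * (1 + bWeber)`, -25% by default).
#' A/B pairs are presented in randomized order.
#'
#' @param cal calibration (projector rig by default).
#' @param adaptFraction adapting luminance as a fraction of I_max.
#' @param aFractions seven decreasing A-step fractions of I_max (all below
#'   `adaptFraction`, all > 0 when `bWeber != 0`).
#' @param bWeber Weber contrast of each B step relative to its A step.
#' @param adaptDuration,stepDuration epoch timing (s).
#' @param nRepeats repetitions of the full randomized pair set.
#' @param seed randomization seed.
#' @return a [StimulusProtocol-class] object.
#' @export
buildAbProtocol <- function(cal = defaultCalibration("imaging"),
                            adaptFraction = 1,
                            aFractions = c(0.70, 0.55, 0.42, 0.32, 0.24, 0.17, 0.12),
                            bWeber = -0.25, adaptDuration = 30,
                            stepDuration = 3, nRepeats = 3L, seed = 1L) {
  if (any(aFractions >= adaptFraction))
    stop("A levels must lie strictly below the adapting luminance")
  if (bWeber != 0 && any(aFractions == 0))
    stop("undefined B level: I_A = 0 with nonzero Weber contrast")
  imax <- iMax(cal)
  aLum <- aFractions * imax
  bLum <- aLum * (1 + bWeber)
  n <- length(aLum)
  ep <- rbind(
    newEpochs("adapt", "step", adaptDuration, NA_real_, adaptFraction * imax,
              0L, NA_real_),
    newEpochs(sprintf("A_%d", seq_len(n)), "step", stepDuration, NA_real_,
              aLum, 0L, NA_real_),
    newEpochs(sprintf("B_%d", seq_len(n)), "step", stepDuration, NA_real_,
              bLum, 0L, NA_real_))
  trialSeqs <- lapply(seq_len(n), function(i) c(1L, 1L + i, 1L + n + i))
  pres <- unlist(withSeed(seed, replicate(nRepeats,
    unlist(trialSeqs[sample.int(n)], use.names = FALSE), simplify = FALSE)))
  newProtocol(ep, pres, cal, 60, 0L, seed,
              list(type = "ab_steps", aFractions = aFractions, bWeber = bWeber,
                   adaptFraction = adaptFraction))
}

## local luminance of one presented epoch at local times tau (vectorized),
## for a receptive field whose distance to the approaching edge start is d deg
epochLocalLum <- function(eprow, tau, d, width) {
  kind <- eprow$kind
  if (kind == "edge_motion") {
    travT <- width / eprow$speed
    phase <- tau %% travT
    ifelse(phase * eprow$speed >= d, eprow$lumFg, eprow$lumBg)
  } else {
    lum <- if (!is.na(eprow$lumFg)) eprow$lumFg else eprow$lumBg
    rep(lum, length(tau))
  }
}

#' Local luminance seen by one receptive field over a protocol
#'
#' Converts a protocol into the luminance time series at a single azimuth:
#' uniform epochs (flashes, steps, intervals, static patterns) contribute
#' their uniform luminance; edge-motion epochs contribute background
#' luminance until the nearest edge crosses the azimuth (crossing time =
#' angular distance / speed), then edge luminance until the within-epoch
#' pattern reset, each reset starting an independent crossing.
#'
#' @param protocol a [StimulusProtocol-class] object.
#' @param rfAzimuth receptive-field azimuth (deg) within `[0, arenaSpan)`.
#' @param sampleRate sampling rate of the returned series (Hz).
#' @return data.frame with columns `time` (s) and `luminance`.
#' @export
rfLuminance <- function(protocol, rfAzimuth, sampleRate = 100) {
  if (rfAzimuth < 0 || rfAzimuth >= protocol@arenaSpan)
    stop("rfAzimuth outside the arena span")
  width <- if (protocol@nEdges > 0) protocol@arenaSpan / protocol@nEdges else Inf
  tl <- protocolTimeline(protocol)
  times <- seq(0, max(tl$tEnd) - 1 / sampleRate, by = 1 / sampleRate)
  lum <- numeric(length(times))
  dFwd <- rfAzimuth %% width
  for (r in seq_len(nrow(tl))) {
    sel <- times >= tl$tStart[r] & times < tl$tEnd[r]
    if (!any(sel)) next
    eprow <- protocol@epochs[tl$idx[r], , drop = FALSE]
    d <- if (eprow$direction >= 0) dFwd else (width - dFwd) %% width
    lum[sel] <- epochLocalLum(eprow, times[sel] - tl$tStart[r], d, width)
  }
  data.frame(time = times, luminance = lum)
}

#' Mean-field luminance of a protocol over time
#'
#' Screen-averaged luminance used as the stimulus regressor for ROI polarity
#' filtering: uniform epochs contribute their luminance; edge-motion epochs
#' ramp linearly from background to edge luminance as the edges sweep their
#' sectors (restarting at every within-epoch reset).
#'
#' @inheritParams rfLuminance
#' @param times evaluation times (s); defaults to a uniform grid.
#' @return numeric luminance series at `times`.
#' @export
sessionLuminance <- function(protocol, times = NULL, sampleRate = 100) {
  tl <- protocolTimeline(protocol)
  if (is.null(times))
    times <- seq(0, max(tl$tEnd) - 1 / sampleRate, by = 1 / sampleRate)
  width <- if (protocol@nEdges > 0) protocol@arenaSpan / protocol@nEdges else Inf
  lum <- numeric(length(times))
  for (r in seq_len(nrow(tl))) {
    sel <- times >= tl$tStart[r] & times < tl$tEnd[r]
    if (!any(sel)) next
    eprow <- protocol@epochs[tl$idx[r], , drop = FALSE]
    if (eprow$kind == "edge_motion") {
      travT <- width / eprow$speed
      frac <- ((times[sel] - tl$tStart[r]) %% travT) / travT
      lum[sel] <- eprow$lumBg + (eprow$lumFg - eprow$lumBg) * frac
    } else {
      lum[sel] <- if (!is.na(eprow$lumFg)) eprow$lumFg else eprow$lumBg
    }
  }
  lum
}

#' Serialize a protocol to JSON / read it back
#'
#' @param protocol a [StimulusProtocol-class] object.
#' @param path file path.
#' @return `readProtocol` returns the reconstructed
#'   [StimulusProtocol-class]; `writeProtocol` returns `path` invisibly.
#' @export
writeProtocol <- function(protocol, path) {
  obj <- list(
    epochs = protocol@epochs, presentation = protocol@presentation,
    calibration = list(
      cdAtNativeMax = protocol@calibration@cdAtNativeMax,
      photonsAtNativeMax = protocol@calibration@photonsAtNativeMax,
      ndAttenuation = protocol@calibration@ndAttenuation,
      nLedLevels = protocol@calibration@nLedLevels),
    arenaSpan = protocol@arenaSpan, nEdges = protocol@nEdges,
    seed = protocol@seed, meta = protocol@meta)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null")
  invisible(path)
}

#' @rdname writeProtocol
#' @export
readProtocol <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  calL <- obj$calibration
  cal <- Calibration(calL$cdAtNativeMax, calL$photonsAtNativeMax,
                     calL$ndAttenuation, calL$nLedLevels)
  ep <- obj$epochs
  for (col in c("duration", "lumBg", "lumFg", "speed"))
    ep[[col]] <- as.numeric(ep[[col]])
  ep$direction <- as.integer(ep$direction)
  newProtocol(ep, obj$presentation, cal, obj$arenaSpan, obj$nEdges,
              obj$seed, as.list(obj$meta))
}

#' Export a luminance series to CSV
#' @param series data.frame with `time` and `luminance` (e.g. [rfLuminance()]).
#' @param path file path.
#' @export
writeLuminanceCsv <- function(series, path) {
  stopifnot(all(c("time", "luminance") %in% names(series)))
  write.csv(series[, c("time", "luminance")], path, row.names = FALSE)
  invisible(path)
}

setMethod("show", "StimulusProtocol", function(object) {
  cat(sprintf("StimulusProtocol <%s>: %d distinct epochs, %d presented, %.1f s total\n",
              if (!is.null(object@meta$type)) object@meta$type else "custom",
              nrow(object@epochs), length(object@presentation),
              totalDuration(object)))
  cat(sprintf("  arena: %g deg, %d edge(s); I_max = %.4g photons/s/receptor\n",
              object@arenaSpan, object@nEdges, iMax(object@calibration)))
})
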