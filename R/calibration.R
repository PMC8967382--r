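#' Construct a photometric calibration
#'
#' Defaults describe the behavioral LED arena: 16 linearly spaced LED levels,
#' a brightest native level of 11.77e5 photons s^-1 photoreceptor^-1 measured
#' as 51.34 cd/m^2, and a 0.9 neutral-density foil whose *measured* effect
#' leaves 14.71e4 photons s^-1 photoreceptor^-1 at the brightest level. The
#' measured attenuation (14.71e4 / 11.77e5) is the default; set
#' `nominalNd = TRUE` for the nominal 10^-0.9 factor instead.
#'
#' @param cdAtNativeMax luminance (cd/m^2) at the brightest native level.
#' @param photonsAtNativeMax photon flux at that level.
#' @param ndAttenuation attenuation factor in (0, 1].
#' @param nLedLevels number of linearly spaced intensity levels.
#' @param nominalNd use the nominal 10^-0.9 neutral-density factor.
#' @return a [Calibration-class] object.
#' @examples
#' cal <- Calibration()
#' iMax(cal)            # 14.71e4 photons/s/photoreceptor
#' cdToPhotons(51.34, cal, attenuate = FALSE)
#' @export
Calibration <- function(cdAtNativeMax = 51.34,
                        photonsAtNativeMax = 11.77e5,
                        ndAttenuation = 14.71e4 / 11.77e5,
                        nLedLevels = 16L,
                        nominalNd = FALSE) {
  if (nominalNd) ndAttenuation <- 10^-0.9
  new("Calibration",
      cdAtNativeMax = as.numeric(cdAtNativeMax),
      photonsAtNativeMax = as.numeric(photonsAtNativeMax),
      ndAttenuation = as.numeric(ndAttenuation),
      nLedLevels = as.integer(nLedLevels))
}

#' Ready-made calibrations for the rigs used in the study design
#'
#' `"behavior"`: LED arena (effective maximum 14.71e4 photons/s/receptor).
#' `"imaging"`: projector rig for staircase and randomized flashes
#' (I_max = 2.17e5). `"imaging_edges"`: projector rig for moving ON edges
#' (I_max = 2.4e5). The projector rigs are expressed with the attenuation
#' already folded into the effective maximum.
#'
#' @param rig one of "behavior", "imaging", "imaging_edges".
#' @return a [Calibration-class] object.
#' @export
defaultCalibration <- function(rig = c("behavior", "imaging", "imaging_edges")) {
  rig <- match.arg(rig)
  switch(rig,
    behavior = Calibration(),
    imaging = Calibration(cdAtNativeMax = 51.34 * 2.17e5 / 11.77e5,
                          photonsAtNativeMax = 2.17e5, ndAttenuation = 1),
    imaging_edges = Calibration(cdAtNativeMax = 51.34 * 2.4e5 / 11.77e5,
                                photonsAtNativeMax = 2.4e5, ndAttenuation = 1))
}

#' Effective maximum photon flux after attenuation
#' @param cal a [Calibration-class] object.
#' @return photon flux (photons s^-1 photoreceptor^-1).
#' @export
iMax <- function(cal) {
  stopifnot(is(cal, "Calibration"))
  cal@photonsAtNativeMax * cal@ndAttenuation
}

#' Convert measured luminance to photon flux
#'
#' Linear transform anchored to the calibration pair (cd at native max,
#' photons at native max), optionally applying the neutral-density
#' attenuation of the light path.
#'
#' @param cd luminance in cd/m^2 (non-negative).
#' @param cal a [Calibration-class] object.
#' @param attenuate apply `cal@ndAttenuation`.
#' @return photon flux (photons s^-1 photoreceptor^-1), linear in `cd`.
#' @export
cdToPhotons <- function(cd, cal = Calibration(), attenuate = TRUE) {
  stopifnot(is(cal, "Calibration"))
  if (any(!is.finite(cd)) || any(cd < 0))
    stop("luminance (cd) must be finite and >= 0")
  cd * (cal@photonsAtNativeMax / cal@cdAtNativeMax) *
    if (attenuate) cal@ndAttenuation else 1
}

#' Snap a requested intensity fraction to the display's level grid
#'
#' An n-level display shows fractions k/(n-1), k = 0..n-1, of its maximum.
#' Quantization moves any requested fraction by at most half a level
#' (1/30 for the default 16-level arena).
#'
#' @param fraction requested fraction(s) of maximum intensity, in \[0, 1\].
#' @param cal a [Calibration-class] object.
#' @return the nearest representable fraction(s).
#' @export
ledFraction <- function(fraction, cal = Calibration()) {
  if (any(fraction < 0 | fraction > 1))
    stop("level fraction outside [0, 1]")
  steps <- cal@nLedLevels - 1L
  round(fraction * steps) / steps
}

#' Michelson contrast of an edge against its background
#'
#' `C_M = (I_edge - I_background) / (I_edge + I_background)`, in \[-1, 1\].
#'
#' @param iEdge,iBackground photon fluxes (>= 0, not both zero).
#' @return dimensionless contrast fraction.
#' @examples
#' michelsonContrast(0.98e4, 0)        # 1: full ON contrast
#' michelsonContrast(10 / 15, 4 / 15)  # 0.4286 (the 43% mixed-set epoch)
#' @export
michelsonContrast <- function(iEdge, iBackground) {
  if (any(iEdge < 0) || any(iBackground < 0))
    stop("luminances must be >= 0")
  s <- iEdge + iBackground
  if (any(s == 0))
    stop("Michelson contrast undefined when both luminances are zero")
  (iEdge - iBackground) / s
}

#' Weber contrast of a step from an adapted level
#'
#' `C_W = (I_B - I_A) / I_A`, the fractional change relative to the level
#' `I_A` the system is adapted to.
#'
#' @param iB step luminance; @param iA pre-step (adapted) luminance (> 0).
#' @return dimensionless contrast.
#' @export
weberContrast <- function(iB, iA) {
  if (any(iA <= 0))
    stop("Weber contrast undefined for a zero (or negative) reference luminance")
  if (any(iB < 0)) stop("luminances must be >= 0")
  (iB - iA) / iA
}

setMethod("show", "Calibration", function(object) {
  cat("Calibration:", object@nLedLevels, "linearly spaced levels\n")
  cat(sprintf("  native max: %.4g photons/s/receptor (%.4g cd/m^2)\n",
              object@photonsAtNativeMax, object@cdAtNativeMax))
  cat(sprintf("  ND attenuation: %.4g -> effective I_max %.4g photons/s/receptor\n",
              object@ndAttenuation, iMax(object)))
})
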