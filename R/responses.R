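## Response quantification on trial-averaged traces. Window conventions:
## "last 2 s" / "last 500 ms" windows are closed on the left and open at the
## epoch end, evaluated on the 10 Hz trial-average grid.

lastWindowIdx <- function(n, rate, seconds) {
  k <- round(seconds * rate)
  if (k > n) stop(sprintf("epoch shorter than the %g s window", seconds))
  (n - k + 1L):n
}

roiIdCols <- function(roiData) {
  keep <- intersect(c("fly", "roi", "cellType"), names(roiData))
  roiData[, keep, drop = FALSE]
}

## per-ROI min-max normalization of the averaged traces across all epochs
normalizeAvgTraces <- function(traces) {
  all <- do.call(cbind, traces)
  lo <- apply(all, 1, min); hi <- apply(all, 1, max)
  rng <- hi - lo
  rng[rng == 0] <- 1
  lapply(traces, function(m) (m - lo) / rng)
}

## label pairs (previous -> step) of luminance-decreasing transitions in the
## presented sequence
downStepPairs <- function(protocol) {
  ep <- protocol@epochs
  pres <- protocol@presentation
  prev <- pres[-length(pres)]; cur <- pres[-1L]
  sel <- ep$kind[prev] == "step" & ep$kind[cur] == "step" &
    ep$lumFg[cur] < ep$lumFg[prev]
  unique(data.frame(prevLabel = ep$label[prev[sel]],
                    label = ep$label[cur[sel]],
                    lumPrev = ep$lumFg[prev[sel]],
                    lum = ep$lumFg[cur[sel]], stringsAsFactors = FALSE))
}

#' OFF-step responses to the luminance staircase
#'
#' For every luminance-decreasing transition of the staircase, the step
#' response of an ROI is the maximum of its trial-averaged dF/F within the
#' step epoch minus the mean over the last 2 s of the previous luminance
#' epoch. With `normalize = TRUE` each ROI's averaged traces are first
#' min-max scaled to `[0, 1]` across the whole session (the convention used
#' before comparing cell types).
#'
#' @param avg a [TrialAverage-class] from a staircase protocol.
#' @param protocol the matching [StimulusProtocol-class].
#' @param normalize min-max normalize traces before extraction.
#' @return data.frame: ROI ids, `label`, `prevLabel`, `weber` (Weber
#'   contrast of the step), `response`.
#' @export
staircaseStepResponse <- function(avg, protocol, normalize = FALSE) {
  pairs <- downStepPairs(protocol)
  if (!nrow(pairs)) stop("protocol has no luminance-decreasing steps")
  traces <- if (normalize) normalizeAvgTraces(avg@traces) else avg@traces
  out <- lapply(seq_len(nrow(pairs)), function(i) {
    stepM <- traces[[pairs$label[i]]]
    prevM <- traces[[pairs$prevLabel[i]]]
    idx <- lastWindowIdx(ncol(prevM), avg@rate, 2)
    resp <- apply(stepM, 1, max) - rowMeans(prevM[, idx, drop = FALSE])
    cbind(roiIdCols(avg@roiData),
          data.frame(label = pairs$label[i], prevLabel = pairs$prevLabel[i],
                     weber = weberContrast(pairs$lum[i], pairs$lumPrev[i]),
                     response = resp, row.names = NULL))
  })
  do.call(rbind, out)
}

#' Plateau responses to full-field flashes
#'
#' The plateau of an ROI for a flash epoch is the mean of its trial-averaged
#' dF/F over the last 2 s of the epoch. With `subtractHighest = TRUE` the
#' plateau at the highest-luminance flash is subtracted per ROI (making that
#' plateau 0), the convention for comparing luminance tuning across cell
#' types.
#'
#' @param avg a [TrialAverage-class] from a flash protocol.
#' @param protocol the matching [StimulusProtocol-class].
#' @param subtractHighest subtract the highest-luminance plateau per ROI.
#' @return data.frame: ROI ids, `label`, `lum`, `plateau`.
#' @export
plateauResponses <- function(avg, protocol, subtractHighest = TRUE) {
  ep <- protocol@epochs
  fl <- ep[ep$kind == "flash", , drop = FALSE]
  if (!nrow(fl)) stop("protocol has no flash epochs")
  mat <- vapply(fl$label, function(lab) {
    m <- avg@traces[[lab]]
    rowMeans(m[, lastWindowIdx(ncol(m), avg@rate, 2), drop = FALSE])
  }, numeric(nrow(avg@roiData)))
  mat <- matrix(mat, nrow = nrow(avg@roiData),
                dimnames = list(NULL, fl$label))
  if (subtractHighest)
    mat <- mat - mat[, which.max(fl$lumFg)]
  out <- lapply(seq_len(nrow(fl)), function(i)
    cbind(roiIdCols(avg@roiData),
          data.frame(label = fl$label[i], lum = fl$lumFg[i],
                     plateau = mat[, i], row.names = NULL)))
  do.call(rbind, out)
}

#' Per-presentation plateau samples
#'
#' One plateau value (mean dF/F over the trailing `window` seconds) per ROI
#' per individual flash presentation, the sample set used for the mutual
#' information between luminance level and sustained response.
#'
#' @param x an [RoiTraceSet-class] with a `dff` assay.
#' @param protocol the matching [StimulusProtocol-class].
#' @param window trailing window (s).
#' @return data.frame: ROI ids, `label`, `lum`, `presentation`, `value`.
#' @export
presentationPlateaus <- function(x, protocol, window = 2) {
  dff <- dffTraces(x)
  tl <- protocolTimeline(protocol)
  tl <- tl[tl$kind == "flash", , drop = FALSE]
  if (!nrow(tl)) stop("protocol has no flash epochs")
  ep <- protocol@epochs
  out <- lapply(seq_len(nrow(tl)), function(r) {
    sel <- x$time >= tl$tEnd[r] - window & x$time < tl$tEnd[r]
    if (!any(sel)) stop("flash epoch shorter than the plateau window")
    cbind(roiIdCols(as.data.frame(SummarizedExperiment::rowData(x))),
          data.frame(label = tl$label[r],
                     lum = ep$lumFg[tl$idx[r]], presentation = r,
                     value = rowMeans(dff[, sel, drop = FALSE]),
                     row.names = NULL))
  })
  do.call(rbind, out)
}

#' Peak and sustained responses to adapted A/B contrast steps
#'
#' Peak = maximum of the trial-averaged dF/F within the step minus the mean
#' baseline over the last 2 s of the adapting epoch; sustained = mean over
#' the last 500 ms of the step.
#'
#' @param avg a [TrialAverage-class] from an A/B protocol.
#' @param protocol the matching [StimulusProtocol-class].
#' @return data.frame: ROI ids, `label`, `type` ("A"/"B"), `pair`, `lum`,
#'   `weber` (vs the adapting level for A steps, vs the A step for B steps),
#'   `peak`, `sustained`.
#' @export
abResponses <- function(avg, protocol) {
  ep <- protocol@epochs
  if (!"adapt" %in% ep$label) stop("not an A/B protocol: no adapting epoch")
  adaptM <- avg@traces[["adapt"]]
  base <- rowMeans(adaptM[, lastWindowIdx(ncol(adaptM), avg@rate, 2),
                          drop = FALSE])
  adaptLum <- ep$lumFg[ep$label == "adapt"]
  steps <- ep[grepl("^[AB]_\\d+$", ep$label), , drop = FALSE]
  out <- lapply(seq_len(nrow(steps)), function(i) {
    lab <- steps$label[i]
    type <- substr(lab, 1, 1)
    pair <- as.integer(sub("^[AB]_", "", lab))
    m <- avg@traces[[lab]]
    refLum <- if (type == "A") adaptLum else ep$lumFg[ep$label == paste0("A_", pair)]
    cbind(roiIdCols(avg@roiData),
          data.frame(label = lab, type = type, pair = pair,
                     lum = steps$lumFg[i],
                     weber = weberContrast(steps$lumFg[i], refLum),
                     peak = apply(m, 1, max) - base,
                     sustained = rowMeans(m[, lastWindowIdx(ncol(m), avg@rate, 0.5),
                                            drop = FALSE]),
                     row.names = NULL))
  })
  do.call(rbind, out)
}

#' ON-edge response amplitudes
#'
#' For each edge-motion epoch, the response is the absolute difference
#' between the mean trial-averaged dF/F over the full-darkness background
#' epoch and the minimum during the edge presentation (lamina neurons
#' hyperpolarize to ON edges, so the minimum captures the response).
#'
#' @param avg a [TrialAverage-class] from an ON-edge imaging protocol.
#' @param protocol the matching [StimulusProtocol-class].
#' @return data.frame: ROI ids, `label`, `lum`, `direction`, `response`.
#' @export
edgeResponse <- function(avg, protocol) {
  ep <- protocol@epochs
  darkLab <- ep$label[ep$kind == "interval" & !is.na(ep$lumBg) & ep$lumBg == 0]
  if (!length(darkLab)) stop("no full-darkness background epoch in protocol")
  darkMean <- rowMeans(avg@traces[[darkLab[1]]])
  mot <- ep[ep$kind == "edge_motion", , drop = FALSE]
  out <- lapply(seq_len(nrow(mot)), function(i) {
    m <- avg@traces[[mot$label[i]]]
    cbind(roiIdCols(avg@roiData),
          data.frame(label = mot$label[i], lum = mot$lumFg[i],
                     direction = mot$direction[i],
                     response = abs(darkMean - apply(m, 1, min)),
                     row.names = NULL))
  })
  do.call(rbind, out)
}
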