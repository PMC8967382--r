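# Shared fixture builders (all generated in code; nothing on disk).

squareMask <- function(rows, cols, h = 20L, w = 20L) {
  m <- matrix(FALSE, h, w)
  m[rows, cols] <- TRUE
  m
}

# masks kept >= 5 px from every border so +-4 px registration shifts never
# push fill pixels into a mask
smallMaskSet <- function() {
  roiMaskSet(list(squareMask(6:8, 6:8), squareMask(12:14, 12:14),
                  squareMask(6:8, 12:14)),
             background = squareMask(12:14, 6:8))
}

# RoiTraceSet built directly from a raw matrix (one fly unless stated)
rtsFromMatrix <- function(raw, rate = 10, fly = NULL) {
  n <- nrow(raw)
  roiTraceSet(raw, time = (seq_len(ncol(raw)) - 1) / rate,
              roiData = data.frame(fly = if (is.null(fly)) rep(1L, n) else fly,
                                   roi = seq_len(n)),
              sampleRate = rate)
}

# short flash protocol for fast pipeline tests
shortFlashes <- function(total = 100, seed = 2L)
  buildRandomFlashes(totalDuration = total, seed = seed)

# per-fly peak matrices with given mean responses (flies x luminances)
peakMatrix <- function(meanPerLum, nFlies, sd = 0, lum = NULL) {
  if (is.null(lum)) lum <- seq_along(meanPerLum)
  m <- matrix(rep(meanPerLum, each = nFlies), nFlies) +
    matrix(rnorm(nFlies * length(meanPerLum), 0, sd), nFlies)
  colnames(m) <- as.character(lum)
  m
}
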