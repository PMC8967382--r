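## Run configuration: YAML/JSON, versioned schema, explicit seeds everywhere.

configSchema <- function() {
  list(
    version = list(default = 1L),
    seed = list(required = TRUE),
    protocol = list(children = list(
      flashes = list(children = list(
        totalDuration = list(default = 300),
        flashDuration = list(default = 10))),
      staircase = list(children = list(
        stepDuration = list(default = 10),
        nRepeats = list(default = 3L))),
      edges = list(children = list(
        kind = list(default = "ON"),
        nTrials = list(default = 10L))))),
    lmc = list(children = list(
      cellTypes = list(default = c("L1", "L2", "L3")),
      nFlies = list(default = 5L),
      roisPerFly = list(default = 8L),
      noiseSd = list(default = 0.05),
      pOffscreen = list(default = 0.1))),
    behavior = list(children = list(
      nFlies = list(default = 10L),
      pSlow = list(default = 0.25))),
    pipeline = list(children = list(
      nBoot = list(default = 50L),
      nPerm = list(default = 1000L),
      miShuffleCorrect = list(default = FALSE),
      alpha = list(default = 0.05))),
    output = list(children = list(
      dir = list(default = NA_character_))))
}

applySchema <- function(cfg, schema, path = "") {
  if (is.null(cfg)) cfg <- list()
  if (!is.list(cfg))
    stop("config section '", path, "' must be a mapping", call. = FALSE)
  unknown <- setdiff(names(cfg), names(schema))
  if (length(unknown))
    stop("unknown config key: '",
         paste0(sub("^\\.", "", paste0(path, ".", unknown[1]))),
         "'", call. = FALSE)
  out <- list()
  for (key in names(schema)) {
    spec <- schema[[key]]
    here <- paste0(path, ".", key)
    if (!is.null(spec$children)) {
      out[[key]] <- applySchema(cfg[[key]], spec$children, here)
    } else if (key %in% names(cfg)) {
      out[[key]] <- cfg[[key]]
    } else if (isTRUE(spec$required)) {
      stop("missing required config key: '", sub("^\\.", "", here),
           "' (explicit seeds are required)", call. = FALSE)
    } else {
      out[[key]] <- spec$default
    }
  }
  out
}

#' Validate and complete a run configuration
#'
#' Reads a YAML or JSON configuration, validates it against the package's
#' schema (unknown keys are rejected with their key path, an explicit `seed`
#' is required) and fills in defaults (e.g. `pipeline.nBoot = 50`,
#' `pipeline.nPerm = 1000`). A list can be passed directly in place of a
#' file path.
#'
#' @param path file path (`.yaml`/`.yml`/`.json`) or a configuration list.
#' @return the completed configuration list, with attribute `hash` (MD5 of
#'   its canonical JSON serialization).
#' @export
validateConfig <- function(path) {
  cfg <- if (is.list(path)) path
  else {
    if (!file.exists(path)) stop("config file not found: ", path)
    if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
      yaml::read_yaml(path)
    else jsonlite::read_json(path, simplifyVector = TRUE)
  }
  out <- applySchema(cfg, configSchema())
  attr(out, "hash") <- configHash(out)
  out
}

#' @rdname validateConfig
#' @param config a configuration list.
#' @export
configHash <- function(config) {
  attributes(config)[c("hash")] <- NULL
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA,
                       na = "null")
  unname(tools::md5sum(tmp))
}
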