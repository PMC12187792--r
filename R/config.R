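# Analysis configuration: one documented default per knob, JSON round-trip.

#' Analysis configuration
#'
#' Bundles every tunable policy of the pipeline with a documented default:
#'
#' * `dl_policy` — substitution for below-detection values (`"half"` = x/2).
#' * `replicate_rule` — replicate aggregation (`"median"`).
#' * `ree_reference` — named shale composition for REE normalization.
#' * `anomaly_band` — symmetric band around 1 within which a Ce/Ce* ratio
#'   is called "none" (default 0.10).
#' * `p_adjust` — multiplicity adjustment across a correlation screen
#'   (`"BH"`; raw p-values are always reported too).
#' * `np_low`, `np_high` — N:P mass-ratio thresholds below/above which
#'   growth is flagged N- or P-limited (defaults 14 and 16).
#' * `quartile_type` — [stats::quantile()] convention (default 7,
#'   linear interpolation).
#' * `median_of_logs` — if `TRUE`, clustering input is median(log10 x)
#'   instead of the default log10(median x).
#' * `bcf_excluder` — median BcF below which an element is called
#'   excluded (0.1, across all horizons).
#' * `ef_accumulated` — median EF at or above which an element is flagged
#'   as accumulated (10).
#' * `seed` — RNG seed recorded with every artifact.
#'
#' @param ... Named overrides of the defaults above.
#' @return A list of class `"accum_config"`.
#' @seealso [write_config()], [read_config()]
#' @export
#' @examples
#' analysis_config(anomaly_band = 0.05)
analysis_config <- function(...) {
  cfg <- list(
    dl_policy = "half",
    replicate_rule = "median",
    ree_reference = "PAAS-P2012",
    anomaly_band = 0.10,
    p_adjust = "BH",
    np_low = 14,
    np_high = 16,
    quartile_type = 7L,
    median_of_logs = FALSE,
    bcf_excluder = 0.1,
    ef_accumulated = 10,
    seed = 1L
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0) {
    abort(paste0(
      "Unknown config field(s): ", paste(unknown, collapse = ", ")
    ))
  }
  cfg <- modifyList(cfg, dots)
  structure(cfg, class = "accum_config")
}

#' Serialize / restore an analysis configuration
#'
#' The JSON round-trip is lossless: `read_config(write_config(cfg))`
#' reproduces `cfg` exactly.
#'
#' @param config An [analysis_config()] object.
#' @param path JSON file path.
#' @return `write_config()` returns `path` invisibly; `read_config()`
#'   returns the restored `"accum_config"` object.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "accum_config"))
  jsonlite::write_json(unclass(config), path,
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$quartile_type <- as.integer(raw$quartile_type)
  raw$seed <- as.integer(raw$seed)
  do.call(analysis_config, raw)
}

# Stable hash of a configuration (md5 of its canonical JSON), for manifests.
.config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(config), tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}
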