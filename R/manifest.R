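#' Write a run manifest
#'
#' Records everything needed to re-run a stage bit-identically: the
#' configuration snapshot, seed, package version, input file digests,
#' output paths and a timestamp.
#'
#' @param path output JSON path.
#' @param stage stage name (e.g. `"preprocess"`).
#' @param config named list of parameters.
#' @param seed integer seed used.
#' @param inputs,outputs character vectors of file paths; inputs are
#'   digested with MD5.
#' @return The path, invisibly.
#' @export
write_run_manifest <- function(path, stage, config, seed,
                               inputs = character(0),
                               outputs = character(0)) {
  digests <- if (length(inputs)) as.list(tools::md5sum(inputs)) else list()
  manifest <- list(stage = stage,
                   package = "dnmap",
                   version = as.character(utils::packageVersion("dnmap")),
                   timestamp = format(Sys.time(), tz = "UTC",
                                      "%Y-%m-%dT%H:%M:%SZ"),
                   seed = seed,
                   config = config,
                   input_md5 = digests,
                   outputs = as.list(outputs))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
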