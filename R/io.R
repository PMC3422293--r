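#' Write a simulation trace and its metadata
#'
#' The trace is written as a CSV (one row per recorded sample, the
#' documented column set) and the metadata needed to reproduce the run
#' bit-for-bit (full parameter document, dt, stride, protocol id) as a YAML
#' sidecar next to it.
#'
#' @param trace A `jsmc_trace`.
#' @param path CSV output path; the sidecar gets extension `.meta.yaml`.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  meta <- list(dt = attr(trace, "dt"), stride = attr(trace, "stride"),
               protocol = attr(trace, "protocol"),
               burn_in = attr(trace, "burn_in"),
               deterministic = TRUE,
               params = yaml::yaml.load(attr(trace, "params_yaml")))
  writeLines(yaml::as.yaml(meta, precision = 17),
             sub("\\.csv$", ".meta.yaml", path))
  invisible(path)
}

#' Read a trace written by [write_trace()]
#'
#' @param path CSV path.
#' @return A `jsmc_trace` with metadata restored from the sidecar.
#' @export
read_trace <- function(path) {
  tr <- utils::read.csv(path)
  meta_path <- sub("\\.csv$", ".meta.yaml", path)
  if (file.exists(meta_path)) {
    meta <- yaml::read_yaml(meta_path)
    attr(tr, "dt") <- meta$dt
    attr(tr, "stride") <- meta$stride
    attr(tr, "protocol") <- meta$protocol
    attr(tr, "burn_in") <- meta$burn_in
    attr(tr, "params_yaml") <- yaml::as.yaml(meta$params, precision = 17)
  }
  class(tr) <- c("jsmc_trace", "data.frame")
  tr
}

write_manifest <- function(path, command, config, overrides, outputs) {
  manifest <- list(command = command, config = config,
                   overrides = overrides, outputs = outputs,
                   tool = "jsmc",
                   version = as.character(utils::packageVersion("jsmc")),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  writeLines(yaml::as.yaml(manifest), path)
  invisible(path)
}
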