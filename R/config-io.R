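#' Read a network configuration from a YAML or JSON file
#'
#' The file holds a flat mapping whose keys are [NetworkConfig-class] slot
#' names; missing keys take the package defaults and unknown keys are an
#' error. The format is chosen by extension (`.yaml`/`.yml` or `.json`).
#'
#' @param path file path.
#' @return a validated [NetworkConfig-class].
#' @seealso [writeNetworkConfig()]
#' @export
readNetworkConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  vals <- switch(ext,
    yaml = ,
    yml = yaml::read_yaml(path),
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    stop("unsupported config format: .", ext)
  )
  if (!length(vals)) return(networkConfig())
  do.call(networkConfig, vals)
}

#' Write a network configuration
#'
#' @param cfg a [NetworkConfig-class].
#' @param path destination; format chosen by extension as in
#'   [readNetworkConfig()].
#' @return `path`, invisibly.
#' @export
writeNetworkConfig <- function(cfg, path) {
  vals <- configAsList(cfg)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    yaml = ,
    yml = yaml::write_yaml(vals, path),
    json = jsonlite::write_json(vals, path, auto_unbox = TRUE, digits = NA,
      pretty = TRUE),
    stop("unsupported config format: .", ext)
  )
  invisible(path)
}

#' Configuration as a plain named list
#'
#' @param cfg a [NetworkConfig-class].
#' @return named list of all slots.
#' @export
configAsList <- function(cfg) {
  nms <- slotNames("NetworkConfig")
  stats::setNames(lapply(nms, function(nm) slot(cfg, nm)), nms)
}
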