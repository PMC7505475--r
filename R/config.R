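#' Read a YAML configuration file
#'
#' Structured text configuration with sections `neuron`, `network`,
#' `drive` and `protocol`; all fields and units as in [neuron_params()],
#' [network_spec()] and [external_drive()]. Missing fields fall back to
#' the package defaults; the `protocol` section is returned as-is.
#'
#' @param path path to a YAML file (see
#'   `system.file("extdata", "default-config.yaml", package = "lifnet")`)
#' @return list with `neuron`, `spec`, `drive`, `protocol`
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  neuron <- do.call(neuron_params, cfg$neuron %||% list())
  spec <- do.call(network_spec, cfg$network %||% list())
  drive <- do.call(external_drive, cfg$drive %||% list())
  list(neuron = neuron, spec = spec, drive = drive,
       protocol = cfg$protocol %||% list())
}

#' Build a network realization from a configuration file
#'
#' @param path YAML configuration path
#' @param seed integer RNG seed
#' @return a `network_realization`
#' @export
build_from_config <- function(path, seed = 1) {
  cfg <- read_config(path)
  build_network(cfg$spec, cfg$neuron, cfg$drive, seed = seed)
}
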