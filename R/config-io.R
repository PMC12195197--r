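# YAML (de)serialization of the full configuration, mirroring the
# hyperparameter tables field for field.

#' Write / read a detector configuration as YAML
#'
#' @param config A [detector_config()].
#' @param path YAML file path.
#' @return `write_config` returns the path invisibly; `read_config`
#'   returns a [detector_config()].
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "detector_config"))
  x <- list(
    ldm = unclass(config$ldm),
    unet = unclass(config$unet),
    train = unclass(config$train),
    band = config$band,
    threshold = config$threshold,
    min_qrs_ms = config$min_qrs_ms,
    match_tol_ms = config$match_tol_ms)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  detector_config(
    ldm = do.call(ldm_config, x$ldm),
    unet = do.call(unet_config, x$unet),
    train = do.call(train_config, x$train),
    band = as.numeric(x$band),
    threshold = x$threshold,
    min_qrs_ms = x$min_qrs_ms,
    match_tol_ms = x$match_tol_ms)
}
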