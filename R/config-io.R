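#' Read / write the pipeline configuration
#'
#' The configuration is a single human-readable YAML file capturing every
#' numeric default of the pipeline ([default_config()]). Unknown keys raise
#' an error; missing keys fall back to the defaults, so a partial file
#' overrides only what it names. [run_batch()] embeds a hash of the
#' effective configuration in its manifest for reproducibility.
#'
#' @param path YAML file path.
#' @return For `read_config()`, a complete parameter list.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  base <- default_config()
  unknown <- setdiff(names(user), names(base))
  if (length(unknown) > 0)
    stop("config error: unknown keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  base[names(user)] <- user
  base
}

#' @rdname read_config
#' @param config Parameter list.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Hash of a configuration (for manifests)
#' @param config Parameter list.
#' @return Character hash.
#' @export
config_hash <- function(config) rlang::hash(config)
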