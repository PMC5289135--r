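#' Default pipeline configuration
#'
#' One nested list holding every tunable of the pipeline, serializable to
#' YAML.  `sketchmap$sigma = NULL` means "choose by [auto_sigma()]".
#'
#' @return Nested list of defaults.
#' @export
default_config <- function() {
  list(
    soap = list(cutoff = 4.0, atom_sigma = 0.3, n_max = 8L, l_max = 6L,
                zeta = 2, species_mask = character()),
    rematch = list(gamma = 0.1, normalize = TRUE, tol = 1e-6, max_iter = 500000L),
    sketchmap = list(sigma = NULL, n_bins = 100L, A_hd = 1, B_hd = 4,
                     a_ld = 1, b_ld = 4, n_landmarks = 500L, n_starts = 5L,
                     grid_n = 64L),
    cluster = list(cut_height = 0.1),
    diagnostics = list(max_size = 2L, min_height = 0.5,
                       sigma_D_max = 0.1, sigma_E_min = 0.25),
    seed = 42L
  )
}

merge_config <- function(base, override, path = "") {
  for (key in names(override)) {
    full <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!(key %in% names(base))) {
      abort(sprintf("unknown configuration key '%s'.", full))
    }
    is_block <- is.list(base[[key]]) && length(names(base[[key]])) > 0
    if (is_block && !is.null(override[[key]])) {
      base[[key]] <- merge_config(base[[key]], as.list(override[[key]]), full)
    } else {
      base[[key]] <- override[[key]]
    }
  }
  base
}

#' Read a pipeline configuration file
#'
#' YAML file with any subset of the [default_config()] keys; unknown keys
#' are rejected, missing ones take their defaults.
#'
#' @param path Path to a YAML file, or `NULL` for pure defaults.
#' @return The resolved configuration list.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    if (!is.null(user)) cfg <- merge_config(cfg, user)
  }
  cfg
}

#' Write the resolved configuration
#'
#' @param cfg Configuration list.
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}

config_soap_params <- function(cfg) {
  soap_params(cutoff = cfg$soap$cutoff, atom_sigma = cfg$soap$atom_sigma,
              n_max = cfg$soap$n_max, l_max = cfg$soap$l_max,
              zeta = cfg$soap$zeta,
              species_mask = cfg$soap$species_mask %||% character())
}
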