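# Run configuration: one YAML document bundling paths, optics, scattering
# parameters, analysis settings, deconvolution plan and seeds, with explicit
# defaults so a saved config reloads identically.

default_run_config <- function() {
  list(
    paths = list(input = NULL, output_dir = "."),
    optics = list(beam_type = "gaussian", lambda_ill = 0.488,
                  lambda_det = 0.52, na_ill = 0.15, na_det = 0.8,
                  n_medium = 1.33, sheet_fov = 300, d_slit = 50,
                  magnification = 40, bessel_ring_frac = 0.05),
    scattering = list(mu_sca = NULL, gamma = NULL, sigma_coef = 1 / sqrt(3)),
    analysis = list(d_cell = 20, k_c = NULL, n_l = 0.002, b = 2, n_ref = 3,
                    n_theta = 16, fit_mode = "widefield", n_boot = 200,
                    ref_snr_min = 20),
    deconv = list(n_sections = 12, wiener_A = 1e4, neighborhood = FALSE),
    phantom = list(kind = "membrane_lattice",
                   dims_um = c(41.6, 60, 41.6),
                   pitch = c(0.1625, 0.5, 0.1625),
                   inner_cell_size = c(5, 7), outer_cell_size = c(10, 20),
                   membrane_thickness = 0.4,
                   bead_radius = 2, bead_count = 40),
    noise = list(photon_budget = 5000, read_noise = 3),
    seeds = list(phantom = 1L, noise = 1L),
    log_level = "info"
  )
}

merge_defaults <- function(user, def) {
  for (nm in names(def)) {
    if (is.null(user[[nm]])) {
      user[nm] <- list(def[[nm]])
    } else if (is.list(def[[nm]]) && is.list(user[[nm]])) {
      user[[nm]] <- merge_defaults(user[[nm]], def[[nm]])
    }
  }
  user
}

#' Read a run configuration
#'
#' Loads a YAML config and fills every missing entry with the package
#' default, so the returned object always carries explicit values and a
#' save/load round trip is the identity.
#'
#' @param path YAML file, or `NULL` for pure defaults.
#' @return named list of class `run_config`.
#' @export
read_run_config <- function(path = NULL) {
  user <- if (is.null(path)) list() else yaml::read_yaml(path)
  cfg <- merge_defaults(user, default_run_config())
  structure(cfg, class = c("run_config", "list"))
}

#' Save a run configuration as YAML
#' @param config a `run_config`.
#' @param path output path.
#' @export
save_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path, precision = 15)
  invisible(path)
}

#' Build the typed objects a run needs from a config
#' @param config a `run_config`.
#' @return list with `optics`, `params` (or NULL), `plan_args`, etc.
#' @keywords internal
config_objects <- function(config) {
  num <- function(x) as.numeric(unlist(x))   # YAML may hand back lists
  config$phantom[c("dims_um", "pitch", "inner_cell_size", "outer_cell_size")] <-
    lapply(config$phantom[c("dims_um", "pitch", "inner_cell_size",
                            "outer_cell_size")], num)
  o <- config$optics
  optics <- optics_config(
    beam_type = o$beam_type, lambda_ill = o$lambda_ill,
    lambda_det = o$lambda_det, na_ill = o$na_ill, na_det = o$na_det,
    n_medium = o$n_medium, sheet_fov = o$sheet_fov, d_slit = o$d_slit,
    magnification = o$magnification, bessel_ring_frac = o$bessel_ring_frac
  )
  params <- NULL
  if (!is.null(config$scattering$mu_sca) && !is.null(config$scattering$gamma)) {
    params <- scattering_params(config$scattering$mu_sca,
                                config$scattering$gamma,
                                config$scattering$sigma_coef)
  }
  ph <- config$phantom
  pspec <- phantom_spec(
    kind = ph$kind, dims_um = ph$dims_um, pitch = ph$pitch,
    inner_cell_size = ph$inner_cell_size, outer_cell_size = ph$outer_cell_size,
    membrane_thickness = ph$membrane_thickness, bead_radius = ph$bead_radius,
    bead_count = ph$bead_count, rng_seed = config$seeds$phantom
  )
  nm <- noise_model(config$noise$photon_budget, config$noise$read_noise,
                    config$seeds$noise)
  list(optics = optics, params = params, phantom_spec = pspec, noise = nm)
}
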