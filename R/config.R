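#' Read a YAML run configuration
#'
#' Orchestration settings for end-to-end runs, with every omitted field
#' filled from package defaults (and reported via \code{message} so a run
#' log records the effective configuration). Blocks: \code{growth}
#' (\code{alpha_per_day}, \code{beta_per_day}, \code{d0_um},
#' \code{d_lethal_mm}), \code{solver} (\code{dt_years}, \code{method}),
#' \code{inference} (\code{lower}, \code{upper}, \code{init},
#' \code{n_starts}, \code{bootstrap_B}), \code{simulation}
#' (\code{n_patients}, \code{theta_true}, \code{bin_weights},
#' \code{subtype_weights}, \code{seed}), \code{cv} (\code{k}, \code{seed},
#' \code{grid_step}), and \code{output_dir}.
#'
#' @param path YAML file, or \code{NULL} for all defaults.
#' @return A validated \code{run_config} list.
#' @export
read_run_config <- function(path = NULL) {
  user <- if (is.null(path)) list() else yaml::read_yaml(path)
  defaults <- list(
    growth = list(alpha_per_day = 0.0359, beta_per_day = 0.0013,
                  d0_um = 10, d_lethal_mm = 100),
    solver = list(dt_years = 1e-3, method = "euler"),
    inference = list(lower = 0, upper = 10, init = 0.01, n_starts = 5,
                     bootstrap_B = 50, seed = 1),
    simulation = list(n_patients = 1000,
                      theta_true = as.list(unclass(default_theta_true())),
                      bin_weights = table1_bin_weights(),
                      subtype_weights = as.list(table1_subtype_weights()),
                      seed = 1),
    cv = list(k = 10, seed = 1, grid_step = 0.25),
    output_dir = "."
  )
  merged <- defaults
  for (block in names(user)) {
    if (!block %in% names(defaults))
      stop("unknown configuration block: ", block)
    if (is.list(defaults[[block]])) {
      unknown <- setdiff(names(user[[block]]), names(defaults[[block]]))
      if (length(unknown))
        stop("unknown field(s) in '", block, "': ",
             paste(unknown, collapse = ", "))
      merged[[block]][names(user[[block]])] <- user[[block]]
    } else {
      merged[[block]] <- user[[block]]
    }
  }
  for (block in setdiff(names(defaults), names(user)))
    message("config: block '", block, "' using defaults")
  if (!merged$solver$method %in% c("euler", "expm"))
    stop("solver method must be 'euler' or 'expm'")
  stopifnot(merged$solver$dt_years > 0,
            merged$simulation$n_patients >= 1,
            merged$cv$k >= 2)
  structure(merged, class = "run_config")
}

#' Gompertz parameters from a run config
#' @param config A \code{run_config}.
#' @keywords internal
#' @export
config_growth <- function(config) {
  gompertz_params(alpha = config$growth$alpha_per_day,
                  beta = config$growth$beta_per_day,
                  d0_um = config$growth$d0_um,
                  d_lethal_mm = config$growth$d_lethal_mm)
}

#' Simulation config from a run config
#' @param config A \code{run_config}.
#' @keywords internal
#' @export
config_sim <- function(config) {
  sim <- config$simulation
  sim_config(n_patients = sim$n_patients,
             theta_true = as_rate_vector(unlist(sim$theta_true)),
             growth = config_growth(config),
             diameter_dist = list(family = "bins",
                                  breaks = c(0, 20, 40, 60, 80, 100),
                                  weights = unlist(sim$bin_weights)),
             subtype_weights = unlist(sim$subtype_weights),
             seed = sim$seed)
}
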