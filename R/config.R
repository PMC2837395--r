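#' Simulation configuration
#'
#' Gathers every simulation parameter by name. The defaults reproduce the
#' reference conditions: b0 = 707.445 (recalibrated per seed genome unless
#' `calibrate_b0 = FALSE`), stationary-phase b0 = 235.815, death rate 0.005,
#' fluctuation rate 0.01, penalty coefficient 100, optimal concentration 0.4
#' (0.04 under starvation), base mutation rate 1e-4, temperatures 0.85 and
#' 1.00, carrying capacity 5000, seed population 500, stress at t = 20000,
#' and a 10,000-structure representative set.
#'
#' @param b0 Base growth rate (the published instance; see `calibrate_b0`).
#' @param b0_stationary Base growth rate after the stationary-phase stress.
#' @param d Death rate per step.
#' @param r Fluctuation probability per gene per step.
#' @param sigma Overproduction penalty coefficient.
#' @param C0 Optimal total protein concentration.
#' @param C0_starvation Optimal concentration under starvation.
#' @param m_min,m_max Mutation-rate bounds per gene per replication.
#' @param T,T_high Reference and heat-shock temperatures.
#' @param theta_nat Lethality stability threshold.
#' @param G_ref Reference functional-MMR concentration; `NA` means calibrate
#'   to the seed cell.
#' @param calibrate_b0 Recalibrate b0 so the seed birth rate equals `d`
#'   (each run's seed genome differs, so the published b0 is one instance).
#' @param cap Carrying capacity (chemostat culling threshold).
#' @param n_seed Seed population size.
#' @param t_max Number of time steps.
#' @param t_apply Stress application step.
#' @param n_struct Size of the representative structure set.
#' @param seed Master RNG seed; all randomness derives from it.
#' @param protocol `"none"`, `"heat_shock"`, `"stationary_phase"`,
#'   `"starvation"`, or `"constant_fitness"`.
#' @param C_init Optional initial per-gene concentrations (default C0/4
#'   each).
#' @param record_every Time-series recording period.
#' @param log_divisions Also log divisions, deaths and culls (full
#'   provenance; memory-heavy, meant for short runs).
#' @param k_form Binding-constant convention (`"min_energy"` or
#'   `"mode_sum"`).
#' @param design Design thresholds (list: `p_nat_threshold`,
#'   `p_int_threshold`, `max_steps`).
#' @param constant_b Fixed birth rate for `protocol = "constant_fitness"`.
#' @param stress_new_value Optional explicit stressed parameter value.
#' @return A validated `run_config` object.
#' @export
run_config <- function(b0 = 707.445, b0_stationary = 235.815, d = 0.005,
                       r = 0.01, sigma = 100, C0 = 0.4, C0_starvation = 0.04,
                       m_min = 1e-4, m_max = 0.1, T = 0.85, T_high = 1.00,
                       theta_nat = 0.6, G_ref = NA_real_, calibrate_b0 = TRUE,
                       cap = 5000, n_seed = 500, t_max = 30000, t_apply = 20000,
                       n_struct = 10000, seed = 1, protocol = "none",
                       C_init = NULL, record_every = 1, log_divisions = FALSE,
                       k_form = "centered",
                       design = list(p_nat_threshold = 0.85,
                                     p_int_threshold = 0.8,
                                     max_steps = 30000),
                       constant_b = NULL, stress_new_value = NULL) {
  cfg <- as.list(environment())
  validate_config(structure(cfg, class = "run_config"))
}

validate_config <- function(config) {
  if (!inherits(config, "run_config"))
    abort("`config` must be a run_config", class = "mutatorsim_config_error")
  chk <- function(cond, key) if (!cond)
    abort(paste0("invalid config value for `", key, "`"),
          class = "mutatorsim_config_error")
  with(config, {
    chk(is.numeric(b0) && b0 > 0, "b0")
    chk(d >= 0 && d <= 1, "d")
    chk(r >= 0 && r <= 1, "r")
    chk(sigma >= 0, "sigma")
    chk(C0 > 0, "C0")
    chk(m_min > 0 && m_min < 0.01, "m_min")
    chk(m_max > 0.01, "m_max")
    chk(T > 0 && T_high > 0, "T")
    chk(theta_nat > 0 && theta_nat < 1, "theta_nat")
    chk(cap >= 1 && n_seed >= 1, "cap")
    chk(t_max >= 0 && t_apply >= 1, "t_max")
    chk(n_struct >= 1, "n_struct")
    chk(protocol %in% c("none", "heat_shock", "stationary_phase",
                        "starvation", "constant_fitness"), "protocol")
    chk(is.null(C_init) || (length(C_init) == 4 && all(C_init > 0)), "C_init")
    chk(record_every >= 1, "record_every")
    chk(k_form %in% c("centered", "min_energy", "mode_sum"), "k_form")
  })
  defaults <- formals(run_config)$design
  config$design <- utils::modifyList(eval(defaults), config$design %||% list())
  config$t_apply <- as.integer(config$t_apply)
  config$t_max <- as.integer(config$t_max)
  config$record_every <- as.integer(config$record_every)
  config
}

#' Load a simulation configuration from a YAML file
#'
#' An empty file yields the full default configuration; unknown keys are
#' rejected with the offending key path.
#'
#' @param path Path to a YAML config file.
#' @return A validated `run_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path))
    abort(paste0("config file not found: ", path),
          class = "mutatorsim_config_error")
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    abort(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")),
          class = "mutatorsim_config_error")
  if (!is.null(vals$C_init)) vals$C_init <- as.numeric(vals$C_init)
  do.call(run_config, vals)
}

#' Save a configuration to YAML
#'
#' @param config A `run_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  config <- validate_config(config)
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
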