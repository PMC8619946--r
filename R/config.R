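#' Default run configuration
#'
#' The configuration a simulation run starts from before any file or CLI
#' overrides: the 60 L/min operating point, 100 tracked particles, default
#' geometry and material constants, mass-weighted summaries and the 5 um
#' respirable cut-off.
#'
#' @return Nested named list (see [load_config()] for the schema).
#' @export
default_config <- function() {
  list(
    formulation = "F1",
    n = 100L,
    seed = NULL,              # mandatory for simulation runs
    flow = list(
      Q_lpm = 60,
      swirl_number = 2,
      gridded_field_path = NULL
    ),
    geometry = list(
      chamber_radius_mm = 14.0,
      grid_z_mm = 25.0,
      total_height_mm = 47.5,
      outlet_diameter_mm = 10.0,
      inlet_width_mm = 1.5,
      inlet_height_mm = 6.0,
      injection_z_mm = 12.0,
      grid_porosity = 0.6
    ),
    materials = list(
      E_s = 4.1e9, E_p = 1e9, v_s = 0.35, v_p = 0.40,
      W_A = 0.039, k_s = 0.50, f = 1.70, C_u = 1,
      mu = 1.7894e-5, rho_air = 1.225, e_n = 0.8, lift_enabled = TRUE
    ),
    tracking = list(
      max_time = 0.5,
      dt_tau_fraction = 0.2,
      max_step_displacement_mm = 0.2,
      gravity_on = FALSE
    ),
    metrics = list(
      fpf_cutoff_um = 5,
      weighting = "mass"
    )
  )
}

# recursively overlay user values onto defaults, rejecting unknown keys
merge_config <- function(defaults, user, path = "") {
  if (is.null(user)) return(defaults)
  if (!is.list(user)) {
    stop("config section '", path, "' must be a mapping", call. = FALSE)
  }
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) {
    stop("unknown config key", if (length(unknown) > 1) "s", " '",
         paste0(path, unknown, collapse = "', '"), "'", call. = FALSE)
  }
  for (k in names(user)) {
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]]))) {
      defaults[[k]] <- merge_config(defaults[[k]], user[[k]],
                                    paste0(path, k, "."))
    } else {
      val <- user[[k]]
      # YAML 1.1 parses exponents like 2.0e9 (no sign) as strings; accept
      # any character value that cleanly reads as a number where the
      # default is numeric
      if (is.numeric(defaults[[k]]) && is.character(val)) {
        num <- suppressWarnings(as.numeric(val))
        if (is.na(num)) {
          stop("config key '", path, k, "' must be numeric, got '", val, "'",
               call. = FALSE)
        }
        val <- num
      }
      defaults[[k]] <- val
    }
  }
  defaults
}

validate_config <- function(cfg) {
  if (!is.numeric(cfg$flow$Q_lpm) || cfg$flow$Q_lpm <= 0) {
    stop("config key 'flow.Q_lpm' must be > 0, got ", cfg$flow$Q_lpm,
         call. = FALSE)
  }
  if (!is.numeric(cfg$n) || cfg$n < 1) {
    stop("config key 'n' must be >= 1", call. = FALSE)
  }
  if (!cfg$metrics$weighting %in% c("mass", "number")) {
    stop("config key 'metrics.weighting' must be 'mass' or 'number'",
         call. = FALSE)
  }
  if (!is.null(cfg$seed) && (!is.numeric(cfg$seed) || cfg$seed != round(cfg$seed))) {
    stop("config key 'seed' must be an integer", call. = FALSE)
  }
  cfg
}

#' Load and validate a run configuration
#'
#' Reads a hierarchical YAML configuration file, overlays it on
#' [default_config()], rejects unknown keys (typos fail loudly rather than
#' silently using a default) and validates values. An empty file yields the
#' full default configuration.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return Validated configuration list.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file '", path, "' not found",
                                 call. = FALSE)
    user <- yaml::read_yaml(path)
    cfg <- merge_config(cfg, user)
  }
  validate_config(cfg)
}

#' Assemble model objects from a configuration
#'
#' @param cfg A [load_config()] configuration.
#' @return List with `formulation`, `geometry`, `materials`, `field`.
#' @export
build_from_config <- function(cfg) {
  geo <- build_geometry(
    chamber_radius_mm = cfg$geometry$chamber_radius_mm,
    grid_z_mm = cfg$geometry$grid_z_mm,
    total_height_mm = cfg$geometry$total_height_mm,
    outlet_diameter_mm = cfg$geometry$outlet_diameter_mm,
    inlet_width_mm = cfg$geometry$inlet_width_mm,
    inlet_height_mm = cfg$geometry$inlet_height_mm,
    injection_z_mm = cfg$geometry$injection_z_mm,
    grid_porosity = cfg$geometry$grid_porosity)
  mats <- do.call(material_params, cfg$materials)
  field <- if (!is.null(cfg$flow$gridded_field_path)) {
    load_gridded_field(cfg$flow$gridded_field_path)
  } else {
    analytic_swirl_field(geo, Q = cfg$flow$Q_lpm / 6e4,
                         swirl_number = cfg$flow$swirl_number)
  }
  list(formulation = get_formulation(cfg$formulation),
       geometry = geo, materials = mats, field = field)
}

#' Run a full simulation from a configuration
#'
#' Convenience wrapper: assembles geometry, materials and flow field from a
#' configuration, runs the tracker, and appends an aerodynamic summary of
#' the emitted aerosol (binned at the standard impactor cut-offs).
#'
#' @param cfg A [load_config()] configuration (must carry a `seed`).
#' @param seed Optional override of `cfg$seed`.
#' @return List with `fates`, `impacts`, `summary` (tracker output),
#'   `summary_number` (number-weighted), and `aero` (an [aero_summary()] of
#'   the emitted particles, or `NULL` if nothing was emitted).
#' @export
run_from_config <- function(cfg, seed = cfg$seed) {
  if (is.null(seed)) {
    stop("a 'seed' is required (set it in the config or pass it explicitly)",
         call. = FALSE)
  }
  parts <- build_from_config(cfg)
  sim <- run_simulation(
    parts$formulation, parts$geometry, parts$field,
    n = cfg$n, seed = seed, materials = parts$materials,
    max_time = cfg$tracking$max_time,
    dt_tau_fraction = cfg$tracking$dt_tau_fraction,
    max_step_displacement = cfg$tracking$max_step_displacement_mm * 1e-3,
    gravity_on = cfg$tracking$gravity_on)
  sim$summary <- summarize_fates(sim$fates, weighting = cfg$metrics$weighting)
  sim$summary_number <- summarize_fates(sim$fates, weighting = "number")
  emitted <- sim$fates[sim$fates$final_status == "emitted", ]
  sim$aero <- NULL
  if (nrow(emitted) >= 2L) {
    # diameters are sampled from the volume-weighted size law, so every
    # tracked particle stands for an equal mass of powder: bin with equal
    # weights rather than d^3 masses (which would double-weight volume)
    n_tot <- nrow(sim$fates)
    st0 <- bin_to_stages(emitted$d_ae_um, rep(1 / n_tot, nrow(emitted)))
    device_mass <- (n_tot - nrow(emitted)) / n_tot
    st <- stage_table(label = c("device", st0$label),
                      cutoff_um = c(NA, st0$cutoff_um),
                      mass = c(device_mass, st0$mass))
    sim$aero <- tryCatch(
      aero_summary(st, fpf_cutoff_um = cfg$metrics$fpf_cutoff_um),
      error = function(e) {
        warning("aerodynamic summary not computable: ", conditionMessage(e),
                call. = FALSE)
        NULL
      })
  }
  sim
}
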