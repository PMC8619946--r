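#' Built-in formulation micromeritics
#'
#' The five solid-lipid-microparticle powder formulations used throughout the
#' package examples, with their laser-diffraction volume quantiles (um) and
#' pycnometric true densities (g/cm^3).
#'
#' @return Data.frame with columns `name`, `dv10_um`, `dv50_um`, `dv90_um`,
#'   `span`, `true_density_g_cm3`.
#' @export
builtin_formulations <- function() {
  data.frame(
    name = c("F1", "F2", "F3", "F4", "F5"),
    dv10_um = c(2.24, 2.43, 2.20, 1.87, 2.26),
    dv50_um = c(4.42, 4.67, 4.03, 5.13, 3.94),
    dv90_um = c(8.84, 8.51, 7.10, 12.21, 6.63),
    span = c(1.492, 1.304, 1.217, 2.016, 1.110),
    true_density_g_cm3 = c(1.050, 1.060, 1.170, 1.230, 1.030),
    stringsAsFactors = FALSE
  )
}

#' Fetch one built-in formulation as a record
#'
#' @param name One of `"F1"`..`"F5"`.
#' @return A [formulation_record()].
#' @export
get_formulation <- function(name) {
  tab <- builtin_formulations()
  row <- tab[tab$name == name, ]
  if (nrow(row) != 1L) {
    stop("unknown formulation '", name, "'; available: ",
         paste(tab$name, collapse = ", "), call. = FALSE)
  }
  formulation_record(row$name, row$dv10_um, row$dv50_um, row$dv90_um,
                     row$true_density_g_cm3, span = row$span)
}

#' Generate a synthetic impactor stage table from a lognormal aerosol
#'
#' Emulates the deposition pattern a cascade impactor would record for an
#' aerosol whose aerodynamic size distribution is lognormal: samples particle
#' diameters, assumes ideal sharp-cut stages, and bins unit-density sphere
#' masses onto the stage cut-offs. Synthetic data for demonstrations and
#' fixtures -- real impactor tables include wall losses and non-ideal stage
#' efficiency curves that this generator does not emulate.
#'
#' @param mmad_um Median aerodynamic diameter of the aerosol (um). Default 4.
#' @param gsd Geometric standard deviation. Default 2.
#' @param n_particles Number of sampled particles. Default 1e5.
#' @param seed Integer seed (required).
#' @param cutoffs Stage cut-offs (um), default [ngi_cutoffs_60lpm()].
#' @param device_fraction Fraction of the metered dose retained in the
#'   device, prepended as a `device` row. Default 0.1.
#' @return A [stage_table()] with `device`, `IP`, sizing stages and `MOC`
#'   rows; total mass normalized to 1.
#' @export
synthetic_stage_table <- function(mmad_um = 4, gsd = 2, n_particles = 1e5,
                                  seed, cutoffs = ngi_cutoffs_60lpm(),
                                  device_fraction = 0.1) {
  if (missing(seed) || is.null(seed)) {
    stop("'seed' is required", call. = FALSE)
  }
  if (mmad_um <= 0 || gsd < 1) stop("need mmad_um > 0 and gsd >= 1", call. = FALSE)
  if (device_fraction < 0 || device_fraction >= 1) {
    stop("'device_fraction' must lie in [0, 1)", call. = FALSE)
  }
  old <- .Random.seed_exists()
  # mass-weighted sampling: draw diameters directly from the mass
  # distribution, so each draw carries equal mass
  set.seed(as.integer(seed))
  d <- stats::rlnorm(n_particles, meanlog = log(mmad_um), sdlog = log(gsd))
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  st <- bin_to_stages(d, mass = rep(1 / n_particles, n_particles),
                      cutoffs = cutoffs)
  emitted <- 1 - device_fraction
  st$mass <- st$mass * emitted
  out <- stage_table(label = c("device", st$label),
                     cutoff_um = c(NA, st$cutoff_um),
                     mass = c(device_fraction, st$mass),
                     flow_lpm = attr(st, "flow_lpm"))
  attr(out, "generator") <- list(mmad_um = mmad_um, gsd = gsd,
                                 n_particles = n_particles, seed = seed,
                                 device_fraction = device_fraction)
  out
}

#' Read a stage table from CSV
#'
#' Expects columns `stage,label,cutoff_um,mass` (or just
#' `label,cutoff_um,mass`); empty/NA cut-offs mark non-sizing rows (device,
#' induction port, final collector).
#'
#' @param path CSV path.
#' @param flow_lpm Flow-rate metadata (L/min).
#' @return A [stage_table()].
#' @export
read_stage_table <- function(path, flow_lpm = 60) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("label", "cutoff_um", "mass") %in% names(df))) {
    stop("stage-table CSV '", path,
         "' must have columns label,cutoff_um,mass", call. = FALSE)
  }
  stage_table(df$label, as.numeric(df$cutoff_um), as.numeric(df$mass),
              flow_lpm = flow_lpm)
}

#' Write fixture files
#'
#' Writes the built-in formulation table, the default material constants and
#' a seeded synthetic impactor stage table (with a JSON sidecar recording the
#' generator parameters) into a directory.
#'
#' @param out_dir Target directory (created if absent).
#' @param seed Seed for the synthetic stage table. Default 20210101.
#' @return Invisibly, the paths written.
#' @export
make_fixtures <- function(out_dir, seed = 20210101) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) {
    stop("cannot create fixture directory '", out_dir, "'", call. = FALSE)
  }
  f_form <- file.path(out_dir, "formulations.csv")
  utils::write.csv(builtin_formulations(), f_form, row.names = FALSE)

  m <- material_params()
  mat <- data.frame(
    parameter = c("E_s", "E_p", "v_s", "v_p", "W_A", "k_s", "f", "C_u",
                  "mu", "rho_air", "e_n"),
    value = c(m$E_s, m$E_p, m$v_s, m$v_p, m$W_A, m$k_s, m$f, m$C_u,
              m$mu, m$rho_air, m$e_n),
    unit = c("Pa", "Pa", "-", "-", "J/m^2", "-", "-", "-", "Pa s",
             "kg/m^3", "-"),
    stringsAsFactors = FALSE)
  f_mat <- file.path(out_dir, "materials.csv")
  utils::write.csv(mat, f_mat, row.names = FALSE)

  st <- synthetic_stage_table(seed = seed)
  f_st <- file.path(out_dir, "synthetic_stage_table.csv")
  utils::write.csv(
    data.frame(stage = seq_len(nrow(st)), label = st$label,
               cutoff_um = st$cutoff_um, mass = st$mass),
    f_st, row.names = FALSE)
  f_side <- file.path(out_dir, "synthetic_stage_table.json")
  jsonlite::write_json(attr(st, "generator"), f_side, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(c(formulations = f_form, materials = f_mat,
              stage_table = f_st, sidecar = f_side))
}

#' Write a fate table to CSV
#'
#' @param fates Fate data.frame from [run_simulation()].
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_fate_table <- function(fates, path) {
  utils::write.csv(fates, path, row.names = FALSE)
  invisible(path)
}
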