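#' Formulation micromeritics
#'
#' A `formulation_record` holds the laser-diffraction size quantiles and
#' helium-pycnometry true density of a powder formulation: the cumulative
#' undersize volume diameters d_v10, d_v50 and d_v90 (micrometres), the span
#' `(d_v90 - d_v10) / d_v50`, and the true particle density (g/cm^3). These
#' are the inputs the simulator needs to inject a realistic polydisperse
#' aerosol.
#'
#' @param name Formulation label, e.g. `"F1"`.
#' @param dv10,dv50,dv90 Volume-distribution quantile diameters (um), strictly
#'   increasing.
#' @param true_density True (skeletal) density (g/cm^3).
#' @param span Optional printed span; if supplied it must agree with
#'   `(dv90 - dv10) / dv50` within ±0.005, the self-consistency expected of a
#'   correctly transcribed size table.
#' @return A `formulation_record` (list).
#' @examples
#' f1 <- formulation_record("F1", 2.24, 4.42, 8.84, 1.050, span = 1.492)
#' @export
formulation_record <- function(name, dv10, dv50, dv90, true_density,
                               span = NULL) {
  if (!(dv10 > 0 && dv10 < dv50 && dv50 < dv90)) {
    stop("size quantiles must satisfy 0 < dv10 < dv50 < dv90; got (",
         dv10, ", ", dv50, ", ", dv90, ")", call. = FALSE)
  }
  if (!is.finite(true_density) || true_density <= 0) {
    stop("'true_density' must be > 0 (g/cm^3)", call. = FALSE)
  }
  computed <- compute_span(dv10, dv50, dv90)
  if (!is.null(span) && abs(span - computed) > 0.005) {
    stop("printed span ", span, " disagrees with (dv90-dv10)/dv50 = ",
         round(computed, 4), " by more than 0.005 for formulation '", name,
         "'", call. = FALSE)
  }
  structure(list(name = name, dv10 = dv10, dv50 = dv50, dv90 = dv90,
                 span = computed, true_density = true_density),
            class = "formulation_record")
}

#' @export
print.formulation_record <- function(x, ...) {
  cat(sprintf("Formulation %s: dv10/50/90 = %.2f/%.2f/%.2f um, span %.3f, rho_p %.3f g/cm^3\n",
              x$name, x$dv10, x$dv50, x$dv90, x$span, x$true_density))
  invisible(x)
}

#' Span of a volume size distribution
#'
#' `span = (d_v90 - d_v10) / d_v50`, the standard width measure reported with
#' laser-diffraction size data.
#'
#' @param dv10,dv50,dv90 Quantile diameters (um), strictly increasing.
#' @return Dimensionless span (> 0).
#' @examples
#' compute_span(1.87, 5.13, 12.21)  # 2.016
#' @export
compute_span <- function(dv10, dv50, dv90) {
  if (!(dv10 > 0 && dv10 < dv50 && dv50 < dv90)) {
    stop("size quantiles must satisfy 0 < dv10 < dv50 < dv90", call. = FALSE)
  }
  (dv90 - dv10) / dv50
}

#' Fit a Rosin-Rammler distribution to three size quantiles
#'
#' The Rosin-Rammler (Weibull) law, `F(d) = 1 - exp(-(d/delta)^n)`, is the
#' conventional description of dispersed/sprayed powders and the injection
#' distribution assumed by the simulator. Its two parameters are fitted to
#' the three measured quantiles by least squares on log quantiles: under the
#' law, `log(-log(1 - q)) = n * (log d_q - log delta)` is linear in `log d_q`,
#' so the fit is an exact ordinary least-squares line through three points and
#' round-trips exactly for quantiles that are themselves Rosin-Rammler.
#'
#' @param dv10,dv50,dv90 Quantile diameters (um), strictly increasing.
#' @param d_min,d_max Truncation bounds (um) attached to the returned
#'   parameter object and honoured by [sample_diameters()]. Defaults
#'   `dv10 / 2` and `1.5 * dv90`.
#' @return A `rosin_rammler` object: list with `delta` (um), `n`, `d_min`,
#'   `d_max`, and `residual` (root-mean-square log-quantile misfit).
#' @examples
#' p <- fit_rosin_rammler(1.623, 4.163, 7.587)  # recovers delta = 5, n = 2
#' @export
fit_rosin_rammler <- function(dv10, dv50, dv90,
                              d_min = dv10 / 2, d_max = 1.5 * dv90) {
  if (!(dv10 > 0 && dv10 < dv50 && dv50 < dv90)) {
    stop("size quantiles must satisfy 0 < dv10 < dv50 < dv90", call. = FALSE)
  }
  if (!(d_min > 0 && d_min < d_max)) {
    stop("truncation bounds must satisfy 0 < d_min < d_max", call. = FALSE)
  }
  q <- c(0.10, 0.50, 0.90)
  y <- log(-log(1 - q))
  x <- log(c(dv10, dv50, dv90))
  # OLS slope/intercept of y on x
  n_hat <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  if (!is.finite(n_hat) || n_hat <= 0) {
    stop("Rosin-Rammler fit failed: non-positive spread exponent", call. = FALSE)
  }
  log_delta <- mean(x) - mean(y) / n_hat
  delta <- exp(log_delta)
  resid <- sqrt(mean((y - n_hat * (x - log_delta))^2))
  structure(list(delta = delta, n = n_hat, d_min = d_min, d_max = d_max,
                 residual = resid),
            class = "rosin_rammler")
}

#' @export
print.rosin_rammler <- function(x, ...) {
  cat(sprintf("Rosin-Rammler: delta = %.4g um, n = %.4g, support [%.3g, %.3g] um (fit rms %.2e)\n",
              x$delta, x$n, x$d_min, x$d_max, x$residual))
  invisible(x)
}

#' Rosin-Rammler quantile function
#'
#' `d(q) = delta * (-log(1 - q))^(1/n)`, the closed-form inverse CDF of the
#' untruncated law.
#'
#' @param q Probabilities in (0, 1).
#' @param params A [fit_rosin_rammler()] object or a list with `delta`, `n`.
#' @return Diameters (um).
#' @export
rosin_rammler_quantile <- function(q, params) {
  stopifnot(all(q > 0 & q < 1))
  params$delta * (-log(1 - q))^(1 / params$n)
}

#' Sample particle diameters from a truncated Rosin-Rammler law
#'
#' Inverse-CDF sampling restricted to `[d_min, d_max]` by transforming uniform
#' draws onto the CDF mass inside the truncation window (equivalent to
#' rejection outside the window but exact in one pass). Reproducible for a
#' given seed.
#'
#' @param params A `rosin_rammler` parameter object.
#' @param n Number of samples (>= 1).
#' @param seed Integer seed; required so that simulation runs are
#'   reproducible.
#' @return Numeric vector of `n` diameters (um) inside `[d_min, d_max]`.
#' @export
sample_diameters <- function(params, n, seed) {
  if (!is.numeric(n) || length(n) != 1L || n < 1) {
    stop("'n' must be a positive count", call. = FALSE)
  }
  if (missing(seed) || is.null(seed)) {
    stop("'seed' is required for reproducible sampling", call. = FALSE)
  }
  n <- as.integer(n)
  cdf <- function(d) 1 - exp(-(d / params$delta)^params$n)
  lo <- cdf(params$d_min)
  hi <- cdf(params$d_max)
  if (hi <= lo) stop("empty truncation window", call. = FALSE)
  old <- .Random.seed_exists()
  set.seed(as.integer(seed))
  uu <- stats::runif(n, min = lo, max = hi)
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  params$delta * (-log(1 - uu))^(1 / params$n)
}

# snapshot of the RNG state, or NULL if none yet
.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
  } else NULL
}

#' Aerodynamic diameter of a sphere
#'
#' `d_ae = d_g * sqrt(rho_p / rho_0)` with reference density
#' `rho_0 = 1 g/cm^3`: the diameter of a unit-density sphere settling at the
#' same terminal velocity as the particle.
#'
#' @param d_g Geometric diameter (um), > 0. Vectorized.
#' @param rho_p True particle density (g/cm^3), > 0.
#' @return Aerodynamic diameter (um).
#' @examples
#' aerodynamic_diameter(4.42, 1.05)  # 4.529 um
#' @export
aerodynamic_diameter <- function(d_g, rho_p) {
  if (any(!is.finite(d_g)) || any(d_g <= 0)) {
    stop("'d_g' must be positive", call. = FALSE)
  }
  if (!is.finite(rho_p) || rho_p <= 0) {
    stop("'rho_p' must be positive", call. = FALSE)
  }
  d_g * sqrt(rho_p / 1.0)
}

#' Stokes relaxation time of a particle
#'
#' `tau = rho_p * d_p^2 * C_u / (18 mu)`: the time constant of velocity
#' equilibration with the carrier gas, which also sets the tracker's time
#' step.
#'
#' @param d_p Geometric diameter (m), > 0. Vectorized.
#' @param rho_p Particle density (kg/m^3).
#' @param mu Gas dynamic viscosity (Pa s).
#' @param C_u Cunningham slip correction (default 1, spherical micron-scale
#'   particles).
#' @return Relaxation time (s).
#' @examples
#' relaxation_time(5e-6, 1050, 1.7894e-5)  # ~8.15e-5 s
#' @export
relaxation_time <- function(d_p, rho_p, mu, C_u = 1) {
  if (any(d_p <= 0) || rho_p <= 0 || mu <= 0 || C_u <= 0) {
    stop("all inputs to relaxation_time must be positive", call. = FALSE)
  }
  rho_p * d_p^2 * C_u / (18 * mu)
}
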