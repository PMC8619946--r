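#' Material and gas constants for particle-wall mechanics
#'
#' Bundles the elastic, adhesion and gas-phase constants entering the
#' capture-velocity sticking model and the rolling/sliding detachment
#' criteria. Defaults are for micron-scale lipid-matrix particles impacting a
#' polystyrene inhaler wall in air at ambient conditions.
#'
#' @param E_s Wall Young's modulus (Pa). Default 4.1e9 (polystyrene).
#' @param E_p Particle Young's modulus (Pa). Default 1e9.
#' @param v_s,v_p Poisson ratios of wall and particle. Defaults 0.35 / 0.40.
#' @param W_A Work of adhesion (J/m^2). Default 0.039.
#' @param k_s Static friction coefficient. Default 0.50.
#' @param f Near-wall drag correction factor. Default 1.70.
#' @param C_u Cunningham slip correction. Default 1 (spheres of a few um).
#' @param mu Air dynamic viscosity (Pa s). Default 1.7894e-5.
#' @param rho_air Air density (kg/m^3). Default 1.225 (1013.25 hPa, 15 C).
#' @param e_n Normal restitution coefficient applied to bouncing particles,
#'   in (0, 1]. Default 0.8 (bounce with reduced velocity).
#' @param lift_enabled Include the Saffman shear lift in detachment force
#'   budgets. Default `TRUE`.
#' @return A `material_params` list.
#' @export
material_params <- function(E_s = 4.1e9, E_p = 1e9,
                            v_s = 0.35, v_p = 0.40,
                            W_A = 0.039, k_s = 0.50, f = 1.70,
                            C_u = 1, mu = 1.7894e-5, rho_air = 1.225,
                            e_n = 0.8, lift_enabled = TRUE) {
  if (E_s <= 0 || E_p <= 0) stop("Young's moduli must be positive", call. = FALSE)
  if (v_s < 0 || v_s >= 0.5 || v_p < 0 || v_p >= 0.5) {
    stop("Poisson ratios must lie in [0, 0.5)", call. = FALSE)
  }
  if (W_A < 0) stop("'W_A' must be >= 0", call. = FALSE)
  if (k_s <= 0) stop("'k_s' must be positive", call. = FALSE)
  if (mu <= 0 || rho_air <= 0 || C_u <= 0 || f <= 0) {
    stop("gas-phase constants must be positive", call. = FALSE)
  }
  if (e_n <= 0 || e_n > 1) stop("'e_n' must lie in (0, 1]", call. = FALSE)
  structure(list(E_s = E_s, E_p = E_p, v_s = v_s, v_p = v_p,
                 W_A = W_A, k_s = k_s, f = f, C_u = C_u, mu = mu,
                 rho_air = rho_air, e_n = e_n,
                 lift_enabled = isTRUE(lift_enabled)),
            class = "material_params")
}

#' @export
print.material_params <- function(x, ...) {
  cat("Particle-wall material parameters:\n")
  cat(sprintf("  E_s %.3g Pa (v_s %.2f) | E_p %.3g Pa (v_p %.2f)\n",
              x$E_s, x$v_s, x$E_p, x$v_p))
  cat(sprintf("  W_A %.3g J/m^2, k_s %.2f, f %.2f, C_u %.2f, e_n %.2f\n",
              x$W_A, x$k_s, x$f, x$C_u, x$e_n))
  cat(sprintf("  air: mu %.4g Pa s, rho %.3f kg/m^3, Saffman lift %s\n",
              x$mu, x$rho_air, if (x$lift_enabled) "on" else "off"))
  invisible(x)
}

#' El Batch parameter of the capture-velocity model
#'
#' `E = 0.51 * [5 pi^2 (k1 + k2) / (4 rho_p^(3/2))]^(2/5)` with the elastic
#' compliances `k1 = (1 - v_s^2) / (pi E_s)` and `k2 = (1 - v_p^2) / (pi E_p)`.
#' Together with the particle diameter it fixes the capture velocity below
#' which an impacting particle sticks. Diameter-independent, so it is computed
#' once per material/density pairing.
#'
#' @param materials A [material_params()] object.
#' @param rho_p Particle density (kg/m^3).
#' @return The parameter E (SI composite units).
#' @export
el_batch_parameter <- function(materials, rho_p) {
  if (!is.finite(rho_p) || rho_p <= 0) stop("'rho_p' must be > 0", call. = FALSE)
  k1 <- (1 - materials$v_s^2) / (pi * materials$E_s)
  k2 <- (1 - materials$v_p^2) / (pi * materials$E_p)
  0.51 * (5 * pi^2 * (k1 + k2) / (4 * rho_p^1.5))^(2 / 5)
}

#' Capture velocity for particle-wall sticking
#'
#' `v_cr = (2 E / d_p)^(10/7)`: the normal impact speed below which adhesion
#' wins and the particle is captured by the wall. Strictly decreasing in both
#' particle diameter and density -- larger, heavier particles are harder to
#' capture.
#'
#' @param d_p Geometric particle diameter (m), > 0. Vectorized.
#' @param rho_p Particle density (kg/m^3).
#' @param materials A [material_params()] object.
#' @return Capture velocity (m/s).
#' @examples
#' m <- material_params()
#' capture_velocity(5e-6, 1050, m)   # ~1.6 m/s
#' capture_velocity(10e-6, 1050, m)  # ~0.60 m/s
#' @export
capture_velocity <- function(d_p, rho_p, materials) {
  if (any(!is.finite(d_p)) || any(d_p <= 0)) {
    stop("'d_p' must be positive", call. = FALSE)
  }
  E <- el_batch_parameter(materials, rho_p)
  (2 * E / d_p)^(10 / 7)
}

#' Resolve a wall impact into stick or bounce
#'
#' Decomposes the impact velocity against the wall normal: if the normal
#' impact speed `v_n` does not exceed the capture velocity the particle
#' sticks (velocity zeroed); otherwise it bounces with its normal component
#' reversed and scaled by the restitution coefficient and its tangential
#' component preserved. Equality is resolved as stick (adhesion is assumed to
#' win the marginal case).
#'
#' @param v_impact Length-3 particle velocity at impact (m/s).
#' @param wall_normal Unit length-3 inward wall normal.
#' @param v_cr Capture velocity for this particle (m/s).
#' @param e_n Normal restitution in (0, 1].
#' @return A list with `outcome` (`"stick"` or `"bounce"`), `v_n` (normal
#'   impact speed, m/s), `v_cr`, and `velocity_after` (length-3, m/s; zero for
#'   stick).
#' @export
impact_outcome <- function(v_impact, wall_normal, v_cr, e_n = 0.8) {
  stopifnot(length(v_impact) == 3L, length(wall_normal) == 3L)
  if (abs(sqrt(sum(wall_normal^2)) - 1) > 1e-8) {
    stop("'wall_normal' must be a unit vector", call. = FALSE)
  }
  # inward normal: an approaching particle has v . n < 0... the normal points
  # into the fluid, so the approach component is the negative projection
  vn_signed <- sum(v_impact * wall_normal)
  v_n <- abs(min(vn_signed, 0))
  if (v_n <= v_cr) {
    list(outcome = "stick", v_n = v_n, v_cr = v_cr,
         velocity_after = c(0, 0, 0))
  } else {
    v_tan <- v_impact - vn_signed * wall_normal
    list(outcome = "bounce", v_n = v_n, v_cr = v_cr,
         velocity_after = v_tan + e_n * v_n * wall_normal)
  }
}

#' JKR pull-off adhesion force
#'
#' `F_st = (3/4) pi W_A d_p`: the force needed to detach an adhering elastic
#' sphere in the JKR limit.
#'
#' @param d_p Particle diameter (m).
#' @param W_A Work of adhesion (J/m^2).
#' @return Adhesion force (N).
#' @examples
#' adhesion_force(5e-6, 0.039)  # ~4.59e-7 N
#' @export
adhesion_force <- function(d_p, W_A) {
  if (any(d_p <= 0) || W_A < 0) stop("invalid adhesion inputs", call. = FALSE)
  0.75 * pi * W_A * d_p
}

#' Near-wall drag force on a deposited particle
#'
#' Stokes drag with the near-wall correction factor and slip correction:
#' `F_D = 3 pi mu d_p u_rel f / C_u`.
#'
#' @param d_p Particle diameter (m).
#' @param u_rel Fluid speed relative to the (stationary) deposited particle,
#'   evaluated near the wall (m/s), >= 0.
#' @param materials A [material_params()] object (supplies `mu`, `f`, `C_u`).
#' @return Drag force (N).
#' @export
wall_drag_force <- function(d_p, u_rel, materials) {
  if (any(d_p <= 0)) stop("'d_p' must be positive", call. = FALSE)
  if (any(u_rel < 0)) stop("'u_rel' must be >= 0", call. = FALSE)
  3 * pi * materials$mu * d_p * u_rel * materials$f / materials$C_u
}

#' Saffman-type shear lift force on a deposited particle
#'
#' `F_L = 1.615 mu d_p^2 u_rel sqrt(rho_air * shear_rate / mu)`, evaluated
#' with the near-wall relative speed. Returns 0 when the lift closure is
#' disabled in the material parameters.
#'
#' @param d_p Particle diameter (m).
#' @param u_rel Near-wall relative fluid speed (m/s).
#' @param shear_rate Local wall-normal velocity gradient magnitude (1/s).
#' @param materials A [material_params()] object.
#' @return Lift force (N).
#' @export
wall_lift_force <- function(d_p, u_rel, shear_rate, materials) {
  if (any(shear_rate < 0)) stop("'shear_rate' must be >= 0", call. = FALSE)
  if (!materials$lift_enabled) return(0 * d_p)
  1.615 * materials$mu * d_p^2 * u_rel *
    sqrt(materials$rho_air * shear_rate / materials$mu)
}

#' JKR contact dimensions of an adhering sphere
#'
#' Zero-external-load JKR contact radius
#' `a = [9 pi W_A (d_p/2)^2 / (2 K)]^(1/3)` with composite stiffness
#' `K = (4/3) / [(1 - v_s^2)/E_s + (1 - v_p^2)/E_p]`, and normal flattening
#' `b = a^2 / d_p`. These set the moment arms of the rolling-detachment
#' criterion.
#'
#' @param d_p Particle diameter (m).
#' @param materials A [material_params()] object.
#' @return List with `a` (m, tangential contact dimension) and `b` (m,
#'   normal deformation); errors if the contact is degenerate (`b >= d_p/2`).
#' @export
contact_geometry <- function(d_p, materials) {
  if (any(d_p <= 0)) stop("'d_p' must be positive", call. = FALSE)
  K <- (4 / 3) / ((1 - materials$v_s^2) / materials$E_s +
                  (1 - materials$v_p^2) / materials$E_p)
  a <- (9 * pi * materials$W_A * (d_p / 2)^2 / (2 * K))^(1 / 3)
  b <- a^2 / d_p
  if (any(b >= d_p / 2)) {
    stop("degenerate contact: normal deformation b >= particle radius ",
         "(inputs outside the small-deformation regime)", call. = FALSE)
  }
  list(a = a, b = b)
}

#' Detachment mode of a deposited particle
#'
#' Applies the two detachment criteria to the force budget on a stuck
#' particle. The particle rolls off when the fluid moment beats the adhesion
#' moment, `F_D (d_p/2 - b) + F_L a >= F_st a`, and slides when drag beats
#' static friction, `F_D >= k_s F_st` (both boundaries inclusive). When both
#' criteria fire, rolling is reported: it is the more likely detachment
#' mechanism for spherical particles. Otherwise the particle remains stuck.
#'
#' @param F_D Drag force (N).
#' @param F_L Lift force (N).
#' @param F_st Adhesion force (N), > 0.
#' @param a,b JKR contact dimensions (m), see [contact_geometry()].
#' @param d_p Particle diameter (m).
#' @param k_s Static friction coefficient.
#' @return One of `"remains_stuck"`, `"rolls"`, `"slides"`.
#' @export
detachment_mode <- function(F_D, F_L, F_st, a, b, d_p, k_s) {
  if (F_st <= 0) stop("'F_st' must be positive", call. = FALSE)
  if (a <= 0 || b < 0 || b >= d_p / 2) {
    stop("invalid contact geometry: need a > 0 and 0 <= b < d_p/2", call. = FALSE)
  }
  rolls <- F_D * (d_p / 2 - b) + F_L * a >= F_st * a
  slides <- F_D >= k_s * F_st
  if (rolls) "rolls"
  else if (slides) "slides"
  else "remains_stuck"
}

#' Full detachment assessment from local flow conditions
#'
#' Convenience composition: computes the near-wall drag, lift, adhesion and
#' contact geometry for a deposited particle and applies [detachment_mode()].
#'
#' @param d_p Particle diameter (m).
#' @param u_rel Near-wall relative fluid speed (m/s).
#' @param shear_rate Local shear rate (1/s).
#' @param materials A [material_params()] object.
#' @return List with `mode` and the force budget (`F_D`, `F_L`, `F_st`, `a`,
#'   `b`).
#' @export
assess_detachment <- function(d_p, u_rel, shear_rate, materials) {
  F_D <- wall_drag_force(d_p, u_rel, materials)
  F_L <- wall_lift_force(d_p, u_rel, shear_rate, materials)
  F_st <- adhesion_force(d_p, materials$W_A)
  cg <- contact_geometry(d_p, materials)
  mode <- detachment_mode(F_D, F_L, F_st, cg$a, cg$b, d_p, materials$k_s)
  list(mode = mode, F_D = F_D, F_L = F_L, F_st = F_st, a = cg$a, b = cg$b)
}
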