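#' Advance a particle one time step through the flow
#'
#' Semi-implicit exponential relaxation of the particle velocity toward the
#' local fluid velocity with time constant `tau` (the Stokes relaxation
#' time), optionally with gravity. The update is the exact solution of the
#' linear drag equation over the step,
#' `v+ = u + g tau + (v - u - g tau) exp(-dt/tau)`, and the position is
#' advanced with the exact integral of that solution, so the scheme remains
#' stable and accurate for `dt >> tau`.
#'
#' @param state A particle state list with `position`, `velocity` (length-3,
#'   SI), `tau` (s) and `status = "in_flight"`.
#' @param field A `flow_field`.
#' @param dt Time step (s), > 0.
#' @param gravity Length-3 gravitational acceleration (m/s^2); default zero
#'   (gravity off).
#' @return The updated state (position and velocity advanced).
#' @export
step_particle <- function(state, field, dt,
                          gravity = c(0, 0, 0)) {
  if (!identical(state$status, "in_flight")) {
    stop("step_particle requires an in-flight particle (status = '",
         state$status, "')", call. = FALSE)
  }
  if (!is.finite(dt) || dt <= 0) stop("'dt' must be > 0", call. = FALSE)
  u <- field_velocity(field, state$position)
  v_inf <- u + gravity * state$tau       # terminal velocity in the local flow
  ex <- exp(-dt / state$tau)
  dv <- state$velocity - v_inf
  v_new <- v_inf + dv * ex
  # exact displacement integral of the exponential relaxation
  x_new <- state$position + v_inf * dt + dv * state$tau * (1 - ex)
  if (any(!is.finite(x_new))) {
    stop("divergent trajectory: non-finite position for particle ",
         state$id, call. = FALSE)
  }
  state$position <- x_new
  state$velocity <- v_new
  state
}

# first crossing of the segment p0 -> p1 with the domain boundary.
# Returns NULL (fully interior) or list(t, point, normal, type, region).
# Types: "side" (cylindrical wall), "floor", "grid_plane" (z = grid_z within
# the bore; porosity draw is the caller's job), "shelf" (grid-plane annulus),
# "outlet".
detect_wall_collision <- function(p0, p1, geometry) {
  d <- p1 - p0
  hits <- list()
  add <- function(t, type) {
    if (is.finite(t) && t > 1e-12 && t <= 1) {
      hits[[length(hits) + 1L]] <<- list(t = t, type = type)
    }
  }
  # axial planes
  if (d[3] < 0) add(-p0[3] / d[3], "floor")
  if (d[3] != 0) {
    add((geometry$grid_z - p0[3]) / d[3], "grid_plane")
    if (d[3] > 0) add((geometry$total_height - p0[3]) / d[3], "outlet")
  }
  # cylindrical walls: |p0_xy + t d_xy| = R, for each region's radius
  quad_hit <- function(R) {
    a <- d[1]^2 + d[2]^2
    b <- 2 * (p0[1] * d[1] + p0[2] * d[2])
    cc <- p0[1]^2 + p0[2]^2 - R^2
    if (a == 0) return(numeric(0))
    disc <- b^2 - 4 * a * cc
    if (disc < 0) return(numeric(0))
    sq <- sqrt(disc)
    ts <- c((-b - sq) / (2 * a), (-b + sq) / (2 * a))
    ts[ts > 1e-12 & ts <= 1]
  }
  for (t in quad_hit(geometry$chamber_radius)) {
    z <- p0[3] + t * d[3]
    if (z >= 0 && z < geometry$grid_z) add(t, "side")
  }
  for (t in quad_hit(geometry$mouthpiece_radius)) {
    z <- p0[3] + t * d[3]
    if (z >= geometry$grid_z && z <= geometry$total_height) add(t, "side")
  }
  if (!length(hits)) return(NULL)
  ord <- order(vapply(hits, `[[`, numeric(1), "t"))
  for (k in ord) {
    h <- hits[[k]]
    pt <- p0 + h$t * d
    r <- sqrt(pt[1]^2 + pt[2]^2)
    if (h$type == "floor") {
      pt[3] <- 0
      return(list(t = h$t, point = pt, normal = c(0, 0, 1),
                  type = "floor", region = "chamber"))
    }
    if (h$type == "outlet") {
      if (r <= geometry$mouthpiece_radius + 1e-12) {
        pt[3] <- geometry$total_height
        return(list(t = h$t, point = pt, normal = c(0, 0, -1),
                    type = "outlet", region = "mouthpiece"))
      }
      next
    }
    if (h$type == "grid_plane") {
      pt[3] <- geometry$grid_z
      nrm <- c(0, 0, -sign(d[3]))
      if (r <= geometry$mouthpiece_radius) {
        return(list(t = h$t, point = pt, normal = nrm,
                    type = "grid_plane", region = "grid"))
      }
      # annular shelf between mouthpiece bore and chamber wall: solid wall,
      # only reachable from below
      if (d[3] > 0) {
        return(list(t = h$t, point = pt, normal = c(0, 0, -1),
                    type = "shelf", region = "grid"))
      }
      next
    }
    # side wall
    if (r < 1e-15) next
    nrm <- c(-pt[1] / r, -pt[2] / r, 0)
    region <- if (pt[3] < geometry$grid_z) "chamber" else "mouthpiece"
    return(list(t = h$t, point = pt, normal = nrm,
                type = "side", region = region))
  }
  NULL
}

#' First wall crossing of a trajectory segment
#'
#' Tests the straight segment from `prev_position` to `new_position` against
#' the domain boundary and returns the first crossing: the cylindrical side
#' walls, the chamber floor, the grid plane (a perforated plane -- the caller
#' decides passage by a porosity draw), the solid annular shelf around the
#' mouthpiece bore, or the open outlet.
#'
#' @param prev_position,new_position Length-3 positions (m); `prev_position`
#'   must be inside the domain.
#' @param geometry An [build_geometry()] object.
#' @return `NULL` if the segment is fully interior, else a list with `t`
#'   (fraction along the segment), `point` (on the boundary), `normal`
#'   (inward unit normal), `type` and `region`.
#' @export
first_wall_crossing <- function(prev_position, new_position, geometry) {
  detect_wall_collision(prev_position, new_position, geometry)
}

default_sim_params <- function() {
  list(
    Q = 1e-3,                 # 60 L/min
    swirl_number = 2,
    dt_tau_fraction = 0.2,    # dt = tau / 5
    max_step_displacement = 2e-4,  # geometric CFL: 0.2 mm per step
    max_time = 0.5,           # s of simulated steady flow
    gravity_on = FALSE,
    weighting = "mass"
  )
}

#' Track a powder charge through the inhaler
#'
#' Injects `n` particles with diameters sampled from the formulation's
#' fitted Rosin-Rammler distribution, positions uniform over the injection
#' cross section and initial velocities equal to the local fluid velocity,
#' then integrates each trajectory until it is emitted through the outlet,
#' permanently stuck to a wall, or the simulated-time budget runs out.
#'
#' Wall impacts are resolved with the capture-velocity model: a particle
#' whose normal impact speed is below its capture velocity sticks; otherwise
#' it bounces with restitution `e_n`. A freshly stuck particle is assessed
#' once for rolling/sliding detachment using the steady local flow one
#' particle radius off the wall (in a steady field the force budget is
#' time-invariant, so one assessment decides permanence); a detached particle
#' re-enters the flow at the local fluid velocity.
#'
#' @param formulation A [formulation_record()].
#' @param geometry An [build_geometry()] object.
#' @param field A `flow_field`.
#' @param n Number of particles (default 100).
#' @param seed Integer seed (required; all stochastic elements -- size
#'   sampling, injection positions, grid-porosity draws -- derive from it).
#' @param materials A [material_params()] object.
#' @param max_time Simulated-time budget per particle (s).
#' @param dt_tau_fraction Time step as a fraction of the particle relaxation
#'   time.
#' @param max_step_displacement Geometric cap on per-step displacement (m).
#' @param gravity_on Include gravity (`-z`). Default `FALSE`.
#' @return A list with `fates` (one data.frame row per particle: diameters,
#'   mass, impact/stick/detach counts, final status/region, stick height,
#'   exit time), `impacts` (data.frame log of every wall impact with `v_n`,
#'   `v_cr` and outcome) and `summary` (mass-weighted
#'   [summarize_fates()] output).
#' @export
run_simulation <- function(formulation, geometry, field,
                           n = 100, seed,
                           materials = material_params(),
                           max_time = 0.5,
                           dt_tau_fraction = 0.2,
                           max_step_displacement = 2e-4,
                           gravity_on = FALSE) {
  stopifnot(inherits(formulation, "formulation_record"),
            inherits(geometry, "inhaler_geometry"),
            inherits(field, "flow_field"))
  if (missing(seed) || is.null(seed)) {
    stop("'seed' is required for a reproducible simulation run", call. = FALSE)
  }
  if (n < 1) stop("'n' must be >= 1", call. = FALSE)
  n <- as.integer(n)

  rr <- fit_rosin_rammler(formulation$dv10, formulation$dv50, formulation$dv90)
  d_um <- sample_diameters(rr, n, seed = seed)
  rho_p <- formulation$true_density * 1000   # g/cm^3 -> kg/m^3

  old_seed <- .Random.seed_exists()
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(as.integer(seed) + 1L)  # stream for positions + porosity draws

  inj_r_max <- region_radius(geometry, geometry$injection_z)
  u_inj <- sqrt(stats::runif(n)) * inj_r_max
  th_inj <- stats::runif(n, 0, 2 * pi)
  # pre-drawn porosity deck: the k-th grid crossing of particle i uses
  # grid_u[i, k], so pass/impact decisions do not depend on the step size
  grid_u <- matrix(stats::runif(n * 64L), nrow = n)
  gravity <- if (gravity_on) c(0, 0, -9.80665) else c(0, 0, 0)

  fates <- vector("list", n)
  impacts <- list()
  for (i in seq_len(n)) {
    d_p <- d_um[i] * 1e-6
    tau <- relaxation_time(d_p, rho_p, materials$mu, materials$C_u)
    v_cr <- capture_velocity(d_p, rho_p, materials)
    pos <- c(u_inj[i] * cos(th_inj[i]), u_inj[i] * sin(th_inj[i]),
             geometry$injection_z)
    st <- list(id = i, position = pos,
               velocity = field_velocity(field, pos),
               d_p = d_p, rho_p = rho_p,
               mass = rho_p * pi * d_p^3 / 6,
               tau = tau, status = "in_flight")
    t_now <- 0
    g_cross <- 0L
    n_impacts <- 0L; n_detach <- 0L; stuck_ever <- FALSE
    final_region <- NA_character_; z_stick <- NA_real_; exit_time <- NA_real_

    while (st$status == "in_flight" && t_now < max_time) {
      speed <- sqrt(sum(st$velocity^2))
      dt <- dt_tau_fraction * tau
      if (speed > 0) dt <- min(dt, max_step_displacement / speed)
      dt <- min(dt, max_time - t_now)
      prev <- st$position
      st <- step_particle(st, field, dt, gravity = gravity)
      t_now <- t_now + dt
      hit <- detect_wall_collision(prev, st$position, geometry)
      if (is.null(hit)) next

      if (hit$type == "outlet") {
        st$status <- "emitted"
        exit_time <- t_now - dt * (1 - hit$t)
        break
      }
      if (hit$type == "grid_plane") {
        g_cross <- g_cross + 1L
        u_draw <- grid_u[i, ((g_cross - 1L) %% ncol(grid_u)) + 1L]
        if (u_draw < geometry$grid_porosity) next  # passed through an open pore
      }
      # wall impact (side, floor, shelf, or closed grid pore)
      n_impacts <- n_impacts + 1L
      res <- impact_outcome(st$velocity, hit$normal, v_cr, materials$e_n)
      impacts[[length(impacts) + 1L]] <- data.frame(
        particle_id = i, d_g_um = d_um[i], region = hit$region,
        v_n = res$v_n, v_cr = v_cr, outcome = res$outcome)
      if (res$outcome == "bounce") {
        st$position <- hit$point + hit$normal * 1e-9
        st$velocity <- res$velocity_after
        next
      }
      # stuck: assess detachment once from the steady near-wall flow
      stuck_ever <- TRUE
      off <- hit$point + hit$normal * (d_p / 2)
      u_loc <- field_velocity(field, off)
      u_rel <- sqrt(sum((u_loc - sum(u_loc * hit$normal) * hit$normal)^2))
      G <- field_gradient(field, off)
      shear <- sqrt(sum((G %*% hit$normal)^2))
      det <- assess_detachment(d_p, u_rel, shear, materials)
      if (det$mode == "remains_stuck") {
        st$status <- "stuck"
        final_region <- hit$region
        z_stick <- hit$point[3]
      } else {
        n_detach <- n_detach + 1L
        st$position <- hit$point + hit$normal * max(d_p, 1e-8)
        st$velocity <- field_velocity(field, st$position)
      }
    }
    if (st$status == "in_flight") st$status <- "in_domain_at_timeout"

    fates[[i]] <- data.frame(
      particle_id = i,
      d_g_um = d_um[i],
      d_ae_um = aerodynamic_diameter(d_um[i], formulation$true_density),
      mass_kg = st$mass,
      n_impacts = n_impacts,
      stuck_ever = stuck_ever,
      n_detachments = n_detach,
      final_status = st$status,
      final_region = final_region,
      z_stick_m = z_stick,
      exit_time_s = exit_time,
      stringsAsFactors = FALSE)
  }
  fates <- do.call(rbind, fates)
  impacts <- if (length(impacts)) do.call(rbind, impacts) else
    data.frame(particle_id = integer(), d_g_um = numeric(),
               region = character(), v_n = numeric(), v_cr = numeric(),
               outcome = character(), stringsAsFactors = FALSE)
  list(fates = fates, impacts = impacts,
       summary = summarize_fates(fates, weighting = "mass"))
}

#' Summarize particle fates into device-level fractions
#'
#' Computes the emitted fraction (EF), impact/stick fractions, the
#' detached-to-permanently-stuck ratio, and the regional split of deposited
#' material, under number or mass weighting of the particle records.
#' `EF + permanently stuck + in-domain-at-timeout = 100` exactly per
#' weighting.
#'
#' @param fates Fate data.frame from [run_simulation()].
#' @param weighting `"mass"` (default) or `"number"`.
#' @return A `sim_summary` list with percentages `ef`, `fraction_impacted`,
#'   `fraction_stuck_ever`, `fraction_permanently_stuck`,
#'   `fraction_in_domain`, `detached_to_stuck_ratio`, and `regional` (percent
#'   of deposited weight in chamber/grid/mouthpiece).
#' @export
summarize_fates <- function(fates, weighting = c("mass", "number")) {
  weighting <- match.arg(weighting)
  if (is.null(fates) || nrow(fates) == 0L) {
    stop("empty fate table", call. = FALSE)
  }
  w <- if (weighting == "mass") fates$mass_kg else rep(1, nrow(fates))
  W <- sum(w)
  pct <- function(mask) 100 * sum(w[mask]) / W
  stuck <- fates$final_status == "stuck"
  out <- list(
    weighting = weighting,
    n = nrow(fates),
    ef = pct(fates$final_status == "emitted"),
    fraction_impacted = pct(fates$n_impacts > 0),
    fraction_stuck_ever = pct(fates$stuck_ever),
    fraction_permanently_stuck = pct(stuck),
    fraction_in_domain = pct(fates$final_status == "in_domain_at_timeout"),
    detached_to_stuck_ratio = {
      n_ever <- sum(fates$stuck_ever)
      n_perm <- sum(stuck)
      if (n_perm > 0) (n_ever - n_perm) / n_perm else NA_real_
    },
    regional = {
      if (any(stuck)) {
        dep <- w[stuck]
        reg <- fates$final_region[stuck]
        sapply(c("chamber", "grid", "mouthpiece"),
               function(r) 100 * sum(dep[reg == r]) / sum(dep))
      } else {
        c(chamber = NA_real_, grid = NA_real_, mouthpiece = NA_real_)
      }
    }
  )
  class(out) <- "sim_summary"
  out
}

#' @export
print.sim_summary <- function(x, ...) {
  cat(sprintf("Simulation summary (%s-weighted, n = %d):\n", x$weighting, x$n))
  cat(sprintf("  emitted fraction (EF):     %6.2f %%\n", x$ef))
  cat(sprintf("  impacted a wall:           %6.2f %%\n", x$fraction_impacted))
  cat(sprintf("  stuck at some point:       %6.2f %%\n", x$fraction_stuck_ever))
  cat(sprintf("  permanently stuck:         %6.2f %%\n", x$fraction_permanently_stuck))
  cat(sprintf("  in domain at timeout:      %6.2f %%\n", x$fraction_in_domain))
  if (is.finite(x$detached_to_stuck_ratio)) {
    cat(sprintf("  detached : stuck ratio:    %6.2f\n", x$detached_to_stuck_ratio))
  }
  if (all(is.finite(x$regional))) {
    cat(sprintf("  deposition split:          chamber %.1f %% | grid %.1f %% | mouthpiece %.1f %%\n",
                x$regional[["chamber"]], x$regional[["grid"]],
                x$regional[["mouthpiece"]]))
  }
  invisible(x)
}
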