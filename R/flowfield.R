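#' Steady velocity-field providers
#'
#' A `flow_field` is a pluggable steady velocity field: any object able to
#' answer `field_velocity(field, position)` with a 3-vector in m/s. The
#' contract deliberately abstracts over where the field came from -- an
#' analytic construction, or an externally computed CFD solution sampled on a
#' structured lattice -- so the particle tracker is agnostic to the flow
#' solver. Fields are steady: repeated queries at the same position return
#' identical values.
#'
#' @name flow_field
NULL

new_flow_field <- function(velocity, gradient = NULL, Q = NA_real_,
                           kind = "custom", meta = list()) {
  structure(list(velocity = velocity, gradient = gradient, Q = Q,
                 kind = kind, meta = meta),
            class = "flow_field")
}

#' @export
print.flow_field <- function(x, ...) {
  cat(sprintf("Steady flow field (%s)", x$kind))
  if (is.finite(x$Q)) cat(sprintf(", Q = %.4g m^3/s (%.1f L/min)", x$Q, x$Q * 6e4))
  cat("\n")
  invisible(x)
}

#' Query fluid velocity at a point
#'
#' @param field A `flow_field`.
#' @param position Numeric length-3 `(x, y, z)` in metres.
#' @return Numeric length-3 velocity (m/s).
#' @export
field_velocity <- function(field, position) {
  stopifnot(inherits(field, "flow_field"), length(position) == 3L)
  field$velocity(position)
}

#' Query the velocity-gradient tensor at a point
#'
#' Returns the 3x3 tensor `G[i, j] = d u_i / d x_j` (1/s). Fields that carry
#' an exact gradient (e.g. the uniform field's zero tensor) return it; others
#' fall back to central finite differences with step `h`.
#'
#' @inheritParams field_velocity
#' @param h Finite-difference step (m). Default `1e-7`.
#' @return 3x3 numeric matrix (1/s).
#' @export
field_gradient <- function(field, position, h = 1e-7) {
  stopifnot(inherits(field, "flow_field"), length(position) == 3L)
  if (!is.null(field$gradient)) return(field$gradient(position))
  G <- matrix(0, 3, 3)
  for (j in 1:3) {
    e <- c(0, 0, 0); e[j] <- h
    G[, j] <- (field$velocity(position + e) - field$velocity(position - e)) / (2 * h)
  }
  G
}

#' Uniform flow field
#'
#' Constant velocity everywhere; zero gradient. Primarily a fixture for
#' verifying tracker behaviour against closed-form relaxation solutions.
#'
#' @param speed Speed in m/s (>= 0; 0 gives quiescent air).
#' @param direction Length-3 direction vector, any nonzero magnitude.
#' @return A `flow_field`.
#' @examples
#' f <- uniform_field(1, c(0, 0, 1))
#' field_velocity(f, c(0, 0, 0.01))  # (0, 0, 1)
#' @export
uniform_field <- function(speed, direction = c(0, 0, 1)) {
  stopifnot(is.numeric(speed), length(speed) == 1L, speed >= 0)
  nrm <- sqrt(sum(direction^2))
  if (!is.finite(nrm) || nrm <= 0) {
    stop("'direction' must have positive magnitude", call. = FALSE)
  }
  u <- speed * direction / nrm
  new_flow_field(
    velocity = function(position) u,
    gradient = function(position) matrix(0, 3, 3),
    kind = "uniform"
  )
}

# C2 smoothstep used to taper the effective flow radius toward the grid
smoothstep <- function(t) {
  t <- pmin(pmax(t, 0), 1)
  t * t * (3 - 2 * t)
}

#' Analytic swirling stand-in for the inhaler flow at a fixed flow rate
#'
#' Constructs an incompressible axisymmetric velocity field from a stream
#' function, calibrated so the axial volumetric flux through every cross
#' section equals `Q` exactly: plug flow in the chamber funnelling smoothly
#' into the mouthpiece bore over the upper part of the chamber, a Poiseuille
#' profile in the mouthpiece, and a solid-body-rotation swirl component in the
#' chamber that decays linearly to zero at the grid plane. This reproduces the
#' qualitative structure of the device's flow -- swirl in the chamber carrying
#' particles toward the outlet, peak speeds in the mouthpiece -- without
#' solving the Navier-Stokes equations; it is a stand-in, not a CFD solution.
#'
#' The no-penetration condition holds on the cylindrical walls by
#' construction: the radial component vanishes where the effective flow
#' radius is constant, and the azimuthal/axial components are wall-parallel.
#'
#' @param geometry An [build_geometry()] object.
#' @param Q Volumetric flow rate (m^3/s). 60 L/min = `1e-3` m^3/s.
#' @param swirl_number Ratio of the chamber's wall tangential speed to its
#'   mean axial speed at the floor. 0 gives a purely axial field. Default 2.
#' @param taper_start Fraction of `grid_z` at which the chamber flow begins
#'   contracting into the mouthpiece bore. Default 0.6.
#' @return A `flow_field` with `Q` metadata.
#' @examples
#' geo <- build_geometry()
#' f <- analytic_swirl_field(geo, Q = 1e-3)
#' # mean outlet speed = Q / (pi * r^2) = 12.73 m/s for the 10 mm outlet
#' @export
analytic_swirl_field <- function(geometry, Q, swirl_number = 2,
                                 taper_start = 0.6) {
  stopifnot(inherits(geometry, "inhaler_geometry"))
  if (!is.finite(Q) || Q <= 0) stop("'Q' must be > 0", call. = FALSE)
  if (taper_start <= 0 || taper_start >= 1) {
    stop("'taper_start' must lie in (0, 1)", call. = FALSE)
  }
  Rc <- geometry$chamber_radius
  Rm <- geometry$mouthpiece_radius
  zg <- geometry$grid_z
  z0 <- taper_start * zg
  U_floor <- Q / (pi * Rc^2)          # mean axial speed over the full chamber bore
  omega_wall <- swirl_number * U_floor # tangential speed at the chamber wall, z = 0

  # effective flow radius: Rc below z0, smoothstep down to Rm at the grid
  r_eff <- function(z) {
    if (z <= z0) return(Rc)
    if (z >= zg) return(Rm)
    Rc + (Rm - Rc) * smoothstep((z - z0) / (zg - z0))
  }
  dr_eff <- function(z) {
    if (z <= z0 || z >= zg) return(0)
    t <- (z - z0) / (zg - z0)
    (Rm - Rc) * 6 * t * (1 - t) / (zg - z0)
  }

  velocity <- function(position) {
    x <- position[1]; y <- position[2]; z <- position[3]
    r <- sqrt(x^2 + y^2)
    if (z > zg) {
      # mouthpiece: Poiseuille, flux Q
      rr <- min(r / Rm, 1)
      uz <- 2 * Q / (pi * Rm^2) * (1 - rr^2)
      ur <- 0
      ut <- 0
    } else {
      Re <- r_eff(z)
      if (r >= Re) {
        uz <- 0; ur <- 0
      } else {
        # plug flow through the contracting effective bore (stream function
        # psi = (Q/2pi) (r/Re)^2): u_z = Q/(pi Re^2), u_r = r u_z Re'/Re
        uz <- Q / (pi * Re^2)
        ur <- r * uz * dr_eff(z) / Re
      }
      # solid-body swirl decaying linearly to zero at the grid plane
      ut <- omega_wall * (r / Rc) * max(0, 1 - z / zg)
    }
    if (r < 1e-15) return(c(0, 0, uz))
    ex <- x / r; ey <- y / r
    c(ur * ex - ut * ey, ur * ey + ut * ex, uz)
  }

  new_flow_field(velocity = velocity, Q = Q, kind = "analytic-swirl",
                 meta = list(swirl_number = swirl_number,
                             taper_start = taper_start))
}

#' Axial volumetric flux through a cross section (numerical quadrature)
#'
#' Integrates the axial velocity component over the disk of radius
#' `r_max` at height `z`, by midpoint quadrature in radius and angle.
#' Mainly a diagnostic for verifying flux conservation of field providers.
#'
#' @param field A `flow_field`.
#' @param z Axial position (m).
#' @param r_max Disk radius (m).
#' @param nr,ntheta Number of radial / azimuthal quadrature nodes.
#' @return Flux in m^3/s.
#' @export
axial_flux <- function(field, z, r_max, nr = 200, ntheta = 16) {
  rs <- (seq_len(nr) - 0.5) / nr * r_max
  ths <- (seq_len(ntheta) - 0.5) / ntheta * 2 * pi
  dr <- r_max / nr
  dth <- 2 * pi / ntheta
  total <- 0
  for (r in rs) {
    for (th in ths) {
      u <- field$velocity(c(r * cos(th), r * sin(th), z))
      total <- total + u[3] * r * dr * dth
    }
  }
  total
}

#' Load a steady velocity field from a structured-lattice CSV
#'
#' Reads a plain CSV with header `x,y,z,u,v,w` (SI units) whose points form a
#' full structured lattice (the Cartesian product of the unique x, y and z
#' coordinates). Queries interpolate with the chosen scheme; queries outside
#' the lattice hull raise an out-of-domain error.
#'
#' @param path CSV file path.
#' @param interpolation `"trilinear"` (default) or `"nearest"`.
#' @return A `flow_field`.
#' @export
load_gridded_field <- function(path, interpolation = c("trilinear", "nearest")) {
  interpolation <- match.arg(interpolation)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("x", "y", "z", "u", "v", "w")
  if (!all(need %in% names(df))) {
    stop("gridded-field file '", path, "' must have columns ",
         paste(need, collapse = ","), "; found: ",
         paste(names(df), collapse = ","), call. = FALSE)
  }
  for (cn in need) {
    bad <- which(!is.finite(suppressWarnings(as.numeric(df[[cn]]))))
    if (length(bad)) {
      stop("gridded-field file '", path, "': non-numeric value in column '",
           cn, "' at data line ", bad[1], call. = FALSE)
    }
    df[[cn]] <- as.numeric(df[[cn]])
  }
  xs <- sort(unique(df$x)); ys <- sort(unique(df$y)); zs <- sort(unique(df$z))
  nx <- length(xs); ny <- length(ys); nz <- length(zs)
  if (nrow(df) != nx * ny * nz) {
    stop("gridded-field file '", path, "': ", nrow(df),
         " points do not form a full ", nx, "x", ny, "x", nz,
         " structured lattice", call. = FALSE)
  }
  ix <- match(df$x, xs); iy <- match(df$y, ys); iz <- match(df$z, zs)
  key <- (ix - 1L) + nx * ((iy - 1L) + ny * (iz - 1L))
  if (anyDuplicated(key)) {
    stop("gridded-field file '", path, "': duplicate lattice point at data line ",
         which(duplicated(key))[1], call. = FALSE)
  }
  U <- V <- W <- array(NA_real_, c(nx, ny, nz))
  idx <- cbind(ix, iy, iz)
  U[idx] <- df$u; V[idx] <- df$v; W[idx] <- df$w

  locate <- function(coords, q, axis) {
    n <- length(coords)
    if (q < coords[1] - 1e-12 || q > coords[n] + 1e-12) {
      stop("query ", axis, " = ", q, " is outside the lattice hull [",
           coords[1], ", ", coords[n], "]", call. = FALSE)
    }
    if (n == 1L) return(list(i = 1L, t = 0))
    i <- findInterval(q, coords, all.inside = TRUE)
    list(i = i, t = (q - coords[i]) / (coords[i + 1] - coords[i]))
  }

  velocity <- function(position) {
    lx <- locate(xs, position[1], "x")
    ly <- locate(ys, position[2], "y")
    lz <- locate(zs, position[3], "z")
    if (interpolation == "nearest") {
      i <- lx$i + (length(xs) > 1L && lx$t > 0.5)
      j <- ly$i + (length(ys) > 1L && ly$t > 0.5)
      k <- lz$i + (length(zs) > 1L && lz$t > 0.5)
      return(c(U[i, j, k], V[i, j, k], W[i, j, k]))
    }
    interp1 <- function(A) {
      acc <- 0
      for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
        wx <- if (length(xs) == 1L) (dx == 0) else abs(1 - dx - lx$t)
        wy <- if (length(ys) == 1L) (dy == 0) else abs(1 - dy - ly$t)
        wz <- if (length(zs) == 1L) (dz == 0) else abs(1 - dz - lz$t)
        w <- wx * wy * wz
        if (w > 0) {
          acc <- acc + w * A[min(lx$i + dx, length(xs)),
                             min(ly$i + dy, length(ys)),
                             min(lz$i + dz, length(zs))]
        }
      }
      acc
    }
    c(interp1(U), interp1(V), interp1(W))
  }

  new_flow_field(velocity = velocity, kind = paste0("gridded-", interpolation),
                 meta = list(path = path, dims = c(nx, ny, nz)))
}
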