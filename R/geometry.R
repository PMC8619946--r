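#' Parameterized capsule-inhaler geometry
#'
#' Builds a simplified stand-in for the internal geometry of an RS01-type
#' capsule dry powder inhaler: two coaxial cylinders (powder-storage chamber
#' and mouthpiece) joined at a thin perforated grid plane. The true internal
#' contours of the device (capsule seat, swirl chamber, grid lattice) are not
#' published; this model preserves the three deposition regions a practitioner
#' cares about -- chamber, grid and mouthpiece -- with the device's bounding
#' dimensions as defaults.
#'
#' All arguments are in millimetres (the unit in which devices are measured);
#' the returned object stores SI metres internally.
#'
#' @param chamber_radius_mm Radius of the powder-storage chamber (mm). Default
#'   14.0, half the device's 28.0 mm maximal width.
#' @param grid_z_mm Axial position of the grid plane above the chamber floor
#'   (mm). Default 25.0.
#' @param total_height_mm Total internal height (mm). Default 47.5.
#' @param outlet_diameter_mm Mouthpiece/outlet diameter (mm). Default 10.0.
#' @param mouthpiece_radius_mm Mouthpiece internal radius (mm). Defaults to
#'   `outlet_diameter_mm / 2`.
#' @param inlet_width_mm,inlet_height_mm Tangential air-inlet slot dimensions
#'   (mm). Defaults 1.5 x 6.0. Metadata only: the analytic flow field imposes
#'   the volumetric flow directly.
#' @param injection_z_mm Axial position of the virtual particle release
#'   surface (mm above the chamber floor). Default 12.0.
#' @param grid_porosity Open-area fraction of the grid plane in `[0, 1]`. A
#'   particle crossing the grid within the mouthpiece radius impacts the grid
#'   with probability `1 - grid_porosity`. Default 0.6.
#'
#' @return An object of class `inhaler_geometry`: a list with fields
#'   `chamber_radius`, `grid_z`, `mouthpiece_radius`, `mouthpiece_length`,
#'   `total_height`, `outlet_diameter`, `inlet_width`, `inlet_height`,
#'   `injection_z` (all metres) and `grid_porosity`.
#' @examples
#' geo <- build_geometry()
#' geo$total_height    # 0.0475 m
#' region_of(geo, c(0, 0, 0.001))
#' @export
build_geometry <- function(chamber_radius_mm = 14.0,
                           grid_z_mm = 25.0,
                           total_height_mm = 47.5,
                           outlet_diameter_mm = 10.0,
                           mouthpiece_radius_mm = outlet_diameter_mm / 2,
                           inlet_width_mm = 1.5,
                           inlet_height_mm = 6.0,
                           injection_z_mm = 12.0,
                           grid_porosity = 0.6) {
  dims <- c(chamber_radius_mm = chamber_radius_mm,
            grid_z_mm = grid_z_mm,
            total_height_mm = total_height_mm,
            outlet_diameter_mm = outlet_diameter_mm,
            mouthpiece_radius_mm = mouthpiece_radius_mm,
            inlet_width_mm = inlet_width_mm,
            inlet_height_mm = inlet_height_mm,
            injection_z_mm = injection_z_mm)
  for (nm in names(dims)) {
    if (!is.finite(dims[[nm]]) || dims[[nm]] <= 0) {
      stop("geometry dimension '", nm, "' must be a positive finite number, got ",
           dims[[nm]], call. = FALSE)
    }
  }
  if (grid_z_mm >= total_height_mm) {
    stop("'grid_z_mm' (", grid_z_mm, ") must be strictly below 'total_height_mm' (",
         total_height_mm, "): the grid plane must partition the device into ",
         "a chamber below and a mouthpiece above", call. = FALSE)
  }
  if (mouthpiece_radius_mm > chamber_radius_mm) {
    stop("'mouthpiece_radius_mm' must not exceed 'chamber_radius_mm'",
         call. = FALSE)
  }
  if (injection_z_mm >= grid_z_mm) {
    stop("'injection_z_mm' (", injection_z_mm,
         ") must lie below the grid plane at 'grid_z_mm' (", grid_z_mm, ")",
         call. = FALSE)
  }
  if (!is.finite(grid_porosity) || grid_porosity < 0 || grid_porosity > 1) {
    stop("'grid_porosity' must lie in [0, 1]", call. = FALSE)
  }
  mm <- 1e-3
  geo <- list(
    chamber_radius = chamber_radius_mm * mm,
    grid_z = grid_z_mm * mm,
    total_height = total_height_mm * mm,
    outlet_diameter = outlet_diameter_mm * mm,
    mouthpiece_radius = mouthpiece_radius_mm * mm,
    mouthpiece_length = (total_height_mm - grid_z_mm) * mm,
    inlet_width = inlet_width_mm * mm,
    inlet_height = inlet_height_mm * mm,
    injection_z = injection_z_mm * mm,
    grid_porosity = grid_porosity
  )
  class(geo) <- "inhaler_geometry"
  geo
}

#' @export
print.inhaler_geometry <- function(x, ...) {
  cat("Capsule-inhaler geometry (two coaxial cylinders + grid plane)\n")
  cat(sprintf("  chamber:    radius %.2f mm, z in [0, %.2f) mm\n",
              x$chamber_radius * 1e3, x$grid_z * 1e3))
  cat(sprintf("  grid plane: z = %.2f mm, porosity %.2f\n",
              x$grid_z * 1e3, x$grid_porosity))
  cat(sprintf("  mouthpiece: radius %.2f mm, z in (%.2f, %.2f] mm\n",
              x$mouthpiece_radius * 1e3, x$grid_z * 1e3, x$total_height * 1e3))
  cat(sprintf("  injection surface: z = %.2f mm\n", x$injection_z * 1e3))
  invisible(x)
}

# radius allowed at axial position z (device is open only at the outlet)
region_radius <- function(geometry, z) {
  ifelse(z < geometry$grid_z, geometry$chamber_radius, geometry$mouthpiece_radius)
}

#' Test whether a point lies inside the inhaler internal volume
#'
#' @param geometry An [build_geometry()] object.
#' @param position Numeric length-3 `(x, y, z)` in metres, z = 0 at the
#'   chamber floor.
#' @return Logical scalar.
#' @export
in_domain <- function(geometry, position) {
  stopifnot(length(position) == 3L, is.numeric(position))
  z <- position[3]
  if (z < 0 || z > geometry$total_height) return(FALSE)
  r <- sqrt(position[1]^2 + position[2]^2)
  r <= region_radius(geometry, z) + 1e-12
}

#' Classify a point into a deposition region
#'
#' Region boundaries follow a lower-edge-inclusive convention so every axial
#' coordinate maps to exactly one region: chamber for `z < grid_z`, grid at
#' `z == grid_z`, mouthpiece for `z > grid_z` (up to and including the
#' outlet plane).
#'
#' @inheritParams in_domain
#' @return One of `"chamber"`, `"grid"`, `"mouthpiece"`.
#' @examples
#' geo <- build_geometry()
#' region_of(geo, c(0, 0, 0))          # "chamber"
#' region_of(geo, c(0, 0, geo$grid_z)) # "grid"
#' @export
region_of <- function(geometry, position) {
  if (!in_domain(geometry, position)) {
    stop("position (", paste(signif(position, 6), collapse = ", "),
         ") is outside the inhaler domain", call. = FALSE)
  }
  z <- position[3]
  if (z < geometry$grid_z) "chamber"
  else if (z == geometry$grid_z) "grid"
  else "mouthpiece"
}

#' Distance and inward normal to the nearest lateral wall
#'
#' Returns the distance from a point to the cylindrical side wall of the
#' region containing it, with the inward (into-the-fluid) unit normal. The
#' chamber floor, grid shelf and outlet plane are boundary events handled by
#' the trajectory crossing test, not lateral walls.
#'
#' @inheritParams in_domain
#' @return A list with `distance` (m, >= 0), `normal` (unit length-3 vector
#'   pointing into the fluid) and `region`.
#' @export
wall_query <- function(geometry, position) {
  region <- region_of(geometry, position)
  r <- sqrt(position[1]^2 + position[2]^2)
  wall_r <- region_radius(geometry, position[3])
  if (r < 1e-15) {
    # on the axis every radial direction is equidistant; pick +x inward = -x̂
    normal <- c(-1, 0, 0)
  } else {
    normal <- c(-position[1] / r, -position[2] / r, 0)
  }
  list(distance = max(wall_r - r, 0), normal = normal, region = region)
}
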