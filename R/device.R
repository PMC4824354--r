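# Domain types for the disk: fluids, valves, cells, gradient sections,
# lanes and spin protocols. Interface units are mm / g/mL / mPa.s / degrees;
# objects keep the entered interface values verbatim and convert to SI only
# inside the physics, so values written and read back are bit-identical.

#' Fluid sample properties
#'
#' Describes the liquid phase that wets the capillary valves (typically
#' whole blood diluted with PBS). The surface tension and advancing contact
#' angle set the Young-Laplace pinning pressure; the density drives the
#' centrifugal column pressure; the viscosity is used only when a lane
#' section contains the sample itself as its medium.
#'
#' The defaults (0.058 N/m, 110 degrees on acrylic, 1.060 g/mL, 1.8 mPa.s)
#' are literature-typical values for diluted whole blood and are intended to
#' be overridden from a device configuration when measured values exist.
#'
#' @param surface_tension surface tension in N/m (> 0).
#' @param contact_angle advancing contact angle on the channel material, in
#'   degrees, strictly between 0 and 180. Angles of 90 or less cannot pin a
#'   meniscus (the valve is degenerate).
#' @param density liquid density in g/mL (> 0).
#' @param viscosity liquid viscosity in mPa.s (> 0).
#' @return an object of class `fluid_sample`.
#' @examples
#' fluid_sample()  # diluted-blood defaults
#' @export
fluid_sample <- function(surface_tension = 0.058, contact_angle = 110,
                         density = 1.060, viscosity = 1.8) {
  stopifnot(length(surface_tension) == 1L, length(contact_angle) == 1L,
            length(density) == 1L, length(viscosity) == 1L)
  if (surface_tension <= 0) stop("surface_tension must be > 0", call. = FALSE)
  if (contact_angle <= 0 || contact_angle >= 180)
    stop("contact_angle must lie strictly between 0 and 180 degrees",
         call. = FALSE)
  if (density <= 0) stop("density must be > 0", call. = FALSE)
  if (viscosity <= 0) stop("viscosity must be > 0", call. = FALSE)
  structure(list(surface_tension = surface_tension,
                 contact_angle = contact_angle,
                 density = density,
                 viscosity = viscosity),
            class = "fluid_sample")
}

#' Capillary burst-valve geometry
#'
#' A rectangular channel constriction whose abrupt expansion pins the
#' advancing meniscus. Height and width enter the Young-Laplace threshold
#' as 1/h + 1/w; the radial position records where on the lane the valve
#' sits.
#'
#' @param height channel height in mm (> 0).
#' @param width channel width in mm (> 0).
#' @param radial_position distance of the valve from the rotation axis,
#'   mm (>= 0).
#' @return an object of class `valve_geometry`.
#' @export
valve_geometry <- function(height, width, radial_position = 0) {
  stopifnot(length(height) == 1L, length(width) == 1L,
            length(radial_position) == 1L)
  if (height <= 0 || width <= 0)
    stop("valve height and width must be > 0", call. = FALSE)
  if (radial_position < 0)
    stop("radial_position must be >= 0", call. = FALSE)
  structure(list(height = height, width = width,
                 radial_position = radial_position),
            class = "valve_geometry")
}

#' A sedimenting cell species
#'
#' A blood cell class modelled as a Stokes sphere: a density, an effective
#' radius, and an agglutination factor that multiplies the radius to model
#' aggregates (red-cell rouleaux sediment much faster than single cells
#' because settling time scales as 1/R^2).
#'
#' @param name species label.
#' @param density cell density in g/mL (> 0).
#' @param radius effective single-particle radius in micrometres (> 0).
#' @param agglutination_factor dimensionless multiplier on the radius
#'   (>= 1); 1 means single cells.
#' @return an object of class `cell_species`.
#' @examples
#' cell_species("RBC", density = 1.098, radius = 2.63, agglutination_factor = 3)
#' @export
cell_species <- function(name, density, radius, agglutination_factor = 1) {
  stopifnot(is.character(name), length(name) == 1L)
  if (density <= 0) stop("density must be > 0", call. = FALSE)
  if (radius <= 0) stop("radius must be > 0", call. = FALSE)
  if (agglutination_factor < 1)
    stop("agglutination_factor must be >= 1", call. = FALSE)
  structure(list(name = name, density = density, radius = radius,
                 agglutination_factor = agglutination_factor),
            class = "cell_species")
}

# Effective Stokes radius in metres (aggregation included).
effective_radius_m <- function(cell) {
  um_to_m(cell$radius * cell$agglutination_factor)
}

#' One density-gradient compartment of a lane
#'
#' A radial interval holding a medium of fixed density and viscosity. A
#' cell sediments through the section only if its density exceeds the
#' medium density; otherwise it is held at the section's proximal
#' interface (isopycnic trapping).
#'
#' @param label single-letter section label (sections are lettered A
#'   distal-most to F proximal-most on the reference lane).
#' @param medium_density medium density in g/mL (> 0).
#' @param medium_viscosity medium viscosity in mPa.s (> 0).
#' @param r_proximal,r_distal radial extent in mm from the rotation axis;
#'   the section is the half-open interval `[r_proximal, r_distal)` and
#'   `r_distal > r_proximal` is required.
#' @param volume nominal fill volume in microlitres; informational only,
#'   never used in the physics.
#' @return an object of class `medium_section`.
#' @export
medium_section <- function(label, medium_density, medium_viscosity,
                           r_proximal, r_distal, volume = NA_real_) {
  stopifnot(is.character(label), length(label) == 1L)
  if (medium_density <= 0) stop("medium_density must be > 0", call. = FALSE)
  if (medium_viscosity <= 0)
    stop("medium_viscosity must be > 0", call. = FALSE)
  if (!(r_distal > r_proximal))
    stop("r_distal must exceed r_proximal (section '", label, "')",
         call. = FALSE)
  if (r_proximal < 0) stop("r_proximal must be >= 0", call. = FALSE)
  structure(list(label = label,
                 medium_density = medium_density,
                 medium_viscosity = medium_viscosity,
                 r_proximal = r_proximal,
                 r_distal = r_distal,
                 volume = volume),
            class = "medium_section")
}

#' One radial separation lane of the disk
#'
#' An ordered stack of gradient sections, proximal (sample) to distal, with
#' one capillary valve at each internal section boundary. Sections must
#' tile the radial interval with no gaps or overlaps, and must fit inside
#' the disk radius. Valve footprints are contained within section
#' boundaries and add no radial length.
#'
#' @param sections list of [medium_section()] ordered proximal to distal.
#' @param valves list of [valve_geometry()], one per internal boundary
#'   (`length(sections) - 1`).
#' @param disk_radius outer disk radius in mm.
#' @return an object of class `lane_design`.
#' @seealso [reference_lane()] for the built-in reference geometry.
#' @export
lane_design <- function(sections, valves, disk_radius) {
  stopifnot(is.list(sections), is.list(valves), length(disk_radius) == 1L)
  if (length(sections) < 1L) stop("at least one section required", call. = FALSE)
  lapply(sections, function(s) {
    if (!inherits(s, "medium_section"))
      stop("sections must be medium_section objects", call. = FALSE)
  })
  lapply(valves, function(v) {
    if (!inherits(v, "valve_geometry"))
      stop("valves must be valve_geometry objects", call. = FALSE)
  })
  if (length(valves) != length(sections) - 1L)
    stop("need exactly one valve per internal boundary: ",
         length(sections) - 1L, " expected, ", length(valves), " given",
         call. = FALSE)
  rp <- vapply(sections, `[[`, numeric(1), "r_proximal")
  rd <- vapply(sections, `[[`, numeric(1), "r_distal")
  lab <- vapply(sections, `[[`, character(1), "label")
  if (length(sections) > 1L) {
    gap <- abs(rd[-length(rd)] - rp[-1L])
    bad <- which(gap > 1e-9)
    if (length(bad))
      stop("sections '", lab[bad[1L]], "' and '", lab[bad[1L] + 1L],
           "' are not radially contiguous (gap/overlap of ",
           signif(gap[bad[1L]], 3), " mm)", call. = FALSE)
  }
  if (max(rd) > disk_radius + 1e-9)
    stop("sections extend beyond the disk radius", call. = FALSE)
  structure(list(sections = sections, valves = valves,
                 disk_radius = disk_radius),
            class = "lane_design")
}

#' @export
print.lane_design <- function(x, ...) {
  cat("Lane design:", length(x$sections), "sections,",
      length(x$valves), "valves, disk radius", x$disk_radius, "mm\n")
  print(as.data.frame(x), digits = 4)
  invisible(x)
}

#' @export
as.data.frame.lane_design <- function(x, ...) {
  data.frame(
    label = vapply(x$sections, `[[`, character(1), "label"),
    r_proximal_mm = vapply(x$sections, `[[`, numeric(1), "r_proximal"),
    r_distal_mm = vapply(x$sections, `[[`, numeric(1), "r_distal"),
    medium_density_g_ml = vapply(x$sections, `[[`, numeric(1), "medium_density"),
    medium_viscosity_mpa_s = vapply(x$sections, `[[`, numeric(1),
                                    "medium_viscosity"),
    stringsAsFactors = FALSE
  )
}

# Index of the section containing radius r_mm, half-open [r_p, r_d);
# the distal end of the last section is included so a cell at the wall
# still has a home.
section_index_at <- function(lane, r_mm) {
  rp <- vapply(lane$sections, `[[`, numeric(1), "r_proximal")
  rd <- vapply(lane$sections, `[[`, numeric(1), "r_distal")
  n <- length(rp)
  if (r_mm >= rd[n]) return(n)
  i <- which(r_mm >= rp - 1e-12 & r_mm < rd)
  if (!length(i)) stop("radius ", r_mm, " mm lies outside the lane",
                       call. = FALSE)
  i[1L]
}

#' Ramped spin protocol
#'
#' A trapezoidal spin programme: linear acceleration to a plateau RCF, a
#' constant-speed plateau, then linear deceleration to rest. Ramp rates are
#' expressed in RCF/min as motor controllers report them. RCF is converted
#' to rotational speed at a single reference radius.
#'
#' Derived quantities: acceleration time `t_a = plateau_rcf / accel_rate`
#' and deceleration time `t_d = plateau_rcf / decel_rate` (both in
#' seconds).
#'
#' @param plateau_rcf plateau relative centrifugal force in g-multiples
#'   (> 0).
#' @param accel_rate,decel_rate ramp rates in RCF/min (> 0).
#' @param plateau_duration time at plateau speed, seconds (> 0).
#' @param reference_radius radius in mm at which RCF converts to RPM;
#'   defaults to the 60 mm outer radius of the reference disk.
#' @return an object of class `spin_protocol` with elements including
#'   `t_a`, `t_d` (s) and `plateau_rpm`.
#' @examples
#' spin_protocol()  # 500 RCF, 500 RCF/min up, 4 min plateau, 322 RCF/min down
#' @export
spin_protocol <- function(plateau_rcf = 500, accel_rate = 500,
                          decel_rate = 322, plateau_duration = 240,
                          reference_radius = 60) {
  vals <- c(plateau_rcf, accel_rate, decel_rate, plateau_duration,
            reference_radius)
  if (any(vals <= 0))
    stop("all spin_protocol rates, durations and radii must be > 0",
         call. = FALSE)
  t_a <- plateau_rcf / accel_rate * 60
  t_d <- plateau_rcf / decel_rate * 60
  plateau_rpm <- speed_convert(plateau_rcf, mm_to_m(reference_radius),
                               "to_rpm")
  structure(list(plateau_rcf = plateau_rcf,
                 accel_rate = accel_rate,
                 decel_rate = decel_rate,
                 plateau_duration = plateau_duration,
                 reference_radius = reference_radius,
                 t_a = t_a, t_d = t_d,
                 plateau_rpm = plateau_rpm),
            class = "spin_protocol")
}

#' @export
print.spin_protocol <- function(x, ...) {
  cat(sprintf(paste0(
    "Spin protocol: %g RCF plateau for %g s (ref. radius %g mm -> %.0f RPM)\n",
    "  accelerate %g RCF/min (t_a = %.1f s), decelerate %g RCF/min (t_d = %.1f s)\n"),
    x$plateau_rcf, x$plateau_duration, x$reference_radius, x$plateau_rpm,
    x$accel_rate, x$t_a, x$decel_rate, x$t_d))
  invisible(x)
}

# Plateau angular velocity in rev/s at the protocol's reference radius.
plateau_rev_s <- function(protocol) protocol$plateau_rpm / 60

#' Built-in reference lane geometry
#'
#' The reference disk lane: an outer radius of 60 mm carrying five
#' 7 mm-long gradient sections (A distal-most to E) plus the proximal
#' sample section F, tiling inward from the rim in 7 mm steps
#' (F spans 18-25 mm, A spans 53-60 mm). Capillary valves with a
#' 1 mm x 7 mm footprint sit at each internal boundary; their height is
#' the bonded channel height, 0.67 mm (the 0.05 + 0.28 + 0.34 mm adhesive
#' stack). Valve footprints are contained within the boundaries and add no
#' radial length.
#'
#' By default every section, including F, is filled with Histopaque-1077
#' (1.077 g/mL; viscosity defaults to 1.5 mPa.s, a typical value for the
#' medium rather than a manufacturer figure). Passing a [fluid_sample()]
#' as `sample_fluid` instead models a loaded assay: section F then takes
#' the sample's own density and viscosity as its medium, which is how
#' cells actually start a run (suspended in diluted blood, not in
#' gradient medium).
#'
#' @param sample_fluid optional [fluid_sample()]; if supplied, section F's
#'   medium is the sample itself.
#' @param medium_density gradient medium density in g/mL (default
#'   Histopaque-1077).
#' @param medium_viscosity gradient medium viscosity in mPa.s.
#' @param channel_height bonded channel height in mm, shared by all valves.
#' @param channel_width lane (and valve) width in mm.
#' @param disk_radius outer radius in mm.
#' @param section_length radial extent of each section in mm.
#' @return a [lane_design()] with 6 sections and 5 valves.
#' @examples
#' reference_lane()
#' reference_lane(sample_fluid = fluid_sample())
#' @export
reference_lane <- function(sample_fluid = NULL,
                           medium_density = 1.077,
                           medium_viscosity = 1.5,
                           channel_height = 0.67,
                           channel_width = 7,
                           disk_radius = 60,
                           section_length = 7) {
  labels <- c("F", "E", "D", "C", "B", "A")  # proximal -> distal
  n <- length(labels)
  rd <- disk_radius - (rev(seq_len(n)) - 1L) * section_length
  rp <- rd - section_length
  sections <- vector("list", n)
  for (i in seq_len(n)) {
    if (i == 1L && !is.null(sample_fluid)) {
      stopifnot(inherits(sample_fluid, "fluid_sample"))
      dens <- sample_fluid$density
      visc <- sample_fluid$viscosity
    } else {
      dens <- medium_density
      visc <- medium_viscosity
    }
    sections[[i]] <- medium_section(labels[i], dens, visc, rp[i], rd[i],
                                    volume = 12)
  }
  valves <- lapply(rd[-n], function(r)
    valve_geometry(height = channel_height, width = channel_width,
                   radial_position = r))
  lane_design(sections, valves, disk_radius)
}

#' Built-in blood-cell reference panel
#'
#' The six common blood components with specific densities and effective
#' radii from the standard haematology literature. Where the literature
#' gives a range, the stored value is the midpoint of that range
#' (overridable by constructing [cell_species()] directly):
#'
#' | species    | density (g/mL)       | radius (um)  |
#' |------------|----------------------|--------------|
#' | Monocyte   | 1.067-1.077 -> 1.072 | 6-7.5 -> 6.75|
#' | Lymphocyte | 1.073-1.077 -> 1.075 | 3-6   -> 4.5 |
#' | Basophil   | 1.072-1.078 -> 1.075 | 4.5-5 -> 4.75|
#' | Neutrophil | 1.08-1.09   -> 1.085 | 6-7.5 -> 6.75|
#' | Eosinophil | 1.09-1.1    -> 1.095 | 6-7.5 -> 6.75|
#' | RBC        | 1.098                | 2.63         |
#'
#' @param rbc_agglutination agglutination factor applied to the RBC entry
#'   (default 1 = single cells). Red cells aggregate into rouleaux in
#'   Histopaque, so values around 2-4 model realistic settling.
#' @return a named list of [cell_species()].
#' @export
reference_cell_panel <- function(rbc_agglutination = 1) {
  panel <- list(
    cell_species("Monocyte",   density = 1.072, radius = 6.75),
    cell_species("Lymphocyte", density = 1.075, radius = 4.5),
    cell_species("Basophil",   density = 1.075, radius = 4.75),
    cell_species("Neutrophil", density = 1.085, radius = 6.75),
    cell_species("Eosinophil", density = 1.095, radius = 6.75),
    cell_species("RBC",        density = 1.098, radius = 2.63,
                 agglutination_factor = rbc_agglutination)
  )
  names(panel) <- vapply(panel, `[[`, character(1), "name")
  panel
}

panel_to_data_frame <- function(panel) {
  data.frame(
    name = vapply(panel, `[[`, character(1), "name"),
    density_g_ml = vapply(panel, `[[`, numeric(1), "density"),
    radius_um = vapply(panel, `[[`, numeric(1), "radius"),
    agglutination_factor = vapply(panel, `[[`, numeric(1),
                                  "agglutination_factor"),
    row.names = NULL, stringsAsFactors = FALSE
  )
}
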