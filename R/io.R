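# Device-configuration and count-table round-tripping. Configs are YAML
# with interface units (mm, g/mL, mPa.s, degrees) converted at this
# boundary; count tables are plain CSV.

CONFIG_SCHEMA_VERSION <- 1L

check_keys <- function(node, allowed, where) {
  unknown <- setdiff(names(node), allowed)
  if (length(unknown))
    stop("unknown key(s) in ", where, ": ",
         paste(unknown, collapse = ", "), call. = FALSE)
}

check_g_ml <- function(x, where) {
  # Densities belong in g/mL here; a value this large is almost certainly
  # kg/m^3 and silently accepting it would corrupt every downstream number.
  if (x > 100)
    stop(where, " = ", x, " is not a plausible density in g/mL ",
         "(did you enter kg/m^3?)", call. = FALSE)
  x
}

#' Read a device configuration
#'
#' Loads a YAML experiment description — lane geometry, gradient sections,
#' valve footprint, spin protocol, sample fluid and cell panel — and
#' returns fully validated domain objects. The file uses interface units
#' throughout: mm, g/mL, mPa.s, degrees, N/m. Unknown keys are rejected by
#' name, and densities whose magnitude implies SI units produce a hard
#' error rather than a silent conversion.
#'
#' A section's `medium` may be the literal string `"sample"`, in which
#' case it takes the density and viscosity of the configured fluid (the
#' loaded-sample section).
#'
#' The schema (`schema_version: 1`) is documented in the shipped example:
#' `system.file("extdata", "paper_reference.yaml", package = "spindisc")`.
#'
#' @param path path to a YAML configuration file.
#' @return an object of class `design_config`: a list with `lane`
#'   ([lane_design()]), `protocol` ([spin_protocol()]), `fluid`
#'   ([fluid_sample()]) and `panel` (list of [cell_species()]).
#' @examples
#' cfg <- read_design(system.file("extdata", "paper_reference.yaml",
#'                                package = "spindisc"))
#' cfg$lane
#' @export
read_design <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  doc <- yaml::read_yaml(path)
  check_keys(doc, c("schema_version", "fluid", "protocol", "lane", "panel"),
             "config root")
  if (is.null(doc$schema_version) ||
      doc$schema_version != CONFIG_SCHEMA_VERSION)
    stop("unrecognized schema_version: ",
         if (is.null(doc$schema_version)) "(missing)" else doc$schema_version,
         " (expected ", CONFIG_SCHEMA_VERSION, ")", call. = FALSE)

  f <- doc$fluid
  check_keys(f, c("surface_tension_n_m", "contact_angle_deg", "density_g_ml",
                  "viscosity_mpa_s"), "fluid")
  fluid <- fluid_sample(
    surface_tension = f$surface_tension_n_m,
    contact_angle = f$contact_angle_deg,
    density = check_g_ml(f$density_g_ml, "fluid density_g_ml"),
    viscosity = f$viscosity_mpa_s)

  p <- doc$protocol
  check_keys(p, c("plateau_rcf", "accel_rcf_min", "decel_rcf_min",
                  "plateau_s", "reference_radius_mm"), "protocol")
  protocol <- spin_protocol(
    plateau_rcf = p$plateau_rcf, accel_rate = p$accel_rcf_min,
    decel_rate = p$decel_rcf_min, plateau_duration = p$plateau_s,
    reference_radius = p$reference_radius_mm)

  l <- doc$lane
  check_keys(l, c("disk_radius_mm", "valve", "sections"), "lane")
  check_keys(l$valve, c("height_mm", "width_mm"), "lane valve")
  sections <- lapply(l$sections, function(s) {
    check_keys(s, c("label", "medium", "medium_density_g_ml",
                    "medium_viscosity_mpa_s", "r_proximal_mm", "r_distal_mm",
                    "volume_ul"), paste0("section '", s$label, "'"))
    if (identical(s$medium, "sample")) {
      dens <- fluid$density
      visc <- fluid$viscosity
    } else {
      dens <- check_g_ml(s$medium_density_g_ml,
                         paste0("section '", s$label, "' medium_density_g_ml"))
      visc <- s$medium_viscosity_mpa_s
    }
    medium_section(s$label, dens, visc, s$r_proximal_mm, s$r_distal_mm,
                   volume = if (is.null(s$volume_ul)) NA_real_ else s$volume_ul)
  })
  rd <- vapply(sections, `[[`, numeric(1), "r_distal")
  valves <- lapply(rd[-length(rd)], function(r)
    valve_geometry(l$valve$height_mm, l$valve$width_mm, radial_position = r))
  lane <- lane_design(sections, valves, l$disk_radius_mm)

  panel <- lapply(doc$panel, function(sp) {
    check_keys(sp, c("name", "density_g_ml", "radius_um",
                     "agglutination_factor"), paste0("panel '", sp$name, "'"))
    cell_species(sp$name,
                 density = check_g_ml(sp$density_g_ml,
                                      paste0("panel '", sp$name,
                                             "' density_g_ml")),
                 radius = sp$radius_um,
                 agglutination_factor =
                   if (is.null(sp$agglutination_factor)) 1
                   else sp$agglutination_factor)
  })
  names(panel) <- vapply(panel, `[[`, character(1), "name")

  structure(list(lane = lane, protocol = protocol, fluid = fluid,
                 panel = panel),
            class = "design_config")
}

#' Write a device configuration
#'
#' Serialises a design back to the YAML schema read by [read_design()].
#' Section media are written as explicit density/viscosity values, so a
#' write-then-read round trip reproduces the loaded objects value for
#' value.
#'
#' @param design a `design_config` as returned by [read_design()], or a
#'   list with elements `lane`, `protocol`, `fluid`, `panel`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_design <- function(design, path) {
  lane <- design$lane; protocol <- design$protocol
  fluid <- design$fluid; panel <- design$panel
  stopifnot(inherits(lane, "lane_design"), inherits(protocol, "spin_protocol"),
            inherits(fluid, "fluid_sample"))
  v1 <- lane$valves[[1L]]
  doc <- list(
    schema_version = CONFIG_SCHEMA_VERSION,
    fluid = list(surface_tension_n_m = fluid$surface_tension,
                 contact_angle_deg = fluid$contact_angle,
                 density_g_ml = fluid$density,
                 viscosity_mpa_s = fluid$viscosity),
    protocol = list(plateau_rcf = protocol$plateau_rcf,
                    accel_rcf_min = protocol$accel_rate,
                    decel_rcf_min = protocol$decel_rate,
                    plateau_s = protocol$plateau_duration,
                    reference_radius_mm = protocol$reference_radius),
    lane = list(
      disk_radius_mm = lane$disk_radius,
      valve = list(height_mm = v1$height, width_mm = v1$width),
      sections = lapply(lane$sections, function(s) {
        out <- list(label = s$label,
                    medium_density_g_ml = s$medium_density,
                    medium_viscosity_mpa_s = s$medium_viscosity,
                    r_proximal_mm = s$r_proximal,
                    r_distal_mm = s$r_distal)
        if (!is.na(s$volume)) out$volume_ul <- s$volume
        out
      })),
    panel = lapply(panel, function(sp)
      list(name = sp$name, density_g_ml = sp$density,
           radius_um = sp$radius,
           agglutination_factor = sp$agglutination_factor))
  )
  names(doc$panel) <- NULL
  yaml::write_yaml(doc, path, precision = 15L)
  invisible(path)
}

#' Read a count-table CSV
#'
#' Reads a CSV with header `disk,section,cell_class,count` and returns a
#' validated [count_table()]. Negative, non-integer or missing counts and
#' duplicate `(disk, section, cell_class)` keys are rejected with the
#' offending row identified.
#'
#' @param path path to the CSV file.
#' @return a [count_table()].
#' @export
read_counts <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("disk", "section", "cell_class", "count")
  if (!identical(sort(names(df)), sort(need)))
    stop("count CSV must have exactly the header: ",
         paste(need, collapse = ","), call. = FALSE)
  count_table(df)
}

#' Write a count-table CSV
#'
#' @param table a [count_table()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(table, path) {
  table <- count_table(table)
  utils::write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
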