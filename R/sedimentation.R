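# Closed-form Stokes sedimentation timing through discrete density
# sections, ramp correction, migration schedules and end-of-run partition
# prediction.
#
# A cell of effective radius R and density rho settling through a medium
# (rho0, eta) on a disk spinning at omega rev/s obeys
#   d(ln r)/dt = 8 pi^2 omega^2 R^2 (rho - rho0) / (9 eta)
# so the time to cross a section from r_p to r_d is
#   t = 9 eta ln(r_d/r_p) / (8 pi^2 omega^2 R^2 (rho - rho0)).
# Sections are crossed in radial order; a medium at least as dense as the
# cell stops it at the section's proximal interface (isopycnic trapping).

# Log-slope sedimentation rate k = d(ln r)/dt in 1/s for one cell in one
# section's medium, at omega_rev_s rev/s. Non-positive when the cell
# cannot sediment.
sediment_rate <- function(cell, section, omega_rev_s) {
  drho <- g_ml_to_kg_m3(cell$density - section$medium_density)
  eta <- mpa_s_to_pa_s(section$medium_viscosity)
  8 * pi^2 * omega_rev_s^2 * effective_radius_m(cell)^2 * drho / (9 * eta)
}

#' Time for a cell to cross one density section
#'
#' Closed-form Stokes transit time
#' \deqn{t = \frac{9 \eta \ln(r_d/r_p)}{8 \pi^2 \omega^2 R^2 (\rho - \rho^\circ)}}
#' with \eqn{\omega} in rev/s and \eqn{R} the effective particle radius
#' (single-cell radius times the agglutination factor). A medium at least
#' as dense as the cell cannot be traversed: the function returns `Inf`,
#' the non-traversable marker.
#'
#' @param cell a [cell_species()].
#' @param section a [medium_section()]; its proximal radius must be > 0
#'   (the logarithm is undefined at the rotation axis).
#' @param omega_rev_s constant angular velocity in revolutions per second
#'   (> 0).
#' @return transit time in seconds, or `Inf` if the section is
#'   non-traversable.
#' @examples
#' rbc <- cell_species("RBC", 1.098, 2.63)
#' s <- medium_section("C", 1.077, 1.5, r_proximal = 30, r_distal = 37)
#' section_transit_time(rbc, s, omega_rev_s = 60)
#' @export
section_transit_time <- function(cell, section, omega_rev_s) {
  stopifnot(inherits(cell, "cell_species"), inherits(section, "medium_section"))
  if (omega_rev_s <= 0) stop("omega_rev_s must be > 0", call. = FALSE)
  if (section$r_proximal <= 0)
    stop("r_proximal must be > 0: transit time is undefined at the axis",
         call. = FALSE)
  k <- sediment_rate(cell, section, omega_rev_s)
  if (k <= 0) return(Inf)
  log(section$r_distal / section$r_proximal) / k
}

#' Ramp correction to the total centrifugation time
#'
#' Spin-up and spin-down contribute less sedimentation per unit time than
#' the plateau. The total-time correction for linear speed ramps is
#' \deqn{\Delta t = \tfrac{2}{3}(t_a + t_d)}
#' where \eqn{t_a} and \eqn{t_d} are the acceleration and deceleration
#' times: a linear-in-RPM ramp achieves one third of the plateau's
#' \eqn{\int \omega^2 dt} over its duration, so two thirds of each ramp is
#' "lost" time that must be added to the plateau-speed estimate.
#'
#' @param protocol a [spin_protocol()].
#' @return correction in seconds.
#' @examples
#' ramp_correction(spin_protocol())  # ~102.1 s for the default protocol
#' @export
ramp_correction <- function(protocol) {
  stopifnot(inherits(protocol, "spin_protocol"))
  2 * (protocol$t_a + protocol$t_d) / 3
}

# Advance one cell along the lane at constant omega_rev_s for up to
# time_budget seconds of plateau-equivalent spinning. Returns the final
# radius (mm), the boundary-crossing log, and whether the cell was stopped
# by a medium it cannot enter.
advance_cell <- function(cell, lane, omega_rev_s, time_budget,
                         start_r = NULL) {
  secs <- lane$sections
  if (is.null(start_r)) start_r <- secs[[1L]]$r_proximal
  if (start_r <= 0)
    stop("start radius must be > 0", call. = FALSE)
  i <- section_index_at(lane, start_r)
  r <- start_r
  t <- 0
  labels <- character(0)
  times <- numeric(0)
  trapped <- FALSE
  repeat {
    s <- secs[[i]]
    k <- sediment_rate(cell, s, omega_rev_s)
    if (k <= 0) { trapped <- TRUE; break }
    t_cross <- log(s$r_distal / r) / k
    if (t + t_cross <= time_budget) {
      t <- t + t_cross
      r <- s$r_distal
      labels <- c(labels, s$label)
      times <- c(times, t)
      if (i == length(secs)) break          # distal wall reached
      i <- i + 1L
    } else {
      r <- r * exp(k * (time_budget - t))
      t <- time_budget
      break
    }
  }
  list(final_r = r, time = t, trapped = trapped,
       crossings = data.frame(section = labels, cumulative_time_s = times,
                              stringsAsFactors = FALSE))
}

#' Migration schedule of one cell species along a lane
#'
#' Walks the cell from the proximal edge of the sample section through
#' successive density sections at the protocol's plateau speed,
#' accumulating the closed-form transit time of each section, and stops at
#' the first section whose medium is at least as dense as the cell
#' (isopycnic trapping) or at the distal wall. The ramp correction
#' `2 (t_a + t_d) / 3` is added once to the lane total.
#'
#' The plateau speed is the protocol RCF converted at the protocol's
#' single reference radius and held constant along the lane; radial
#' variation of the centrifugal field is handled only by the numerical
#' integrator ([simulate_trajectory()]).
#'
#' @param cell a [cell_species()].
#' @param lane a [lane_design()].
#' @param protocol a [spin_protocol()].
#' @return an object of class `migration_result`: a list with `species`,
#'   `boundary_arrivals` (data.frame of section label and cumulative
#'   plateau-equivalent time at which the cell clears that section's
#'   distal boundary), `terminal_section` (label of the section containing
#'   the cell's resting position), `trapped_at_interface`,
#'   `ramp_correction_s`, and `total_time_s` (cumulative traversal time
#'   plus the ramp correction; the predicted wall-clock centrifugation
#'   time for the cell to reach its terminal position).
#' @examples
#' lane <- reference_lane()
#' migration_schedule(cell_species("Neutrophil", 1.085, 6.75),
#'                    lane, spin_protocol())
#' @export
migration_schedule <- function(cell, lane, protocol) {
  stopifnot(inherits(cell, "cell_species"), inherits(lane, "lane_design"),
            inherits(protocol, "spin_protocol"))
  omega <- plateau_rev_s(protocol)
  adv <- advance_cell(cell, lane, omega, Inf)
  corr <- ramp_correction(protocol)
  terminal <- lane$sections[[section_index_at(lane, adv$final_r)]]$label
  structure(list(species = cell$name,
                 boundary_arrivals = adv$crossings,
                 terminal_section = terminal,
                 trapped_at_interface = adv$trapped,
                 final_radius_mm = adv$final_r,
                 ramp_correction_s = corr,
                 total_time_s = adv$time + corr),
            class = "migration_result")
}

#' @export
print.migration_result <- function(x, ...) {
  cat("Migration schedule for", x$species, "\n")
  if (nrow(x$boundary_arrivals)) {
    print(x$boundary_arrivals, digits = 4, row.names = FALSE)
  } else {
    cat("  (no section fully traversed)\n")
  }
  cat(if (x$trapped_at_interface)
    sprintf("  trapped at interface, resting in section %s (r = %.2f mm)\n",
            x$terminal_section, x$final_radius_mm)
    else
      sprintf("  reaches section %s (r = %.2f mm)\n",
              x$terminal_section, x$final_radius_mm))
  cat(sprintf("  total time incl. ramp correction: %.1f s\n", x$total_time_s))
  invisible(x)
}

#' Predicted end-of-run partition of a cell panel
#'
#' For each species, advances the cell for the sedimentation-equivalent
#' duration of the full spin protocol and reports the section containing
#' its final radial position. The protocol's wall-clock duration is
#' `t_a + plateau_duration + t_d`; because the ramps contribute only one
#' third of plateau-rate sedimentation per unit time, the equivalent
#' plateau time is `plateau_duration + (t_a + t_d) / 3` (the wall clock
#' minus the ramp correction).
#'
#' A cell trapped at a density interface rests exactly at the boundary
#' radius, which under the half-open `[r_proximal, r_distal)` section
#' convention lies in the distal (blocking) section — the banding position
#' from which such cells are recovered in practice. A cell that reaches
#' the distal wall is assigned to the distal-most section.
#'
#' @param panel list of [cell_species()] (e.g. [reference_cell_panel()]).
#' @param lane a [lane_design()].
#' @param protocol a [spin_protocol()].
#' @return an object of class `partition_map`: a data.frame with one row
#'   per species (`species`, `section`, `final_radius_mm`, `trapped`).
#' @examples
#' lane <- reference_lane(sample_fluid = fluid_sample())
#' predict_partitions(reference_cell_panel(rbc_agglutination = 3),
#'                    lane, spin_protocol())
#' @export
predict_partitions <- function(panel, lane, protocol) {
  stopifnot(is.list(panel), inherits(lane, "lane_design"),
            inherits(protocol, "spin_protocol"))
  omega <- plateau_rev_s(protocol)
  t_eff <- protocol$plateau_duration + (protocol$t_a + protocol$t_d) / 3
  rows <- lapply(panel, function(cell) {
    stopifnot(inherits(cell, "cell_species"))
    adv <- advance_cell(cell, lane, omega, t_eff)
    data.frame(species = cell$name,
               section = lane$sections[[section_index_at(lane, adv$final_r)]]$label,
               final_radius_mm = adv$final_r,
               trapped = adv$trapped,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  class(out) <- c("partition_map", "data.frame")
  out
}

#' @export
print.partition_map <- function(x, ...) {
  cat("Predicted partitions at protocol end:\n")
  print.data.frame(x, digits = 4, row.names = FALSE)
  invisible(x)
}
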