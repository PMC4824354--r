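# Numerical integration of a cell's radial trajectory under a
# time-varying spin speed. This is the package's independent check on the
# closed-form section timing: it uses the local centrifugal acceleration
# omega(t)^2 * r at the cell's actual radius and supports spin-up/down
# ramps, which the closed form approximates with a single correction term.

# Angular velocity (rad/s) at time t under a trapezoidal protocol.
# ramp = "rcf": RCF rises/falls linearly in time (omega ~ sqrt(t)), the
#   literal reading of a ramp quoted in RCF/min.
# ramp = "rpm": rotational speed rises/falls linearly in time, the reading
#   under which the 2(t_a + t_d)/3 total-time correction is exact.
# ramp = "none": constant plateau speed from t = 0 (no deceleration), used
#   for closed-form comparisons.
protocol_omega_fun <- function(protocol, ramp = c("rcf", "rpm", "none")) {
  ramp <- match.arg(ramp)
  w_max <- rpm_to_rad_s(protocol$plateau_rpm)
  t_a <- protocol$t_a
  t_d <- protocol$t_d
  t1 <- t_a + protocol$plateau_duration
  t2 <- t1 + t_d
  function(t) {
    if (ramp == "none") return(w_max)
    if (t <= 0) return(0)
    if (t < t_a) {
      frac <- t / t_a
      return(if (ramp == "rcf") w_max * sqrt(frac) else w_max * frac)
    }
    if (t <= t1) return(w_max)
    if (t < t2) {
      frac <- (t2 - t) / t_d
      return(if (ramp == "rcf") w_max * sqrt(frac) else w_max * frac)
    }
    0
  }
}

#' Simulate a cell's radial trajectory numerically
#'
#' Integrates the Stokes settling law
#' \deqn{dr/dt = \frac{2}{9} \frac{R^2 (\rho - \rho^\circ(r))}{\eta(r)} \omega(t)^2 r}
#' with piecewise-constant medium properties taken from the section the
#' cell currently occupies and the local centrifugal acceleration
#' \eqn{\omega(t)^2 r}. The velocity is clamped at zero where the medium
#' is at least as dense as the cell (no flotation), and the cell halts at
#' the distal wall. Integration is fixed-step fourth-order Runge-Kutta
#' (via \pkg{deSolve}); section-boundary crossing times are located by
#' linear interpolation between steps.
#'
#' @param cell a [cell_species()].
#' @param lane a [lane_design()].
#' @param protocol a [spin_protocol()].
#' @param ramp ramp shape: `"rcf"` (RCF linear in time, the default),
#'   `"rpm"` (rotational speed linear in time), or `"none"` (constant
#'   plateau speed throughout, for closed-form comparisons).
#' @param dt integration step in seconds.
#' @param t_end end time in seconds; defaults to the protocol duration
#'   `t_a + plateau_duration + t_d` (or just the plateau duration when
#'   `ramp = "none"`).
#' @param start_r starting radius in mm; defaults to the proximal edge of
#'   the sample (first) section.
#' @return an object of class `cell_trajectory`: a list with `path`
#'   (data.frame: `time_s`, `radius_mm`, `section`), `crossings`
#'   (data.frame: `boundary_mm`, `section_entered`, `time_s`), `species`,
#'   and the arguments used.
#' @examples
#' lane <- reference_lane(sample_fluid = fluid_sample())
#' tr <- simulate_trajectory(reference_cell_panel()$Neutrophil, lane,
#'                           spin_protocol(), dt = 0.1)
#' head(tr$path)
#' @export
simulate_trajectory <- function(cell, lane, protocol,
                                ramp = c("rcf", "rpm", "none"),
                                dt = 0.02, t_end = NULL, start_r = NULL) {
  stopifnot(inherits(cell, "cell_species"), inherits(lane, "lane_design"),
            inherits(protocol, "spin_protocol"))
  ramp <- match.arg(ramp)
  if (dt <= 0) stop("dt must be > 0", call. = FALSE)
  if (is.null(t_end))
    t_end <- if (ramp == "none") protocol$plateau_duration else
      protocol$t_a + protocol$plateau_duration + protocol$t_d
  secs <- lane$sections
  if (is.null(start_r)) start_r <- secs[[1L]]$r_proximal
  if (start_r <= 0) stop("start radius must be > 0", call. = FALSE)

  omega_fun <- protocol_omega_fun(protocol, ramp)
  r_wall <- mm_to_m(secs[[length(secs)]]$r_distal)
  rp_si <- mm_to_m(vapply(secs, `[[`, numeric(1), "r_proximal"))
  rd_si <- mm_to_m(vapply(secs, `[[`, numeric(1), "r_distal"))
  rho_med <- g_ml_to_kg_m3(vapply(secs, `[[`, numeric(1), "medium_density"))
  eta_med <- mpa_s_to_pa_s(vapply(secs, `[[`, numeric(1), "medium_viscosity"))
  R2 <- effective_radius_m(cell)^2
  rho_cell <- g_ml_to_kg_m3(cell$density)

  # The wall halt is applied in post-processing, not in the derivative:
  # integrating freely past the wall keeps the solution smooth inside each
  # step, so first-passage times interpolate with O(dt^2) accuracy instead
  # of picking up an O(dt) bias from a clamped final step.
  deriv <- function(t, y, parms) {
    r <- min(y[1L], r_wall)
    i <- findInterval(r, rp_si, rightmost.closed = TRUE)
    i <- min(max(i, 1L), length(rp_si))
    v <- (2 / 9) * R2 * (rho_cell - rho_med[i]) / eta_med[i] *
      omega_fun(t)^2 * r
    list(max(v, 0))
  }

  times <- seq(0, t_end, by = dt)
  if (times[length(times)] < t_end) times <- c(times, t_end)
  sol <- deSolve::ode(y = c(r = mm_to_m(start_r)), times = times,
                      func = deriv, parms = NULL, method = "rk4")
  r_raw <- sol[, "r"] * 1000
  r_mm <- pmin(r_raw, secs[[length(secs)]]$r_distal)
  sec_lab <- vapply(r_mm, function(r)
    secs[[section_index_at(lane, r)]]$label, character(1))
  path <- data.frame(time_s = sol[, "time"], radius_mm = r_mm,
                     section = sec_lab, stringsAsFactors = FALSE)

  # First passage of every section's distal edge (the last one is the
  # distal wall), linearly interpolated on the unclamped solution.
  boundaries <- vapply(secs, `[[`, numeric(1), "r_distal")
  entered <- c(vapply(secs[-1L], `[[`, character(1), "label"), NA_character_)
  keep <- boundaries > start_r + 1e-12
  cross_t <- vapply(boundaries, function(b) {
    idx <- which(r_raw >= b)[1L]
    if (is.na(idx) || idx == 1L) return(NA_real_)
    t0 <- path$time_s[idx - 1L]; t1 <- path$time_s[idx]
    r0 <- r_raw[idx - 1L]; r1 <- r_raw[idx]
    t0 + (b - r0) / (r1 - r0) * (t1 - t0)
  }, numeric(1))
  crossings <- data.frame(boundary_mm = boundaries, section_entered = entered,
                          time_s = cross_t, stringsAsFactors = FALSE)
  crossings <- crossings[keep & !is.na(crossings$time_s), , drop = FALSE]
  row.names(crossings) <- NULL

  structure(list(species = cell$name, path = path, crossings = crossings,
                 ramp = ramp, dt = dt, t_end = t_end, start_r = start_r),
            class = "cell_trajectory")
}

#' @export
print.cell_trajectory <- function(x, ...) {
  cat(sprintf("Trajectory of %s: %.1f s, ramp = %s, dt = %g s\n",
              x$species, x$t_end, x$ramp, x$dt))
  cat(sprintf("  start %.2f mm -> end %.2f mm (section %s)\n",
              x$start_r, x$path$radius_mm[nrow(x$path)],
              x$path$section[nrow(x$path)]))
  if (nrow(x$crossings)) {
    cat("  boundary crossings:\n")
    print(x$crossings, digits = 5, row.names = FALSE)
  }
  invisible(x)
}

#' @export
plot.cell_trajectory <- function(x, ...) {
  graphics::plot(x$path$time_s, x$path$radius_mm, type = "l",
                 xlab = "time (s)", ylab = "radius (mm)",
                 main = paste("Radial trajectory:", x$species), ...)
  graphics::abline(h = x$crossings$boundary_mm, lty = 3, col = "grey50")
  invisible(x)
}
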