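# Capillary burst-valve physics: Young-Laplace pinning threshold,
# centrifugal column pressure, and the burst-speed solver.

#' Young-Laplace burst threshold of a capillary valve
#'
#' Pressure difference a pinned meniscus can sustain at an abrupt
#' rectangular expansion:
#' \deqn{P_h = -2 \sigma \cos\theta_A (1/h + 1/w)}
#' with surface tension \eqn{\sigma}, advancing contact angle
#' \eqn{\theta_A}, and channel height and width \eqn{h, w}. The threshold
#' is positive for non-wetting fluids (\eqn{\theta_A > 90} degrees); at or
#' below 90 degrees the valve cannot pin and the threshold is reported as
#' zero with a warning.
#'
#' @param valve a [valve_geometry()] (dimensions in mm).
#' @param fluid a [fluid_sample()].
#' @return burst threshold pressure in Pa (scalar, >= 0).
#' @examples
#' v <- valve_geometry(height = 0.67, width = 7)
#' burst_pressure(v, fluid_sample())  # ~64.9 Pa
#' @export
burst_pressure <- function(valve, fluid) {
  stopifnot(inherits(valve, "valve_geometry"), inherits(fluid, "fluid_sample"))
  h <- mm_to_m(valve$height)
  w <- mm_to_m(valve$width)
  p <- -2 * fluid$surface_tension * cos(deg2rad(fluid$contact_angle)) *
    (1 / h + 1 / w)
  if (p <= 0) {
    warning("degenerate valve: contact angle <= 90 degrees cannot pin a ",
            "wetting fluid; burst threshold set to 0 Pa", call. = FALSE)
    p <- 0
  }
  p
}

#' Centrifugal pressure of a rotating liquid column
#'
#' Pressure exerted at the distal end of a liquid column spanning radii
#' `r_proximal` to `r_distal` while the disk spins at angular velocity
#' `omega`:
#' \deqn{P_A = \tfrac{1}{2} \rho \omega^2 |r_d^2 - r_p^2|}
#' The magnitude is used so that an outward-driven column always exerts a
#' positive driving pressure.
#'
#' @param density liquid density in g/mL.
#' @param r_proximal,r_distal radial extent of the liquid column in mm;
#'   `r_distal > r_proximal`.
#' @param omega angular velocity in rad/s (>= 0).
#' @return pressure in Pa.
#' @examples
#' column_pressure(1.060, r_proximal = 23, r_distal = 30, omega = 18.2) # ~65 Pa
#' @export
column_pressure <- function(density, r_proximal, r_distal, omega) {
  if (density <= 0) stop("density must be > 0", call. = FALSE)
  if (!(r_distal > r_proximal))
    stop("r_distal must exceed r_proximal", call. = FALSE)
  if (any(omega < 0)) stop("omega must be >= 0", call. = FALSE)
  rho <- g_ml_to_kg_m3(density)
  rp <- mm_to_m(r_proximal)
  rd <- mm_to_m(r_distal)
  0.5 * rho * omega^2 * abs(rd^2 - rp^2)
}

#' Burst speed of a capillary valve
#'
#' The rotational speed at which the centrifugal column pressure equals
#' the Young-Laplace burst threshold, from the closed form
#' \deqn{\omega = \sqrt{2 P_h / (\rho |r_d^2 - r_p^2|)}}
#' converted to RPM. The burst speed rises with the pinning threshold and
#' falls with column length and liquid density. A degenerate valve
#' (threshold 0) bursts at any speed and returns 0 RPM with a warning.
#'
#' @inheritParams burst_pressure
#' @param r_proximal,r_distal radial extent (mm) of the liquid column
#'   pressing on the valve.
#' @return burst speed in RPM.
#' @examples
#' v <- valve_geometry(height = 0.67, width = 7)
#' f <- fluid_sample()
#' burst_speed(v, f, r_proximal = 23, r_distal = 30)  # ~174 RPM
#' @export
burst_speed <- function(valve, fluid, r_proximal, r_distal) {
  p_h <- burst_pressure(valve, fluid)
  if (p_h == 0) {
    warning("burst threshold is 0 Pa: valve bursts at any speed",
            call. = FALSE)
    return(0)
  }
  rho <- g_ml_to_kg_m3(fluid$density)
  rp <- mm_to_m(r_proximal)
  rd <- mm_to_m(r_distal)
  if (!(rd > rp)) stop("r_distal must exceed r_proximal", call. = FALSE)
  omega <- sqrt(2 * p_h / (rho * abs(rd^2 - rp^2)))
  omega * 60 / (2 * pi)
}

#' Per-valve burst threshold table for a lane
#'
#' Evaluates the burst threshold and burst speed of every valve on a lane,
#' taking as the pressing liquid column the section immediately proximal
#' to each valve (the column that must burst through it during loading
#' and spin-up).
#'
#' @param lane a [lane_design()].
#' @param fluid a [fluid_sample()].
#' @param reference_radius radius (mm) at which burst RPM is also reported
#'   as RCF; defaults to the lane's disk radius.
#' @return a data.frame with one row per valve: valve index, radial
#'   position (mm), threshold `P_h` (Pa), burst RPM, and burst RCF at the
#'   reference radius.
#' @export
burst_table <- function(lane, fluid, reference_radius = lane$disk_radius) {
  stopifnot(inherits(lane, "lane_design"))
  n <- length(lane$valves)
  if (n == 0L)
    return(data.frame(valve = integer(), radial_position_mm = numeric(),
                      p_h_pa = numeric(), burst_rpm = numeric(),
                      burst_rcf = numeric()))
  rows <- lapply(seq_len(n), function(i) {
    v <- lane$valves[[i]]
    s <- lane$sections[[i]]  # section proximal to valve i
    p_h <- burst_pressure(v, fluid)
    rpm <- burst_speed(v, fluid, s$r_proximal, s$r_distal)
    data.frame(valve = i,
               radial_position_mm = v$radial_position,
               p_h_pa = p_h,
               burst_rpm = rpm,
               burst_rcf = speed_convert(rpm, mm_to_m(reference_radius),
                                         "to_rcf"))
  })
  do.call(rbind, rows)
}
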