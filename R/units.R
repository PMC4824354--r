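#' @keywords internal
#' @importFrom stats predict simulate sd setNames rmultinom
#' @importFrom graphics plot
#' @importFrom utils head read.csv write.csv write.table
"_PACKAGE"

# Standard gravity used for all RCF conversions, exact by convention.
G_STD <- 9.80665

deg2rad <- function(x) x * pi / 180

#' Convert between RCF and RPM at a reference radius
#'
#' Relative centrifugal force (RCF) is the centrifugal acceleration in
#' multiples of standard gravity, \eqn{RCF = r \omega^2 / g} with
#' \eqn{\omega} in rad/s and \eqn{g = 9.80665} m/s^2. The conversion is
#' anchored at a single radius, so the same spin speed corresponds to a
#' different RCF at every radial position on the disk.
#'
#' @param value non-negative speed value, RCF (g-multiples) or RPM
#'   depending on `direction`.
#' @param radius reference radius in metres (> 0).
#' @param direction `"to_rpm"` converts an RCF value to RPM;
#'   `"to_rcf"` converts an RPM value to RCF. The two are exact inverses.
#' @return the converted value (numeric, vectorised over `value`).
#' @examples
#' speed_convert(500, radius = 0.060, "to_rpm")  # ~2730 RPM
#' @export
speed_convert <- function(value, radius, direction = c("to_rpm", "to_rcf")) {
  direction <- match.arg(direction)
  stopifnot(is.numeric(value), is.numeric(radius), length(radius) == 1L)
  if (radius <= 0) stop("radius must be > 0", call. = FALSE)
  if (any(value < 0)) stop("speed values must be >= 0", call. = FALSE)
  if (direction == "to_rpm") {
    omega <- sqrt(value * G_STD / radius)      # rad/s
    omega * 60 / (2 * pi)
  } else {
    omega <- value * 2 * pi / 60               # rad/s
    radius * omega^2 / G_STD
  }
}

rpm_to_rad_s <- function(rpm) rpm * 2 * pi / 60
rad_s_to_rev_s <- function(omega) omega / (2 * pi)

# Interface units are mm, g/mL, mPa.s, degrees; everything internal is SI.
mm_to_m <- function(x) x / 1000
g_ml_to_kg_m3 <- function(x) x * 1000
kg_m3_to_g_ml <- function(x) x / 1000
mpa_s_to_pa_s <- function(x) x / 1000
um_to_m <- function(x) x / 1e6
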