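#' @useDynLib trackerr, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif rgamma rbinom sd var cor.test qlogis plogis
#'   pchisq optim logLik dgamma setNames aggregate as.formula complete.cases
#' @importFrom utils read.csv write.csv
NULL

# Earth radius (m) shared by the planar tangent plane and the spherical mode,
# so the two agree to sub-mm at fine scale.
.EARTH_RADIUS <- 6371000
.M_PER_DEG <- .EARTH_RADIUS * pi / 180

#' Convert an absolute angle to a compass azimuth
#'
#' Absolute angles measure step direction counterclockwise in radians from the
#' x (east/longitude) axis, the convention used by trajectory packages such as
#' adehabitatLT. Compass azimuths run clockwise from north in degrees. The two
#' are related by `az = (90 - theta * 180/pi) mod 360`, so 0 rad is east
#' (90 deg), +pi/2 rad is north (0 deg), -pi/2 rad is south (180 deg) and
#' pi rad is west (270 deg).
#'
#' @param theta Absolute angle(s) in radians. Must be finite.
#' @return Azimuth(s) in degrees, in `[0, 360)`.
#' @examples
#' absangle_to_azimuth(c(0, pi / 2, -pi / 2, pi))
#' @seealso [azimuth_to_absangle()]
#' @export
absangle_to_azimuth <- function(theta) {
  if (!is.numeric(theta) || any(!is.finite(theta)))
    stop("`theta` must be finite numeric (radians)")
  (90 - theta * 180 / pi) %% 360
}

#' Convert a compass azimuth to an absolute angle
#'
#' Inverse of [absangle_to_azimuth()]: maps degrees clockwise from north to
#' radians counterclockwise from east, wrapped to `(-pi, pi]` (ties at +/- pi
#' resolve to +pi, so 270 deg maps to +pi).
#'
#' @param az Azimuth(s) in degrees, each in `[0, 360)`.
#' @return Absolute angle(s) in radians in `(-pi, pi]`.
#' @export
azimuth_to_absangle <- function(az) {
  if (!is.numeric(az) || any(!is.finite(az)) || any(az < 0 | az >= 360))
    stop("`az` must be in [0, 360)")
  wrap_pi((90 - az) * pi / 180)
}

#' Wrap an angle in radians to (-pi, pi]
#'
#' @param x Angle(s) in radians.
#' @return Wrapped angle(s); exact ties at +/- pi return +pi.
#' @export
wrap_pi <- function(x) {
  r <- x %% (2 * pi)
  i <- which(r > pi)  # NA entries pass through untouched
  r[i] <- r[i] - 2 * pi
  r
}

#' Apply magnetic declination to a magnetic azimuth
#'
#' Magnetic declination is the east-positive angular offset between magnetic
#' and true geographic north; adding it to a magnetic compass azimuth yields
#' the true azimuth. For example, at a site with declination +5.133 deg, a
#' magnetic azimuth of 30 deg corresponds to a true azimuth of 35.133 deg.
#'
#' @param az_magnetic Magnetic azimuth(s) in degrees, in `[0, 360)`.
#' @param declination Declination in degrees, east-positive.
#' @return True azimuth(s) in degrees, in `[0, 360)`.
#' @export
apply_declination <- function(az_magnetic, declination) {
  if (any(az_magnetic < 0 | az_magnetic >= 360))
    stop("`az_magnetic` must be in [0, 360)")
  (az_magnetic + declination) %% 360
}

#' Circular (bearing) error between two azimuths
#'
#' The shortest angular separation on the circle, `min(|a-b|, 360-|a-b|)`.
#' Bearing errors are reported as absolute values because bearing is circular:
#' 350 deg and 10 deg are 20 deg apart, not 340.
#'
#' @param a,b Azimuths in degrees, in `[0, 360)`.
#' @return Error(s) in degrees, in `[0, 180]`.
#' @export
circular_error_deg <- function(a, b) {
  d <- abs(a - b) %% 360
  pmin(d, 360 - d)
}

#' Project WGS84 coordinates to a local planar frame
#'
#' Azimuthal equirectangular tangent plane at `origin`: x is meters east,
#' y meters north, with meters-per-degree-latitude `6371000 * pi / 180` and
#' longitude scaled by `cos(lat_origin)`. Intended for fine-scale work; a
#' warning is issued past a 10 km extent where planar distortion grows.
#'
#' @param lon,lat Coordinate vectors in decimal degrees (WGS84).
#' @param origin Numeric of length 2, `c(lon, lat)` of the tangent point.
#' @return A data.frame with columns `x`, `y` (meters).
#' @seealso [local_unproject()]
#' @export
local_project <- function(lon, lat, origin) {
  x <- (lon - origin[1]) * .M_PER_DEG * cos(origin[2] * pi / 180)
  y <- (lat - origin[2]) * .M_PER_DEG
  if (any(sqrt(x^2 + y^2) > 10000))
    warning("extent exceeds 10 km; planar approximation degrades")
  data.frame(x = x, y = y)
}

#' Inverse of [local_project()]
#'
#' @param x,y Planar coordinates in meters (east, north).
#' @param origin Numeric `c(lon, lat)` used in the forward projection.
#' @return A data.frame with columns `lon`, `lat` in decimal degrees.
#' @export
local_unproject <- function(x, y, origin) {
  lon <- origin[1] + x / (.M_PER_DEG * cos(origin[2] * pi / 180))
  lat <- origin[2] + y / .M_PER_DEG
  data.frame(lon = lon, lat = lat)
}

#' Dead-reckon WGS84 coordinates from distance-bearing steps
#'
#' Concatenates a trajectory from a start point and an ordered sequence of
#' (distance, azimuth) steps, the way a field worker's tape-and-compass log is
#' turned into coordinates. Azimuths are taken as magnetic unless
#' `declination = 0`; the declination is added to obtain true azimuths before
#' displacement.
#'
#' @param start Numeric `c(lon, lat)` (WGS84) of the trajectory start.
#' @param steps A data.frame with columns `distance_m` (> 0) and `azimuth_deg`
#'   (in `[0, 360)`), one row per step; zero rows allowed.
#' @param declination Magnetic declination in degrees, east-positive
#'   (default 0).
#' @param mode `"planar"` (default, tangent-plane) or `"sphere"`
#'   (great-circle forward on a sphere of radius 6,371,000 m). At <= 1 km
#'   extent the two agree to sub-mm.
#' @return A data.frame with columns `lon`, `lat`; first row is `start`,
#'   one further row per step.
#' @export
db_to_coords <- function(start, steps, declination = 0,
                         mode = c("planar", "sphere")) {
  mode <- match.arg(mode)
  if (nrow(steps) == 0)
    return(data.frame(lon = start[1], lat = start[2]))
  bad <- which(!is.finite(steps$distance_m) | steps$distance_m <= 0 |
                 !is.finite(steps$azimuth_deg) |
                 steps$azimuth_deg < 0 | steps$azimuth_deg >= 360)
  if (length(bad))
    stop(sprintf("invalid DB step at order %s: need distance > 0 and azimuth in [0, 360)",
                 paste(bad, collapse = ", ")))
  az <- apply_declination(steps$azimuth_deg, declination) * pi / 180
  if (mode == "planar") {
    x <- c(0, cumsum(steps$distance_m * sin(az)))
    y <- c(0, cumsum(steps$distance_m * cos(az)))
    local_unproject(x, y, start)
  } else {
    n <- nrow(steps)
    lon <- numeric(n + 1); lat <- numeric(n + 1)
    lon[1] <- start[1]; lat[1] <- start[2]
    for (i in seq_len(n)) {
      p <- sphere_forward(lon[i], lat[i], az[i], steps$distance_m[i])
      lon[i + 1] <- p[1]; lat[i + 1] <- p[2]
    }
    data.frame(lon = lon, lat = lat)
  }
}

# Great-circle forward problem on the sphere; azimuth in radians from north.
sphere_forward <- function(lon, lat, az, dist) {
  phi1 <- lat * pi / 180
  lam1 <- lon * pi / 180
  dr <- dist / .EARTH_RADIUS
  phi2 <- asin(sin(phi1) * cos(dr) + cos(phi1) * sin(dr) * cos(az))
  lam2 <- lam1 + atan2(sin(az) * sin(dr) * cos(phi1),
                       cos(dr) - sin(phi1) * sin(phi2))
  c(((lam2 * 180 / pi + 180) %% 360) - 180, phi2 * 180 / pi)
}

#' Derive step lengths, azimuths and turning angles from coordinates
#'
#' The inverse of dead reckoning: given an ordered set of fixes, computes per
#' step the planar distance, the absolute compass azimuth, and per interior
#' step the turning angle (wrapped difference of successive step directions,
#' in `(-pi, pi]`). Zero-length steps (passive fixes) have undefined azimuth,
#' encoded as `NA` rather than a spurious 0-degree bearing; turning angles
#' adjacent to an undefined azimuth are `NA` too.
#'
#' @param lon,lat Coordinate vectors (>= 1 point), decimal degrees WGS84.
#' @param min_distance Optional floor (m) applied to positive step lengths,
#'   emulating legacy trajectory software that cannot report distances below a
#'   preset minimum (e.g. 1.6 m). Default 0 = off.
#' @return A `step_series` object; see [step_series()].
#' @export
coords_to_steps <- function(lon, lat, min_distance = 0) {
  n <- length(lon)
  if (n < 2)
    return(step_series(numeric(0), numeric(0), numeric(0)))
  p <- local_project(lon, lat, c(lon[1], lat[1]))
  dx <- diff(p$x); dy <- diff(p$y)
  d <- sqrt(dx^2 + dy^2)
  az <- ifelse(d > 0, (atan2(dx, dy) * 180 / pi) %% 360, NA_real_)
  if (min_distance > 0) d[d > 0] <- pmax(d[d > 0], min_distance)
  theta <- azimuth_to_absangle(ifelse(is.na(az), 0, az))
  theta[is.na(az)] <- NA_real_
  turn <- if (n > 2) wrap_pi(diff(theta)) else numeric(0)
  step_series(d, az, turn)
}

#' Construct a step series
#'
#' Per-track derived arrays for a trajectory of `n + 1` fixes: `n` step
#' lengths (m; 0 allowed for passive steps), `n` absolute azimuths (degrees in
#' `[0, 360)`, `NA` for zero-length steps) and `n - 1` turning angles (radians
#' in `(-pi, pi]`, `NA` when either adjacent azimuth is undefined).
#'
#' @param step_lengths Numeric vector of step lengths (m), >= 0.
#' @param abs_azimuths Numeric vector, same length, degrees or `NA`.
#' @param turning_angles Numeric vector of length `length(step_lengths) - 1`
#'   (or 0 when there are no interior steps), radians or `NA`.
#' @return An object of class `step_series`.
#' @export
step_series <- function(step_lengths, abs_azimuths, turning_angles) {
  n <- length(step_lengths)
  stopifnot(length(abs_azimuths) == n,
            length(turning_angles) == max(n - 1, 0))
  if (any(step_lengths < 0, na.rm = TRUE)) stop("negative step length")
  structure(list(step_lengths = as.numeric(step_lengths),
                 abs_azimuths = as.numeric(abs_azimuths),
                 turning_angles = as.numeric(turning_angles)),
            class = "step_series")
}

#' @export
print.step_series <- function(x, ...) {
  n <- length(x$step_lengths)
  cat(sprintf("step_series: %d steps, total length %.2f m, %d defined turning angles\n",
              n, sum(x$step_lengths), sum(!is.na(x$turning_angles))))
  invisible(x)
}

#' @export
length.step_series <- function(x) length(x$step_lengths)
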