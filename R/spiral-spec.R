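#' Spiral specification
#'
#' Construct the full parameterization of one spiral family used for
#' coarse-grained genome tracing. A spherical spiral follows
#' \deqn{\theta = \frac{p}{2\pi r}(\varphi - \varphi_0)}
#' where \eqn{\theta} is the polar angle from the north pole (the spiral
#' axis) and \eqn{p} is the pitch, the distance between consecutive turns
#' measured along constant \eqn{\varphi}. A cylindrical spiral follows
#' \deqn{z = \frac{p}{2\pi}(\varphi - \varphi_0).}
#' Multi-start families (\code{n_entries} > 1, the "points of entry" of a
#' winding shell, like a multi-threaded screw) are obtained by replicating
#' the spiral at initial offsets \eqn{\varphi_0 + 2\pi k/n_{entries}}.
#'
#' The winding radius may be modulated as a harmonic function of
#' \eqn{\varphi}, \eqn{r(\varphi) = r + \sum_k a_k \cos(k\varphi + \psi_k)},
#' to absorb departures of faceted capsids from ideal spheres/cylinders.
#'
#' All lengths are in nanometres and all angles in radians at this
#' programmatic interface; the command-line interface accepts degrees.
#'
#' @param geometry "spherical" or "cylindrical".
#' @param r Winding radius, nm.
#' @param p Pitch (distance between consecutive turns along constant
#'   \eqn{\varphi}), nm.
#' @param phi0 Initial angular offset, radians.
#' @param center Spiral center, numeric 3-vector, nm.
#' @param axis Unit 3-vector: the spiral (polar) axis.
#' @param theta_start,theta_end Polar-angle bounds in \eqn{[0, \pi]},
#'   radians (spherical geometry only).
#' @param h Cylinder height, nm (cylindrical geometry only).
#' @param n_entries Number of entry strands (a multi-start spiral family),
#'   integer >= 1.
#' @param rise Arc-length spacing between consecutive base-pair
#'   pseudoatoms, nm. Default 0.34 nm, the canonical B-DNA rise, so that
#'   one pseudoatom represents one base pair.
#' @param harmonics Optional radius modulation: a data.frame with columns
#'   \code{order} (integer k), \code{amplitude} (nm) and \code{phase}
#'   (radians), one row per harmonic term.
#' @return An object of class \code{"spiral_spec"}.
#' @examples
#' spec <- spiral_spec("cylindrical", r = 18.84, p = 25.1, h = 30,
#'                     n_entries = 10)
#' spec
#' @export
spiral_spec <- function(geometry = c("cylindrical", "spherical"),
                        r, p, phi0 = 0, center = c(0, 0, 0),
                        axis = c(0, 0, 1),
                        theta_start = 0, theta_end = pi, h = NULL,
                        n_entries = 1L, rise = 0.34, harmonics = NULL) {
  geometry <- match.arg(geometry)
  spec <- structure(list(
    geometry    = geometry,
    r           = as.numeric(r),
    p           = as.numeric(p),
    phi0        = as.numeric(phi0),
    center      = as.numeric(center),
    axis        = as.numeric(axis),
    theta_start = as.numeric(theta_start),
    theta_end   = as.numeric(theta_end),
    h           = if (is.null(h)) NULL else as.numeric(h),
    n_entries   = as.integer(n_entries),
    rise        = as.numeric(rise),
    harmonics   = normalize_harmonics(harmonics)
  ), class = "spiral_spec")
  validate_spiral_spec(spec)
  spec
}

normalize_harmonics <- function(h) {
  if (is.null(h) || (is.data.frame(h) && nrow(h) == 0L)) return(NULL)
  if (is.numeric(h) && length(h) == 3L)
    h <- data.frame(order = h[1], amplitude = h[2], phase = h[3])
  if (!is.data.frame(h) ||
      !all(c("order", "amplitude", "phase") %in% names(h)))
    stop("harmonics must be a data.frame with columns order, amplitude, phase",
         call. = FALSE)
  data.frame(order = as.numeric(h$order),
             amplitude = as.numeric(h$amplitude),
             phase = as.numeric(h$phase))
}

#' Validate a spiral specification
#'
#' Checks every invariant of a \code{\link{spiral_spec}} and stops with a
#' message naming the offending field on the first violation. Called by the
#' constructor; exported so that externally assembled specs can be checked.
#'
#' @param spec A \code{spiral_spec}.
#' @return \code{spec}, invisibly.
#' @export
validate_spiral_spec <- function(spec) {
  stop_field <- function(field, msg)
    stop(sprintf("invalid spiral_spec: field '%s' %s", field, msg),
         call. = FALSE)
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  if (!spec$geometry %in% c("spherical", "cylindrical"))
    stop_field("geometry", "must be 'spherical' or 'cylindrical'")
  if (!num1(spec$r) || spec$r <= 0) stop_field("r", "must be > 0")
  if (!num1(spec$p) || spec$p <= 0) stop_field("p", "must be > 0")
  if (!num1(spec$rise) || spec$rise <= 0) stop_field("rise", "must be > 0")
  if (!num1(spec$phi0)) stop_field("phi0", "must be a finite number")
  if (length(spec$center) != 3L || !all(is.finite(spec$center)))
    stop_field("center", "must be a finite 3-vector")
  if (length(spec$axis) != 3L || !all(is.finite(spec$axis)))
    stop_field("axis", "must be a finite 3-vector")
  if (abs(sqrt(sum(spec$axis^2)) - 1) > 1e-9)
    stop_field("axis", "must be a unit vector (|axis| = 1 within 1e-9)")
  if (spec$n_entries < 1L) stop_field("n_entries", "must be >= 1")
  if (spec$geometry == "spherical") {
    if (!num1(spec$theta_start) || !num1(spec$theta_end))
      stop_field("theta_start/theta_end", "must be finite numbers")
    if (spec$theta_start < 0 || spec$theta_end > pi ||
        spec$theta_start > spec$theta_end)
      stop_field("theta_start/theta_end",
                 "must satisfy 0 <= theta_start <= theta_end <= pi")
  } else {
    if (is.null(spec$h) || !num1(spec$h) || spec$h <= 0)
      stop_field("h", "must be > 0 for cylindrical geometry")
  }
  if (!is.null(spec$harmonics)) {
    rng <- phi_range(spec)
    phis <- seq(rng[1], rng[2], length.out = 4096L)
    if (min(modulated_radius(spec, phis)) <= 0)
      stop_field("harmonics",
                 "must keep the modulated radius positive over the phi range")
  }
  invisible(spec)
}

# phi interval swept by one strand starting at spec$phi0
phi_range <- function(spec) {
  if (spec$geometry == "spherical") {
    spec$phi0 + c(spec$theta_start, spec$theta_end) * 2 * pi * spec$r / spec$p
  } else {
    spec$phi0 + c(0, spec$h) * 2 * pi / spec$p
  }
}

modulated_radius <- function(spec, phi) {
  r <- rep_len(spec$r, length(phi))
  h <- spec$harmonics
  if (!is.null(h))
    for (i in seq_len(nrow(h)))
      r <- r + h$amplitude[i] * cos(h$order[i] * phi + h$phase[i])
  r
}

modulated_radius_deriv <- function(spec, phi) {
  d <- numeric(length(phi))
  h <- spec$harmonics
  if (!is.null(h))
    for (i in seq_len(nrow(h)))
      d <- d - h$amplitude[i] * h$order[i] * sin(h$order[i] * phi + h$phase[i])
  d
}

#' @export
print.spiral_spec <- function(x, ...) {
  cat(sprintf("<spiral_spec: %s>\n", x$geometry))
  cat(sprintf("  r = %g nm, p = %g nm, phi0 = %g deg, rise = %g nm\n",
              x$r, x$p, x$phi0 * 180 / pi, x$rise))
  if (x$geometry == "spherical")
    cat(sprintf("  theta: [%g, %g] deg\n",
                x$theta_start * 180 / pi, x$theta_end * 180 / pi))
  else
    cat(sprintf("  h = %g nm\n", x$h))
  cat(sprintf("  center = (%g, %g, %g) nm, axis = (%g, %g, %g)\n",
              x$center[1], x$center[2], x$center[3],
              x$axis[1], x$axis[2], x$axis[3]))
  cat(sprintf("  n_entries = %d", x$n_entries))
  if (!is.null(x$harmonics))
    cat(sprintf(", %d radius harmonic(s)", nrow(x$harmonics)))
  cat("\n")
  invisible(x)
}

# Orthonormal frame whose third column is `axis`: the minimal rotation
# taking +z to `axis` (identity when axis == +z). Used so that traces
# generated about a tilted axis are exact rigid rotations of the
# default-axis trace.
axis_frame <- function(axis) {
  z <- c(0, 0, 1)
  c_ <- sum(z * axis)
  v <- c(z[2] * axis[3] - z[3] * axis[2],
         z[3] * axis[1] - z[1] * axis[3],
         z[1] * axis[2] - z[2] * axis[1])
  s2 <- sum(v^2)
  if (s2 < 1e-24) {
    if (c_ > 0) return(diag(3))
    return(diag(c(1, -1, -1)))  # axis == -z: half-turn about x
  }
  vx <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  diag(3) + vx + vx %*% vx * ((1 - c_) / s2)
}

# Rodrigues rotation matrix about unit `axis` by `angle` radians
rotation_about_axis <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  vx <- matrix(c(0, axis[3], -axis[2],
                 -axis[3], 0, axis[1],
                 axis[2], -axis[1], 0), 3, 3)
  diag(3) + sin(angle) * vx + (1 - cos(angle)) * (vx %*% vx)
}
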