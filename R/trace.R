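#' Coarse-grained spiral traces
#'
#' Generate the coarse-grained genome model: one pseudoatom per base pair,
#' placed along the spiral at equal arc-length steps of \code{spec$rise}.
#' The curve is parameterized by \eqn{\varphi}; its speed
#' \eqn{|d\mathbf{x}/d\varphi|} is integrated numerically (composite
#' trapezoid on a fine grid, refined until the grid is much finer than one
#' rise) to obtain cumulative arc length, which is inverted to locate the
#' pseudoatoms. Every emitted point is an exact evaluation of the curve, so
#' points lie on the (possibly radius-modulated) spiral surface to machine
#' precision.
#'
#' Point count is \code{floor(L/rise) + 1} where \code{L} is the strand's
#' arc length. Traces are emitted leading-end (5') first: from
#' \code{theta_start} for spherical spirals and from \code{z = 0} for
#' cylindrical ones.
#'
#' @param spec A \code{\link{spiral_spec}}. \code{make_spherical_trace} and
#'   \code{make_cylindrical_trace} generate the single strand at
#'   \code{spec$phi0}; \code{make_multi_entry} generates all
#'   \code{spec$n_entries} strands at offsets
#'   \eqn{\varphi_0 + 2\pi k/n_{entries}}; \code{make_trace} dispatches on
#'   \code{spec$geometry} and always honours \code{n_entries}.
#' @return An object of class \code{"spool_trace"}: a list with
#'   \code{points} (N x 3 matrix, nm), \code{entry} (integer strand label
#'   in \code{0:(n_entries-1)}) and \code{spec}.
#' @examples
#' tr <- make_trace(spiral_spec("cylindrical", r = 10, p = 12, h = 8))
#' nrow(tr$points)
#' @export
make_trace <- function(spec) {
  validate_spiral_spec(spec)
  make_multi_entry(spec)
}

#' @rdname make_trace
#' @export
make_spherical_trace <- function(spec) {
  validate_spiral_spec(spec)
  if (spec$geometry != "spherical")
    stop("make_spherical_trace requires geometry = 'spherical'",
         call. = FALSE)
  single_strand_trace(spec, spec$phi0)
}

#' @rdname make_trace
#' @export
make_cylindrical_trace <- function(spec) {
  validate_spiral_spec(spec)
  if (spec$geometry != "cylindrical")
    stop("make_cylindrical_trace requires geometry = 'cylindrical'",
         call. = FALSE)
  single_strand_trace(spec, spec$phi0)
}

#' @rdname make_trace
#' @export
make_multi_entry <- function(spec) {
  validate_spiral_spec(spec)
  n <- spec$n_entries
  strands <- lapply(seq_len(n) - 1L, function(k)
    single_strand_points(spec, spec$phi0 + 2 * pi * k / n))
  new_trace(do.call(rbind, strands),
            rep(seq_len(n) - 1L, vapply(strands, nrow, 1L)),
            spec)
}

new_trace <- function(points, entry, spec) {
  dimnames(points) <- NULL
  structure(list(points = points, entry = as.integer(entry), spec = spec),
            class = "spool_trace")
}

#' @export
print.spool_trace <- function(x, ...) {
  cat(sprintf("<spool_trace: %d pseudoatoms, %d entry strand(s), %s spiral>\n",
              nrow(x$points), length(unique(x$entry)), x$spec$geometry))
  invisible(x)
}

single_strand_trace <- function(spec, phi_start) {
  new_trace(single_strand_points(spec, phi_start), 0L, spec)
}

# Curve evaluation in world coordinates, vectorized over phi.
# `phi0` is the strand's own offset (the family offset for entry k).
curve_points <- function(spec, phi, phi0) {
  rho <- modulated_radius(spec, phi)
  if (spec$geometry == "spherical") {
    theta <- spec$p / (2 * pi * spec$r) * (phi - phi0)
    local <- cbind(rho * sin(theta) * cos(phi),
                   rho * sin(theta) * sin(phi),
                   rho * cos(theta))
  } else {
    z <- spec$p / (2 * pi) * (phi - phi0)
    local <- cbind(rho * cos(phi), rho * sin(phi), z)
  }
  B <- axis_frame(spec$axis)
  sweep(local %*% t(B), 2, spec$center, "+")
}

# |d position / d phi|, analytic
curve_speed <- function(spec, phi, phi0) {
  rho <- modulated_radius(spec, phi)
  drho <- modulated_radius_deriv(spec, phi)
  if (spec$geometry == "spherical") {
    tp <- spec$p / (2 * pi * spec$r)  # d theta / d phi
    theta <- tp * (phi - phi0)
    st <- sin(theta); ct <- cos(theta)
    dx <- drho * st * cos(phi) + rho * tp * ct * cos(phi) - rho * st * sin(phi)
    dy <- drho * st * sin(phi) + rho * tp * ct * sin(phi) + rho * st * cos(phi)
    dz <- drho * ct - rho * tp * st
    sqrt(dx^2 + dy^2 + dz^2)
  } else {
    sqrt(drho^2 + rho^2 + (spec$p / (2 * pi))^2)
  }
}

single_strand_points <- function(spec, phi_start) {
  if (spec$geometry == "spherical") {
    span <- (spec$theta_end - spec$theta_start) * 2 * pi * spec$r / spec$p
    phi_a <- phi_start + spec$theta_start * 2 * pi * spec$r / spec$p
  } else {
    span <- spec$h * 2 * pi / spec$p
    phi_a <- phi_start
  }
  if (span <= 0) {
    warning("degenerate spiral extent: emitting a single-point trace",
            call. = FALSE)
    return(curve_points(spec, phi_a, phi_start))
  }
  # coarse pass for the arc-length estimate, then a grid fine enough that
  # the trapezoid/interpolation error is far below 1% of one rise
  phi_c <- seq(phi_a, phi_a + span, length.out = 257L)
  L_est <- sum(diff(phi_c) *
                 (curve_speed(spec, phi_c, phi_start)[-257L] +
                  curve_speed(spec, phi_c, phi_start)[-1L]) / 2)
  n_fine <- max(2049L, 32L * ceiling(L_est / spec$rise) + 1L)
  phi_f <- seq(phi_a, phi_a + span, length.out = n_fine)
  sp <- curve_speed(spec, phi_f, phi_start)
  s <- c(0, cumsum(diff(phi_f) * (sp[-n_fine] + sp[-1L]) / 2))
  L <- s[n_fine]
  n_pts <- floor(L / spec$rise) + 1L
  s_target <- (seq_len(n_pts) - 1L) * spec$rise
  phi_i <- stats::approx(s, phi_f, xout = s_target, ties = "ordered")$y
  curve_points(spec, phi_i, phi_start)
}

#' Export a trace as plain text
#'
#' Writes one row per pseudoatom: \code{x y z entry_index} (nm,
#' whitespace-delimited), 5' end first within each entry strand.
#'
#' @param trace A \code{spool_trace}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_trace_txt <- function(trace, path) {
  df <- data.frame(x = trace$points[, 1], y = trace$points[, 2],
                   z = trace$points[, 3], entry = trace$entry)
  utils::write.table(format(df, digits = 10, trim = TRUE), path,
                     quote = FALSE, row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Arc length of one spiral strand
#'
#' Total arc length of the strand starting at \code{spec$phi0}, by the same
#' quadrature used for pseudoatom placement.
#'
#' @param spec A \code{\link{spiral_spec}}.
#' @param n Number of quadrature nodes.
#' @return Arc length in nm.
#' @export
spiral_arc_length <- function(spec, n = 20001L) {
  validate_spiral_spec(spec)
  if (spec$geometry == "spherical") {
    span <- (spec$theta_end - spec$theta_start) * 2 * pi * spec$r / spec$p
    phi_a <- spec$phi0 + spec$theta_start * 2 * pi * spec$r / spec$p
  } else {
    span <- spec$h * 2 * pi / spec$p
    phi_a <- spec$phi0
  }
  if (span <= 0) return(0)
  phi <- seq(phi_a, phi_a + span, length.out = n)
  sp <- curve_speed(spec, phi, spec$phi0)
  sum(diff(phi) * (sp[-n] + sp[-1L]) / 2)
}
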