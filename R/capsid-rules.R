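#' Capsid geometry and quantization rules
#'
#' Analytic relations between the spiral winding parameters of a spooled
#' dsDNA genome and the geometry of an elongated (C3-morphotype)
#' icosahedral capsid. Under nested-arc turnaround rules, two discrete
#' parameters — the number of points of entry \code{n_pe} (parallel
#' strands winding a shell, like a multi-start screw) and the number of
#' shells \code{n_s} whose end-cap turnarounds nest against the portal
#' funnel — fix the capsid inner diameter, so related viruses are
#' predicted to show a discrete rather than continuous diameter spectrum.
#'
#' @param n_pe Points of entry (integer).
#' @param n_s Number of shells obeying nested-arc turnaround rules.
#' @param theta_f Funnel/facet slope angle of the portal protein, degrees.
#' @param D_mp Portal minor diameter, nm.
#' @param C_cs Conical-slope edge correction, nm (may be negative).
#' @param L_cs Conical slope length, nm. When \code{NULL}, derived as
#'   \code{n_s * s_shell + C_cs}.
#' @param w_tr Transition-width correction between dome arcs and the
#'   cylindrical spiral, nm.
#' @param s_shell Intershell spacing, nm (default 2.3).
#' @param d_arc Dome arc spacing, nm (default 2.48).
#' @return For \code{capsid_params}, an object of class
#'   \code{"capsid_params"}.
#' @examples
#' cp <- capsid_params(n_pe = 10, theta_f = 51, D_mp = 4.7, L_cs = 8.5,
#'                     w_tr = 8.3)
#' capsid_inner_diameter(cp)
#' @export
capsid_params <- function(n_pe, n_s = NULL, theta_f, D_mp, C_cs = -2,
                          L_cs = NULL, w_tr = 0, s_shell = 2.3,
                          d_arc = 2.48) {
  if (n_pe < 2) stop("n_pe must be >= 2", call. = FALSE)
  if (!is.null(n_s) && n_s < 1) stop("n_s must be >= 1", call. = FALSE)
  if (theta_f <= 0 || theta_f >= 90)
    stop("theta_f must be in (0, 90) degrees", call. = FALSE)
  if (D_mp <= 0 || s_shell <= 0 || d_arc <= 0 || w_tr < 0)
    stop("D_mp, s_shell, d_arc must be > 0 and w_tr >= 0", call. = FALSE)
  if (is.null(L_cs) && is.null(n_s))
    stop("supply either L_cs or n_s (with C_cs)", call. = FALSE)
  structure(list(n_pe = as.integer(n_pe),
                 n_s = if (is.null(n_s)) NULL else as.integer(n_s),
                 theta_f = theta_f, D_mp = D_mp, C_cs = C_cs, L_cs = L_cs,
                 w_tr = w_tr, s_shell = s_shell, d_arc = d_arc),
            class = "capsid_params")
}

resolve_L_cs <- function(cp)
  if (!is.null(cp$L_cs)) cp$L_cs else cp$n_s * cp$s_shell + cp$C_cs

#' DNA slope angle of a winding shell
#'
#' The slope (axial over tangential travel) of DNA wound at radius r with
#' pitch p: \code{atan(p / (2 pi r))}, in degrees. Note: implemented with
#' the 2 pi factor, which is the form consistent with the geometry of a
#' helix unrolled onto a plane (one turn advances p axially while
#' travelling 2 pi r tangentially); the bare \code{atan(p/r)} form is not
#' self-consistent with the interhelical spacings this module computes.
#'
#' @param p Pitch, nm.
#' @param r Winding radius, nm.
#' @return Slope angle, degrees.
#' @examples
#' slope_angle(25.1, 18.84)  # ~12 degrees
#' @export
slope_angle <- function(p, r) {
  if (any(p <= 0) || any(r <= 0)) stop("p and r must be > 0", call. = FALSE)
  atan(p / (2 * pi * r)) * 180 / pi
}

#' Intrashell interhelical distance
#'
#' Perpendicular axis-to-axis distance between adjacent DNA strands within
#' one winding shell: \code{(p / n_pe) * cos(theta_s)}. Decreases as the
#' slope steepens (i.e. as r decreases at fixed p).
#'
#' @param p Pitch, nm.
#' @param n_pe Points of entry.
#' @param theta_s Slope angle, degrees.
#' @return Distance, nm.
#' @examples
#' intrashell_distance(25.1, 10, 12)  # ~2.46 nm
#' @export
intrashell_distance <- function(p, n_pe, theta_s) {
  if (any(n_pe < 1)) stop("n_pe must be >= 1", call. = FALSE)
  (p / n_pe) * cos(theta_s * pi / 180)
}

#' Intershell interhelical distance
#'
#' Perpendicular distance between the nearest DNA strands of two adjacent
#' shells. With hexagonal-like packing the nearest neighbour in the next
#' shell sits half an intrashell spacing over and one radial gap out, so
#' the distance is the hypotenuse \code{sqrt((d_intra/2)^2 + dr^2)}.
#'
#' @param d_intra Intrashell interhelical distance, nm.
#' @param dr Radial gap between the shells, nm.
#' @return Distance, nm.
#' @examples
#' intershell_distance(2.46, 2.18)  # ~2.50 nm
#' @export
intershell_distance <- function(d_intra, dr) {
  if (any(d_intra < 0) || any(dr < 0))
    stop("d_intra and dr must be >= 0", call. = FALSE)
  sqrt((d_intra / 2)^2 + dr^2)
}

#' Hexagonal-packing rotation offset between consecutive shells
#'
#' With n_pe equally spaced strands per shell (360/n_pe degrees apart in
#' cross-section), hexagonal packing requires consecutive shells to be
#' rotated by half that: \code{360 / (2 n_pe)} degrees.
#'
#' @param n_pe Points of entry.
#' @return Offset, degrees.
#' @examples
#' hexagonal_offset(10)  # 18 degrees
#' @export
hexagonal_offset <- function(n_pe) {
  if (any(n_pe < 1)) stop("n_pe must be >= 1", call. = FALSE)
  360 / (2 * n_pe)
}

#' DNA turns in the two end-cap domes
#'
#' Under nested-arc turnaround rules with an even number of entry points,
#' the leading end and the shell-1-to-shell-2 crossover sit in the same
#' (tail) dome and account for two of the n_pe entries; the remaining
#' entries pair up into turnaround arcs, giving \code{n_pe/2} turns in the
#' distal dome and \code{(n_pe - 2)/2} in the tail dome.
#'
#' @param n_pe Points of entry; must be even.
#' @return Named list: \code{distal}, \code{tail} (integer turn counts).
#' @examples
#' dome_turns(10)  # distal 5, tail 4
#' @export
dome_turns <- function(n_pe) {
  if (n_pe < 2 || n_pe %% 2 != 0)
    stop(paste("dome_turns: n_pe must be even and >= 2 (the turnaround",
               "rule assumes the leading end and crossover share a dome,",
               "which requires even n_pe)"), call. = FALSE)
  list(distal = as.integer(n_pe / 2), tail = as.integer((n_pe - 2) / 2))
}

#' Minimum radius conserving the number of entry points
#'
#' As shells shrink, the DNA slope steepens; at the limit (strands parallel
#' to the capsid axis) n_pe strands at separation \code{strand_sep} need a
#' circumference of \code{strand_sep * n_pe}, i.e. a minimum radius of
#' \code{strand_sep * n_pe / (2 pi)}.
#'
#' @param strand_sep Strand separation, nm.
#' @param n_pe Points of entry (>= 0; 0 gives 0).
#' @return Radius, nm.
#' @examples
#' min_conserving_radius(2.3, 10)  # ~3.7 nm
#' @export
min_conserving_radius <- function(strand_sep, n_pe) {
  if (any(strand_sep <= 0)) stop("strand_sep must be > 0", call. = FALSE)
  if (any(n_pe < 0)) stop("n_pe must be >= 0", call. = FALSE)
  strand_sep * n_pe / (2 * pi)
}

#' Portal-protein major diameter
#'
#' The funnel quantization relation: the sloping portion of the portal
#' (length L_cs at slope theta_f) widens the minor diameter D_mp to
#' \code{D_p = 2 L_cs sin(theta_f) + D_mp}. Alternatively L_cs is derived
#' from the number of nested shells as \code{n_s * s_shell + C_cs}.
#'
#' @param L_cs Conical slope length, nm; or \code{NULL} to use
#'   \code{n_s, s_shell, C_cs}.
#' @param theta_f Funnel slope angle, degrees.
#' @param D_mp Portal minor diameter, nm.
#' @param n_s,s_shell,C_cs Used only when \code{L_cs} is \code{NULL}.
#' @return Major diameter D_p, nm.
#' @examples
#' portal_major_diameter(8.5, 51, 4.7)  # ~18 nm
#' @export
portal_major_diameter <- function(L_cs = NULL, theta_f, D_mp,
                                  n_s = NULL, s_shell = 2.3, C_cs = -2) {
  if (is.null(L_cs)) {
    if (is.null(n_s)) stop("supply L_cs or n_s", call. = FALSE)
    L_cs <- n_s * s_shell + C_cs
  }
  2 * L_cs * sin(theta_f * pi / 180) + D_mp
}

#' Capsid inner diameter under nested-arc turnaround rules
#'
#' The full quantization formula: the dome contributes
#' \code{2 d_arc (n_pe/2 - 1) cos(theta_f)} (stacked turnaround arcs), the
#' portal funnel contributes \code{2 L_cs sin(theta_f)} over the minor
#' diameter \code{D_mp}, and \code{w_tr} corrects for the dome-to-cylinder
#' transition width:
#' \deqn{D = 2 d_{arc} (n_{pe}/2 - 1)\cos\theta_f +
#'       2 L_{cs} \sin\theta_f + D_{mp} + w_{tr}.}
#' The diameter is affine in \code{n_s} (through \code{L_cs}) and in
#' \code{n_pe/2 - 1}, hence quantized in the two integers.
#'
#' @param cp A \code{\link{capsid_params}}.
#' @return Inner diameter, nm.
#' @export
capsid_inner_diameter <- function(cp) {
  stopifnot(inherits(cp, "capsid_params"))
  tf <- cp$theta_f * pi / 180
  2 * cp$d_arc * (cp$n_pe / 2 - 1) * cos(tf) +
    2 * resolve_L_cs(cp) * sin(tf) + cp$D_mp + cp$w_tr
}

#' Survey the discrete capsid-diameter spectrum
#'
#' Tabulates \code{\link{capsid_inner_diameter}} over ranges of
#' \code{n_pe} and \code{n_s}, exposing the discrete spectrum of diameters
#' allowed by the winding rules.
#'
#' @param n_pe_values,n_s_values Integer vectors.
#' @param theta_f,D_mp,C_cs,w_tr,s_shell,d_arc As in
#'   \code{\link{capsid_params}}.
#' @return data.frame with columns \code{n_pe}, \code{n_s},
#'   \code{L_cs}, \code{D_p}, \code{inner_diameter}.
#' @export
capsid_diameter_table <- function(n_pe_values, n_s_values, theta_f, D_mp,
                                  C_cs = -2, w_tr = 0, s_shell = 2.3,
                                  d_arc = 2.48) {
  grid <- expand.grid(n_s = n_s_values, n_pe = n_pe_values)[, 2:1]
  grid$L_cs <- grid$n_s * s_shell + C_cs
  grid$D_p <- portal_major_diameter(grid$L_cs, theta_f, D_mp)
  grid$inner_diameter <- vapply(seq_len(nrow(grid)), function(i)
    capsid_inner_diameter(capsid_params(
      n_pe = grid$n_pe[i], n_s = grid$n_s[i], theta_f = theta_f,
      D_mp = D_mp, C_cs = C_cs, w_tr = w_tr, s_shell = s_shell,
      d_arc = d_arc)), numeric(1))
  rownames(grid) <- NULL
  grid
}
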