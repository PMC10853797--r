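#' Density grid container
#'
#' A regular 3D scalar field with explicit origin and per-axis voxel
#' spacing. Axis order is always X, Y, Z internally regardless of the
#' on-disk axis permutation of an MRC/CCP4 file. All lengths are nm
#' (converted from the Angstrom units of the MRC standard at I/O).
#'
#' Voxel \code{[i, j, k]} (1-based) is centered at
#' \code{origin + (c(i, j, k) - 1) * spacing}.
#'
#' @param values 3D numeric array.
#' @param origin Position of the center of voxel \code{[1,1,1]}, nm.
#' @param spacing Per-axis voxel size, nm (scalar recycled to 3).
#' @return An object of class \code{"density_grid"}.
#' @export
density_grid <- function(values, origin = c(0, 0, 0), spacing = 1) {
  if (length(dim(values)) != 3L)
    stop("values must be a 3D array", call. = FALSE)
  spacing <- rep_len(as.numeric(spacing), 3L)
  if (any(spacing <= 0)) stop("spacing must be > 0", call. = FALSE)
  if (any(dim(values) < 2L)) stop("dims must be >= 2 on all axes",
                                  call. = FALSE)
  structure(list(values = values, origin = as.numeric(origin),
                 spacing = spacing, dims = dim(values)),
            class = "density_grid")
}

#' @export
print.density_grid <- function(x, ...) {
  cat(sprintf("<density_grid: %d x %d x %d voxels, spacing (%g, %g, %g) nm>\n",
              x$dims[1], x$dims[2], x$dims[3],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  origin (%g, %g, %g) nm, values in [%g, %g]\n",
              x$origin[1], x$origin[2], x$origin[3],
              min(x$values), max(x$values)))
  invisible(x)
}

#' Trilinear interpolation of a density grid
#'
#' Interpolates grid values at arbitrary points. Points beyond the
#' outermost voxel centers are flagged as outside and get \code{NA}.
#' Trilinear interpolation reproduces node values exactly and is exact on
#' fields that are linear in each coordinate.
#'
#' @param grid A \code{\link{density_grid}}.
#' @param points Numeric 3-vector or N x 3 matrix, nm.
#' @return Numeric vector of interpolated values with attribute
#'   \code{"outside"}: a logical vector marking points outside the grid.
#' @export
interpolate_density <- function(grid, points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3L)
  fx <- (points[, 1] - grid$origin[1]) / grid$spacing[1]
  fy <- (points[, 2] - grid$origin[2]) / grid$spacing[2]
  fz <- (points[, 3] - grid$origin[3]) / grid$spacing[3]
  d <- grid$dims
  outside <- !(fx >= 0 & fx <= d[1] - 1 & fy >= 0 & fy <= d[2] - 1 &
               fz >= 0 & fz <= d[3] - 1)
  outside[is.na(outside)] <- TRUE
  out <- rep(NA_real_, nrow(points))
  if (any(!outside)) {
    fx <- fx[!outside]; fy <- fy[!outside]; fz <- fz[!outside]
    i0 <- pmin(floor(fx), d[1] - 2); tx <- fx - i0
    j0 <- pmin(floor(fy), d[2] - 2); ty <- fy - j0
    k0 <- pmin(floor(fz), d[3] - 2); tz <- fz - k0
    v <- grid$values
    idx <- function(di, dj, dk)
      v[(i0 + di) + d[1] * (j0 + dj) + d[1] * d[2] * (k0 + dk) + 1]
    out[!outside] <-
      idx(0, 0, 0) * (1 - tx) * (1 - ty) * (1 - tz) +
      idx(1, 0, 0) * tx       * (1 - ty) * (1 - tz) +
      idx(0, 1, 0) * (1 - tx) * ty       * (1 - tz) +
      idx(1, 1, 0) * tx       * ty       * (1 - tz) +
      idx(0, 0, 1) * (1 - tx) * (1 - ty) * tz +
      idx(1, 0, 1) * tx       * (1 - ty) * tz +
      idx(0, 1, 1) * (1 - tx) * ty       * tz +
      idx(1, 1, 1) * tx       * ty       * tz
  }
  attr(out, "outside") <- outside
  out
}

#' Fitting energy of a trace against a density map
#'
#' The objective used throughout: the negated sum of interpolated map
#' values at the pseudoatom positions, so that lower energy means better
#' fit. Points outside the grid contribute zero (not a penalty, so scans
#' over the center remain continuous) and are reported via
#' \code{outside_fraction}.
#'
#' @param trace A \code{spool_trace} (or bare N x 3 matrix of points, nm).
#' @param grid A \code{\link{density_grid}}.
#' @return An object of class \code{"fit_result"}: list with \code{spec},
#'   \code{energy_total}, \code{energy_per_atom}, \code{n_points},
#'   \code{outside_fraction}.
#' @export
fitting_energy <- function(trace, grid) {
  pts <- if (inherits(trace, "spool_trace")) trace$points else
    if (is.null(dim(trace))) matrix(trace, ncol = 3L) else trace
  if (is.null(pts) || nrow(pts) == 0L)
    stop("fitting_energy: trace is empty", call. = FALSE)
  rho <- interpolate_density(grid, pts)
  outside <- attr(rho, "outside")
  total <- -sum(rho[!outside])
  if (length(rho[!outside]) == 0L) total <- 0
  structure(list(
    spec = if (inherits(trace, "spool_trace")) trace$spec else NULL,
    energy_total = total,
    energy_per_atom = total / nrow(pts),
    n_points = nrow(pts),
    outside_fraction = mean(outside)
  ), class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf(
    "<fit_result: E_total = %.6g, E/atom = %.6g, %d points, %.1f%% outside>\n",
    x$energy_total, x$energy_per_atom, x$n_points,
    100 * x$outside_fraction))
  invisible(x)
}

#' Synthesize a planted-spiral density map
#'
#' Builds a synthetic density grid from a trace: each pseudoatom splats an
#' isotropic 3D Gaussian of standard deviation \code{sigma} and peak
#' \code{amplitude}, truncated at a radial distance of 4 sigma. Optional
#' i.i.d. Gaussian voxel noise is added with a fixed seed, so maps are
#' bit-reproducible. This stands in for an experimental cryo-EM map in all
#' validation work: a map with a known, planted spiral whose parameters a
#' scan should recover.
#'
#' @param trace A \code{spool_trace} or N x 3 matrix of points, nm.
#' @param sigma Gaussian splat standard deviation, nm.
#' @param voxel Isotropic voxel size, nm.
#' @param amplitude Peak density of one splat.
#' @param noise_sd Standard deviation of additive Gaussian voxel noise
#'   (0 = noise-free).
#' @param seed Integer seed for the noise (ignored when noise_sd = 0).
#' @param padding Margin added around the trace bounding box, nm.
#' @return A \code{\link{density_grid}}.
#' @export
synth_map <- function(trace, sigma = 0.5, voxel = 0.4, amplitude = 1,
                      noise_sd = 0, seed = 1L, padding = 2) {
  pts <- if (inherits(trace, "spool_trace")) trace$points else
    if (is.null(dim(trace))) matrix(trace, ncol = 3L) else trace
  if (sigma <= 0 || voxel <= 0 || padding <= 0)
    stop("sigma, voxel and padding must be > 0", call. = FALSE)
  if (sigma < voxel / 2)
    warning("sigma < voxel/2: splats are undersampled by the grid",
            call. = FALSE)
  lo <- apply(pts, 2, min) - padding
  hi <- apply(pts, 2, max) + padding
  dims <- pmax(2L, as.integer(ceiling((hi - lo) / voxel)) + 1L)
  vals <- array(0, dims)
  cutoff <- 4 * sigma
  nrad <- ceiling(cutoff / voxel)
  for (n in seq_len(nrow(pts))) {
    ctr <- (pts[n, ] - lo) / voxel  # 0-based fractional voxel index
    i0 <- pmax(0L, floor(ctr) - nrad)
    i1 <- pmin(dims - 1L, ceiling(ctr) + nrad)
    if (any(i0 > i1)) next
    ax <- (seq.int(i0[1], i1[1]) - ctr[1]) * voxel
    ay <- (seq.int(i0[2], i1[2]) - ctr[2]) * voxel
    az <- (seq.int(i0[3], i1[3]) - ctr[3]) * voxel
    d2 <- outer(outer(ax^2, ay^2, "+"), az^2, "+")
    g <- amplitude * exp(-d2 / (2 * sigma^2))
    g[d2 > cutoff^2] <- 0
    xs <- seq.int(i0[1], i1[1]) + 1L
    ys <- seq.int(i0[2], i1[2]) + 1L
    zs <- seq.int(i0[3], i1[3]) + 1L
    vals[xs, ys, zs] <- vals[xs, ys, zs] + g
  }
  if (noise_sd > 0) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                        globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(as.integer(seed))
    vals <- vals + array(stats::rnorm(prod(dims), sd = noise_sd), dims)
  }
  density_grid(vals, origin = lo, spacing = voxel)
}
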