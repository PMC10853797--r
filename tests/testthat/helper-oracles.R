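# Independent oracles and fixture builders used across the suite.
# Everything here is deliberately brute-force / analytic and shares no code
# with the package implementation paths it checks.

# numerical arc length of a spherical spiral by a fine Riemann sum over
# ds = r * sqrt(1 + (2*pi*r*sin(theta)/p)^2) dtheta
oracle_spherical_arc_length <- function(r, p, theta_start, theta_end,
                                        n = 2e5) {
  th <- seq(theta_start, theta_end, length.out = n + 1)
  mid <- (th[-1] + th[-(n + 1)]) / 2
  dth <- diff(th)
  sum(r * sqrt(1 + (2 * pi * r * sin(mid) / p)^2) * dth)
}

# brute-force trilinear interpolation, one point at a time, explicit loops
oracle_trilinear <- function(grid, pt) {
  f <- (pt - grid$origin) / grid$spacing
  d <- grid$dims
  if (any(f < 0) || any(f > d - 1)) return(NA_real_)
  i <- pmin(floor(f), d - 2)
  t <- f - i
  acc <- 0
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (if (dx) t[1] else 1 - t[1]) *
         (if (dy) t[2] else 1 - t[2]) *
         (if (dz) t[3] else 1 - t[3])
    acc <- acc + w * grid$values[i[1] + dx + 1, i[2] + dy + 1,
                                 i[3] + dz + 1]
  }
  acc
}

# rotation matrix about a unit axis (Rodrigues), test-local copy
oracle_rotmat <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

# Independent low-level MRC writer used to test dialect handling.
# Writes mode-2 data in an arbitrary axis order (mapc/mapr/maps) with
# nstart-based origin, little-endian, values in Angstrom units.
oracle_write_mrc <- function(path, values_xyz, spacing_nm, nstart_xyz,
                             axis_order = c(1, 2, 3)) {
  dims_xyz <- dim(values_xyz)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4L,
                             endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4L,
                             endian = "little")
  disk_vals <- aperm(values_xyz, axis_order)   # disk dim d = axis order[d]
  wi(dim(disk_vals)); wi(2L)
  wi(nstart_xyz[axis_order])
  wi(dims_xyz)
  wf(spacing_nm * 10 * dims_xyz); wf(c(90, 90, 90))
  wi(axis_order)
  wf(c(min(values_xyz), max(values_xyz), mean(values_xyz)))
  wi(c(1L, 0L)); writeBin(raw(100L), con)
  wf(c(0, 0, 0))                               # origin words unset
  writeChar("MAP ", con, 4L, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0, 0)), con)
  wf(stats::sd(as.numeric(values_xyz))); wi(0L)
  writeBin(raw(800L), con)
  writeBin(as.numeric(disk_vals), con, size = 4L, endian = "little")
  invisible(path)
}

# Independent rigid-placement oracle for duplex building on a trace.
# Finite-difference tangents (the documented contract), minimal-rotation
# parallel transport (a different discrete transport than the package's
# double-reflection method), explicit per-atom rigid placement.
oracle_build_atoms <- function(pts, twist_deg, template, base = "A") {
  n <- nrow(pts)
  tg <- matrix(0, n, 3)
  tg[1, ] <- pts[2, ] - pts[1, ]
  tg[n, ] <- pts[n, ] - pts[n - 1, ]
  if (n > 2) tg[2:(n - 1), ] <- pts[3:n, ] - pts[1:(n - 2), ]
  tg <- tg / sqrt(rowSums(tg^2))
  u <- matrix(0, n, 3)
  cv <- pts[1, ] - 2 * pts[2, ] + pts[3, ]
  u0 <- cv - sum(cv * tg[1, ]) * tg[1, ]
  u[1, ] <- u0 / sqrt(sum(u0^2))
  for (i in seq_len(n - 1)) {
    ax <- c(tg[i, 2] * tg[i + 1, 3] - tg[i, 3] * tg[i + 1, 2],
            tg[i, 3] * tg[i + 1, 1] - tg[i, 1] * tg[i + 1, 3],
            tg[i, 1] * tg[i + 1, 2] - tg[i, 2] * tg[i + 1, 1])
    s <- sqrt(sum(ax^2))
    cth <- sum(tg[i, ] * tg[i + 1, ])
    u[i + 1, ] <- if (s < 1e-14) u[i, ] else
      as.numeric(oracle_rotmat(ax / s, atan2(s, cth)) %*% u[i, ])
  }
  tp <- template[[base]]
  loc <- as.matrix(tp[, c("x", "y", "z")])
  out <- vector("list", n)
  for (i in seq_len(n)) {
    yv <- as.numeric(oracle_rotmat(tg[i, ],
                                   (i - 1) * twist_deg * pi / 180) %*% u[i, ])
    zv <- tg[i, ]
    xv <- c(yv[2] * zv[3] - yv[3] * zv[2],
            yv[3] * zv[1] - yv[1] * zv[3],
            yv[1] * zv[2] - yv[2] * zv[1])
    R <- cbind(xv, yv, zv)
    xyz <- sweep(loc %*% t(R), 2, pts[i, ], "+")
    out[[i]] <- data.frame(bp = i, strand = tp$strand, atom = tp$atom,
                           x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
  }
  do.call(rbind, out)
}

# planted-spec fixture: a cylindrical or spherical single-strand spec with
# parameters drawn from realistic shell dimensions
random_planted_spec <- function(geometry = c("cylindrical", "spherical")) {
  geometry <- match.arg(geometry)
  r <- stats::runif(1, 7, 12)
  p <- stats::runif(1, 7, 16)
  phi0 <- stats::runif(1, 0, 2 * pi)
  if (geometry == "cylindrical")
    spiral_spec("cylindrical", r = r, p = p, phi0 = phi0,
                h = stats::runif(1, 8, 12))
  else
    spiral_spec("spherical", r = r, p = p, phi0 = phi0,
                theta_start = pi / 6, theta_end = 5 * pi / 6)
}

# circular trace in the xy-plane (used by the atomistic oracle tests)
circle_trace_points <- function(radius = 5, rise = 0.34, n = 60) {
  s <- (seq_len(n) - 1) * rise
  cbind(radius * cos(s / radius), radius * sin(s / radius), 0)
}
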