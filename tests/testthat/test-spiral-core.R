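test_that("spiral_spec validates its invariants and names offending fields", {
  expect_error(spiral_spec("cylindrical", r = -1, p = 2, h = 5), "'r'")
  expect_error(spiral_spec("cylindrical", r = 1, p = 0, h = 5), "'p'")
  expect_error(spiral_spec("cylindrical", r = 1, p = 2, h = 5, rise = 0),
               "'rise'")
  expect_error(spiral_spec("cylindrical", r = 1, p = 2, h = -1), "'h'")
  expect_error(spiral_spec("spherical", r = 1, p = 2, theta_start = -0.1),
               "theta_start")
  expect_error(spiral_spec("spherical", r = 1, p = 2, theta_end = 3.5),
               "theta")
  expect_error(spiral_spec("cylindrical", r = 1, p = 2, h = 5,
                           axis = c(0, 0, 2)), "'axis'")
  expect_error(spiral_spec("cylindrical", r = 1, p = 2, h = 5,
                           n_entries = 0), "n_entries")
  # harmonic modulation must keep the radius positive over the swept range
  expect_error(spiral_spec("cylindrical", r = 1, p = 2, h = 5,
                           harmonics = data.frame(order = 1, amplitude = 2,
                                                  phase = 0)),
               "harmonics")
})

test_that("spherical spiral has constant pitch: r * dtheta per turn = p", {
  spec <- spiral_spec("spherical", r = 10, p = 2.5, phi0 = 0,
                      theta_start = 0, theta_end = pi)
  set.seed(42)
  phis <- runif(100, 0, 20 * pi)
  pos1 <- dnaspool:::curve_points(spec, phis, 0)
  pos2 <- dnaspool:::curve_points(spec, phis + 2 * pi, 0)
  th1 <- acos(pmin(1, pmax(-1, pos1[, 3] / 10)))
  th2 <- acos(pmin(1, pmax(-1, pos2[, 3] / 10)))
  expect_true(all(abs(10 * (th2 - th1) - 2.5) < 1e-6))
})

test_that("point count matches floor(L/rise) + 1 with L from the quadrature oracle", {
  spec <- spiral_spec("spherical", r = 10, p = 2.5, theta_start = 0,
                      theta_end = pi, rise = 0.34)
  L <- oracle_spherical_arc_length(10, 2.5, 0, pi)
  tr <- make_spherical_trace(spec)
  expect_equal(nrow(tr$points), floor(L / 0.34) + 1)
  expect_equal(spiral_arc_length(spec), L, tolerance = 1e-6)
})

test_that("pseudoatoms are spaced one rise apart along arc length", {
  specs <- list(
    spiral_spec("spherical", r = 8, p = 3, theta_start = 0.2,
                theta_end = 2.8),
    spiral_spec("cylindrical", r = 8, p = 10, h = 12),
    spiral_spec("cylindrical", r = 8, p = 10, h = 12,
                harmonics = data.frame(order = 3, amplitude = 0.6,
                                       phase = 0.5)))
  for (spec in specs) {
    tr <- make_trace(spec)
    gaps <- sqrt(rowSums(diff(tr$points)^2))
    # chord length <= arc length = rise; uniformity within 1% of rise
    expect_lt(stats::sd(gaps), 0.01 * spec$rise)
    expect_lt(abs(mean(gaps) - spec$rise), 0.01 * spec$rise)
  }
})

test_that("every point lies on the (modulated) spiral surface", {
  spec <- spiral_spec("spherical", r = 9, p = 4, theta_start = 0.1,
                      theta_end = 3)
  tr <- make_spherical_trace(spec)
  expect_lt(max(abs(sqrt(rowSums(tr$points^2)) - 9)), 1e-6)

  harm <- data.frame(order = 5, amplitude = 0.8, phase = 1.1)
  spec2 <- spiral_spec("cylindrical", r = 9, p = 6, h = 10,
                       harmonics = harm)
  tr2 <- make_cylindrical_trace(spec2)
  phi <- atan2(tr2$points[, 2], tr2$points[, 1])
  r_expect <- 9 + 0.8 * cos(5 * phi + 1.1)  # 2*pi-periodic in phi
  expect_lt(max(abs(sqrt(rowSums(tr2$points[, 1:2]^2)) - r_expect)), 1e-6)
})

test_that("phi0 shift equals rotation about the axis", {
  for (geom in c("spherical", "cylindrical")) {
    base <- if (geom == "spherical")
      spiral_spec(geom, r = 7, p = 3, phi0 = 0.3, theta_start = 0.2,
                  theta_end = 2.5)
    else spiral_spec(geom, r = 7, p = 9, phi0 = 0.3, h = 8)
    delta <- 0.7
    shifted <- base; shifted$phi0 <- base$phi0 + delta
    tr0 <- make_trace(base)
    tr1 <- make_trace(shifted)
    rot <- tr0$points %*% t(oracle_rotmat(c(0, 0, 1), delta))
    expect_lt(max(abs(tr1$points - rot)), 1e-9)
  }
})

test_that("generation about a tilted axis equals rotating the default-axis trace", {
  ax <- c(1, 2, 2) / 3
  base <- spiral_spec("cylindrical", r = 6, p = 8, h = 7,
                      center = c(1, -2, 3))
  tilted <- spiral_spec("cylindrical", r = 6, p = 8, h = 7,
                        center = c(1, -2, 3), axis = ax)
  # minimal rotation taking +z to ax, same convention the generator uses
  v <- c(-ax[2], ax[1], 0)
  R <- oracle_rotmat(v / sqrt(sum(v^2)), acos(ax[3]))
  tr0 <- make_trace(base)
  tr1 <- make_trace(tilted)
  expected <- sweep(sweep(tr0$points, 2, c(1, -2, 3)) %*% t(R), 2,
                    c(1, -2, 3), "+")
  expect_lt(max(abs(tr1$points - expected)), 1e-9)
})

test_that("zero-amplitude harmonics reproduce the unmodulated trace bit-for-bit", {
  plain <- spiral_spec("cylindrical", r = 8, p = 10, h = 9)
  zero <- spiral_spec("cylindrical", r = 8, p = 10, h = 9,
                      harmonics = data.frame(order = c(2, 5),
                                             amplitude = c(0, 0),
                                             phase = c(0.3, 1)))
  expect_identical(make_trace(plain)$points, make_trace(zero)$points)
})

test_that("cylindrical spiral: dz over one turn is p; constant radius", {
  spec <- spiral_spec("cylindrical", r = 18.84, p = 25.1, h = 60)
  phis <- seq(0, 8, length.out = 17)
  z1 <- dnaspool:::curve_points(spec, phis, 0)[, 3]
  z2 <- dnaspool:::curve_points(spec, phis + 2 * pi, 0)[, 3]
  expect_equal(z2 - z1, rep(25.1, 17), tolerance = 1e-12)
  tr <- make_cylindrical_trace(spec)
  expect_lt(max(abs(sqrt(rowSums(tr$points[, 1:2]^2)) - 18.84)), 1e-9)
})

test_that("10-entry family: strands are 36 deg rotations, p/10 axial offsets", {
  spec <- spiral_spec("cylindrical", r = 10, p = 25.1, h = 20,
                      n_entries = 10)
  tr <- make_multi_entry(spec)
  s0 <- tr$points[tr$entry == 0L, ]
  for (k in c(1L, 4L, 9L)) {
    sk <- tr$points[tr$entry == k, ]
    rotated <- s0 %*% t(oracle_rotmat(c(0, 0, 1), 2 * pi * k / 10))
    expect_lt(max(abs(sk - rotated)), 1e-9)
  }
  # at fixed phi, adjacent strands are p/n_pe = 2.51 nm apart axially
  z_at_phi0 <- vapply(0:9, function(k)
    dnaspool:::curve_points(spec, 4 * pi, 2 * pi * k / 10)[, 3],
    numeric(1))
  expect_equal(sort(diff(sort(z_at_phi0))), rep(2.51, 9),
               tolerance = 1e-9)
})

test_that("multi-entry cross-section angles are equally spaced 360/n_pe apart", {
  spec <- spiral_spec("cylindrical", r = 9, p = 30, h = 25,
                      n_entries = 10)
  tr <- make_multi_entry(spec)
  # brute force: nearest point of each strand to the z = 12 plane
  nearest <- vapply(0:9, function(k) {
    idx <- which(tr$entry == k)
    idx[which.min(abs(tr$points[idx, 3] - 12))]
  }, integer(1))
  ang <- sort(atan2(tr$points[nearest, 2], tr$points[nearest, 1])) * 180 / pi
  gaps <- diff(c(ang, ang[1] + 360))
  expect_equal(length(ang), 10L)
  expect_true(all(abs(gaps - 36) < 1.5))
})

test_that("n_entries = 1 multi-entry equals the single-spiral generator", {
  spec <- spiral_spec("spherical", r = 7, p = 4, theta_start = 0.3,
                      theta_end = 2.6)
  expect_identical(make_multi_entry(spec)$points,
                   make_spherical_trace(spec)$points)
})

test_that("pole start and degenerate extent are handled", {
  spec <- spiral_spec("spherical", r = 5, p = 3, theta_start = 0,
                      theta_end = pi / 2, center = c(1, 1, 1))
  tr <- make_spherical_trace(spec)
  expect_equal(tr$points[1, ], c(1, 1, 1 + 5), tolerance = 1e-12)
  dg <- spiral_spec("spherical", r = 5, p = 3, theta_start = 1,
                    theta_end = 1)
  expect_warning(trd <- make_spherical_trace(dg), "degenerate")
  expect_equal(nrow(trd$points), 1L)
})

test_that("trace text export round-trips", {
  tr <- make_trace(spiral_spec("cylindrical", r = 4, p = 5, h = 3,
                               n_entries = 2))
  f <- withr::local_tempfile(fileext = ".txt")
  write_trace_txt(tr, f)
  df <- read.table(f, header = TRUE)
  expect_equal(nrow(df), nrow(tr$points))
  expect_equal(df$entry, tr$entry)
  expect_equal(as.matrix(df[, 1:3]), tr$points, tolerance = 1e-8,
               ignore_attr = TRUE)
})
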