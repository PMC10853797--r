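tmpl <- load_bp_template()

test_that("template has full heavy-atom Watson-Crick pairs with PDB v3 naming", {
  expect_setequal(names(tmpl), c("A", "C", "G", "T"))
  backbone <- c("P", "OP1", "OP2", "O5'", "C5'", "C4'", "O4'", "C3'",
                "O3'", "C2'", "C1'")
  for (b in names(tmpl)) {
    d <- tmpl[[b]]
    for (s in c("A", "B"))
      expect_true(all(backbone %in% d$atom[d$strand == s]))
    expect_false(any(grepl("^H", d$atom)))            # heavy atoms only
    expect_false(any(duplicated(paste(d$strand, d$atom))))
  }
  expect_equal(tmpl[["A"]]$resname[tmpl[["A"]]$strand == "B"][1], "DT")
  expect_equal(tmpl[["G"]]$resname[tmpl[["G"]]$strand == "B"][1], "DC")
  # C1'-C1' distance is a template constant near the canonical 1.05 nm
  expect_gt(attr(tmpl, "c1c1"), 1.0)
  expect_lt(attr(tmpl, "c1c1"), 1.1)
  # stacked O3'-P references are covalent bond lengths (~0.16 nm)
  expect_equal(unname(attr(tmpl, "o3p_ref")), c(0.16, 0.16),
               tolerance = 0.02)
})

straight_trace <- function(n = 30, rise = 0.34)
  cbind(0, 0, (seq_len(n) - 1) * rise)

test_that("straight-trace limit reproduces canonical B-DNA", {
  m <- build_duplex(straight_trace(30), twist_per_bp = 36, template = tmpl)
  at <- m$atoms
  # helical repeat: bp 11 superimposes on bp 1 translated by 3.4 nm.
  # chain A resid i is bp i; chain B resid is reversed
  a1 <- at[at$chain == "A" & at$resid == 1, ]
  a11 <- at[at$chain == "A" & at$resid == 11, ]
  a1 <- a1[order(a1$atom), ]; a11 <- a11[order(a11$atom), ]
  expect_lt(max(abs(as.matrix(a11[, c("x", "y", "z")]) -
                    sweep(as.matrix(a1[, c("x", "y", "z")]), 2,
                          c(0, 0, 3.4), "+"))), 1e-6)
  # strain-free: every O3'-P bond at the reference length
  rep <- bond_strain_report(m)
  expect_lt(attr(rep, "max_abs"), 1e-6)
  expect_equal(nrow(rep), 2 * 29)
})

test_that("bp centers coincide with trace points; C1'-C1' is invariant", {
  tr <- make_trace(spiral_spec("cylindrical", r = 6, p = 8, h = 3))
  m <- build_duplex(tr, template = tmpl)
  at <- m$atoms
  n <- nrow(tr$points)
  for (i in c(1L, 7L, n)) {
    ca <- unlist(at[at$strand == "A" & at$resid == i,
                    c("x", "y", "z")][at$atom[at$strand == "A" &
                                              at$resid == i] == "C1'", ])
    cb <- unlist(at[at$strand == "B" & at$resid == n - i + 1, ][
      at[at$strand == "B" & at$resid == n - i + 1, ]$atom == "C1'",
      c("x", "y", "z")])
    expect_equal(sqrt(sum((ca - cb)^2)), attr(tmpl, "c1c1"),
                 tolerance = 1e-9)
    # the pair center (C1' midpoint projected per template frame) tracks
    # the trace: C1' midpoint sits c1c1-independent offset from the trace
    # point only along the pair axes, so distance is bounded by template
    # extent; the exact contract is that the template origin maps to the
    # trace point, checked via the placed origin below
  }
  # placement contract: template origin maps exactly onto each trace point.
  # Verify by rebuilding one bp with a probe atom at the local origin.
  probe <- tmpl
  probe[["A"]] <- rbind(probe[["A"]],
                        data.frame(strand = "A", resname = "DA",
                                   atom = "XORG", element = "X",
                                   x = 0, y = 0, z = 0))
  seqA <- paste(rep("A", n), collapse = "")
  m2 <- build_duplex(tr, sequence = seqA, template = probe)
  org <- m2$atoms[m2$atoms$atom == "XORG", ]
  org <- org[order(org$resid), ]
  expect_lt(max(abs(as.matrix(org[, c("x", "y", "z")]) - tr$points)), 1e-6)
})

test_that("twist accumulates at exactly twist_per_bp on straight traces", {
  m <- build_duplex(straight_trace(12), twist_per_bp = 34.5,
                    template = tmpl)
  at <- m$atoms
  # in-plane angle of the C1'(A) -> C1'(B) direction advances by the twist
  ang <- vapply(1:12, function(i) {
    a <- unlist(at[at$strand == "A" & at$resid == i & at$atom == "C1'",
                   c("x", "y")])
    b <- unlist(at[at$strand == "B" & at$resid == 12 - i + 1 &
                   at$atom == "C1'", c("x", "y")])
    atan2(b[2] - a[2], b[1] - a[1]) * 180 / pi
  }, numeric(1))
  steps <- diff(ang) %% 360
  expect_true(all(abs(steps - 34.5) < 1e-6))
})

test_that("circular traces strain bonds: compressed inside, extended outside", {
  pts <- circle_trace_points(radius = 5, n = 60)
  m <- build_duplex(pts, sequence = paste(rep("A", 60), collapse = ""),
                    template = tmpl)
  rep <- bond_strain_report(m)
  at <- m$atoms
  # classify each bond by the radius of its midpoint vs the trace radius
  mid_r <- vapply(seq_len(nrow(rep)), function(k) {
    a <- at[at$chain == rep$chain[k] & at$resid == rep$resid_from[k] &
            at$atom == "O3'", c("x", "y")]
    b <- at[at$chain == rep$chain[k] & at$resid == rep$resid_to[k] &
            at$atom == "P", c("x", "y")]
    sqrt(sum(((unlist(a) + unlist(b)) / 2)^2))
  }, numeric(1))
  inner <- mid_r < 5 - 0.2
  outer <- mid_r > 5 + 0.2
  expect_gt(sum(inner), 10)
  expect_gt(sum(outer), 10)
  expect_lt(mean(rep$deviation[inner]), 0)   # compressed on the inside
  expect_gt(mean(rep$deviation[outer]), 0)   # extended on the outside
})

test_that("rigid placement matches the independent minimal-rotation oracle", {
  pts <- circle_trace_points(radius = 5, n = 40)
  m <- build_duplex(pts, sequence = paste(rep("A", 40), collapse = ""),
                    template = tmpl)
  orc <- oracle_build_atoms(pts, 36, tmpl, base = "A")
  at <- m$atoms
  at$bp <- ifelse(at$strand == "A", at$resid, 40 - at$resid + 1)
  key <- function(d) paste(d$bp, d$strand, d$atom)
  at <- at[order(key(at)), ]; orc <- orc[order(key(orc)), ]
  expect_equal(key(at), key(orc))
  expect_lt(max(abs(as.matrix(at[, c("x", "y", "z")]) -
                    as.matrix(orc[, c("x", "y", "z")]))), 1e-6)
  # intra-strand P-P distances: inner side shorter than outer side,
  # and the inner/outer mean ratio agrees with the oracle to 1e-6
  pp_ratio <- function(tab) {
    p <- tab[tab$atom == "P" & tab$strand == "A", ]
    p <- p[order(p$bp), ]
    d <- sqrt(rowSums(diff(as.matrix(p[, c("x", "y", "z")]))^2))
    rmid <- sqrt(p$x^2 + p$y^2)
    rmid <- (rmid[-1] + rmid[-length(rmid)]) / 2
    mean(d[rmid < 5]) / mean(d[rmid > 5])
  }
  at$bp <- ifelse(at$strand == "A", at$resid, 40 - at$resid + 1)
  r_impl <- pp_ratio(at)
  r_orc <- pp_ratio(orc)
  expect_lt(r_impl, 1)
  expect_equal(r_impl, r_orc, tolerance = 1e-6)
})

test_that("models transform rigidly with their traces", {
  tr <- make_trace(spiral_spec("cylindrical", r = 5, p = 6, h = 2))
  n <- nrow(tr$points)
  seqs <- paste(rep("G", n), collapse = "")
  m0 <- build_duplex(tr$points, sequence = seqs, template = tmpl)
  R <- oracle_rotmat(c(2, -1, 2) / 3, 1.1)
  shift <- c(3, 4, -5)
  m1 <- build_duplex(sweep(tr$points %*% t(R), 2, shift, "+"),
                     sequence = seqs, template = tmpl)
  x0 <- as.matrix(m0$atoms[, c("x", "y", "z")])
  x1 <- as.matrix(m1$atoms[, c("x", "y", "z")])
  expect_lt(max(abs(x1 - sweep(x0 %*% t(R), 2, shift, "+"))), 1e-6)
})

test_that("degenerate inputs are rejected or degrade gracefully", {
  tr3 <- straight_trace(3)
  expect_error(build_duplex(tr3, sequence = "AC", template = tmpl),
               "length")
  expect_error(build_duplex(tr3, sequence = "AXT", template = tmpl),
               "A, C, G, T")
  expect_error(build_duplex(rbind(c(0, 0, 0), c(0, 0, 0), c(0, 0, 1)),
                            template = tmpl), "coincident")
  # single-bp model: buildable, strain report is empty
  m1 <- build_duplex(matrix(c(0, 0, 0), 1), sequence = "G",
                     template = tmpl)
  rep <- bond_strain_report(m1)
  expect_equal(nrow(rep), 0L)
})

test_that("default sequence is an AT alternation and is flagged", {
  m <- build_duplex(straight_trace(4), template = tmpl)
  expect_true(m$default_sequence)
  expect_equal(m$sequence, "ATAT")
  resA <- m$atoms[m$atoms$strand == "A" & m$atoms$atom == "C1'", ]
  expect_equal(resA$resname[order(resA$resid)], c("DA", "DT", "DA", "DT"))
})

test_that("FASTA sequences load and drive base identities", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">toy", "ACG", "T"), f)
  expect_equal(read_fasta_sequence(f), "ACGT")
  m <- build_duplex(straight_trace(4), sequence = read_fasta_sequence(f),
                    template = tmpl)
  resA <- m$atoms[m$atoms$strand == "A" & m$atoms$atom == "C1'", ]
  expect_equal(resA$resname[order(resA$resid)], c("DA", "DC", "DG", "DT"))
  writeLines("ACGT", f)
  expect_error(read_fasta_sequence(f), "FASTA")
})
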