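# Head-model geometry: landmark frame, curve walks, 10-5 positions,
# measurements, iterative warping, parcel labels.

rot_z <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3L, 3L,
         byrow = TRUE)
}

test_that("landmark-frame alignment is the identity on an aligned mesh and inverts rigid transforms", {
  ph <- get_small_phantom()
  al <- align_to_landmark_frame(ph)
  expect_lt(max(abs(al$scalp$vertices - ph$scalp$vertices)), 1e-9)
  expect_lt(max(abs(al$landmarks - ph$landmarks)), 1e-9)

  # rotate 30 degrees about z (plus a translation) and realign
  R <- rot_z(30)
  moved <- dotstream:::apply_affine(ph, function(p)
    sweep(p %*% t(R), 2L, c(5, -3, 7), `+`))
  back <- align_to_landmark_frame(moved)
  expect_lt(max(abs(back$scalp$vertices - ph$scalp$vertices)), 1e-6)

  # random rigid transform: realignment equalizes preauricular heights
  set.seed(3)
  for (k in 1:3) {
    ax <- dotstream:::unit(stats::rnorm(3))
    th <- stats::runif(1, 0, 2 * pi)
    K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0),
                3L, 3L, byrow = TRUE)
    R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
    moved <- dotstream:::apply_affine(ph, function(p)
      sweep(p %*% t(R), 2L, stats::rnorm(3, 0, 20), `+`))
    out <- align_to_landmark_frame(moved)
    expect_lt(abs(out$landmarks["Ar", 3L] - out$landmarks["Al", 3L]), 1e-6)
    expect_lt(max(abs(out$landmarks["Iz", ])), 1e-6)
    expect_lt(abs(out$landmarks["Nz", 1L]), 1e-6)
    expect_lt(abs(out$landmarks["Nz", 3L]), 1e-6)
  }
})

test_that("alignment errors name a missing landmark", {
  ph <- get_small_phantom()
  ph$landmarks["Cz", ] <- NA_real_
  expect_error(align_to_landmark_frame(ph), "Cz")
})

test_that("curve walk reproduces great-circle arcs and metric properties", {
  sp <- get_sphere_phantom()
  lm <- sp$landmarks
  # pole-to-pole via Cz: half circumference of r = 70 sphere
  cw <- curve_walk(sp$scalp, lm["Nz", ], lm["Iz", ], plane_ref = lm["Cz", ],
                   guide = lm["Cz", ])
  expect_lt(abs(cw$length - pi * 70) / (pi * 70), 0.02)
  # arc length >= straight-line distance, path on the surface
  expect_gte(cw$length, sqrt(sum((lm["Nz", ] - lm["Iz", ])^2)))
  centre <- colMeans(sp$scalp$vertices)
  r <- sqrt(rowSums(sweep(cw$points, 2L, centre, `-`)^2))
  expect_lt(max(abs(r - 70)), 0.7)
  # start == end is a zero-length path
  cw0 <- curve_walk(sp$scalp, lm["Nz", ], lm["Nz", ], plane_ref = lm["Cz", ])
  expect_equal(cw0$length, 0)
})

test_that("curve walk converges to the analytic geodesic under mesh refinement", {
  errs <- vapply(list(c(17L, 24L), c(33L, 48L)), function(res) {
    ph <- make_phantom(phantom_spec(semi_axes = c(70, 70, 70),
                                    n_lat = res[1L], n_lon = res[2L]))
    cw <- curve_walk(ph$scalp, ph$landmarks["Nz", ], ph$landmarks["Iz", ],
                     plane_ref = ph$landmarks["Cz", ],
                     guide = ph$landmarks["Cz", ])
    abs(cw$length - pi * 70) / (pi * 70)
  }, numeric(1))
  expect_lt(errs[2L], errs[1L])
})

test_that("10-5 positions: midpoint at Cz, left-right mirror symmetry, FPz at 10%", {
  sp <- get_sphere_phantom()
  pos <- compute_10_5_positions(sp)
  edge <- 2 * pi * 70 / 48  # longitude step, an upper bound on edge length
  expect_lt(sqrt(sum((pos$sagittal["Cz", ] - sp$landmarks["Cz", ])^2)), edge)
  # homologous coronal points mirror in x
  mirrored <- pos$coronal[nrow(pos$coronal):1, ] * matrix(c(-1, 1, 1),
    nrow(pos$coronal), 3L, byrow = TRUE)
  expect_lt(max(abs(mirrored - pos$coronal)), 1.0)
  # FPz is the 10% point of the Nz -> Iz curve
  sag <- pos$sagittal_curve
  s_fpz <- dotstream:::nearest_on_polyline(sag$points, pos$sagittal["FPz", ])$s
  expect_lt(abs(s_fpz / sag$length - 0.10), 0.005)
  # CCPz at 55%
  s_cc <- dotstream:::nearest_on_polyline(sag$points, pos$sagittal["CCPz", ])$s
  expect_lt(abs(s_cc / sag$length - 0.55), 0.005)
})

test_that("head measurements match analytic values and scale with similarity", {
  sp <- get_sphere_phantom()
  m <- measure_head(sp)
  expect_lt(abs(m$circumference - 2 * pi * 7) / (2 * pi * 7), 0.02)
  expect_lt(abs(m$nz_cz_iz - m$circumference / 2) / (m$circumference / 2),
            0.02)
  doubled <- dotstream:::apply_affine(sp, function(p) 2 * p)
  m2 <- measure_head(doubled)
  expect_lt(abs(m2$circumference / m$circumference - 2), 1e-6)
  expect_lt(abs(m2$ar_cz_al / m$ar_cz_al - 2), 1e-6)
  expect_lt(abs(m2$nz_cz_iz / m$nz_cz_iz - 2), 1e-6)
})

test_that("warping: fixed point, similarity solution, anisotropic convergence", {
  ph <- get_small_phantom()
  m <- measure_head(ph)

  w <- warp_head_model(ph, m)
  expect_true(w$converged)
  expect_lt(max(abs(w$factors - 1)), 1e-9)
  expect_lt(max(abs(w$mesh$vol_nodes - ph$vol_nodes)), 1e-6)

  t2 <- head_measurements(2 * m$circumference, 2 * m$ar_cz_al,
                          2 * m$nz_cz_iz)
  w2 <- warp_head_model(ph, t2)
  expect_lt(max(abs(w2$mesh$scalp$vertices - 2 * ph$scalp$vertices)), 1e-3)

  t3 <- head_measurements(1.05 * m$circumference, 0.97 * m$ar_cz_al,
                          m$nz_cz_iz)
  w3 <- warp_head_model(ph, t3)
  m3 <- measure_head(w3$mesh)
  expect_lt(10 * abs(m3$circumference - t3$circumference), 3)
  expect_lt(10 * abs(m3$ar_cz_al - t3$ar_cz_al), 6)
  expect_lt(10 * abs(m3$nz_cz_iz - t3$nz_cz_iz), 6)

  # re-warping a converged mesh to the same target moves nothing
  w4 <- warp_head_model(w3$mesh, t3)
  expect_lt(max(abs(w4$mesh$vol_nodes - w3$mesh$vol_nodes)), 1e-6)
})

test_that("warping with absent Nz-Cz-Iz uses circumference and Ar-Cz-Al only", {
  ph <- get_small_phantom()
  m <- measure_head(ph)
  tgt <- head_measurements(0.95 * m$circumference, 1.02 * m$ar_cz_al)
  w <- warp_head_model(ph, tgt)
  mm <- measure_head(w$mesh)
  expect_lt(10 * abs(mm$circumference - tgt$circumference), 3)
  expect_lt(10 * abs(mm$ar_cz_al - tgt$ar_cz_al), 6)
  expect_false("nz_cz_iz" %in% w$log$measurement)
})

test_that("warping preserves topology, correspondence and rejects bad targets", {
  ph <- get_small_phantom()
  m <- measure_head(ph)
  t3 <- head_measurements(1.04 * m$circumference, m$ar_cz_al, m$nz_cz_iz)
  w <- warp_head_model(ph, t3)
  expect_identical(w$mesh$tets, ph$tets)
  expect_identical(w$mesh$gm$faces, ph$gm$faces)
  expect_identical(nrow(w$mesh$vol_nodes), nrow(ph$vol_nodes))
  expect_error(warp_head_model(ph, head_measurements(44)),
               NA)  # circumference-only target is legal
  expect_error(head_measurements(-40), "positive")
  # unreachable target within the iteration cap
  crazy <- head_measurements(m$circumference, 5 * m$ar_cz_al, m$nz_cz_iz)
  expect_error(warp_head_model(ph, crazy,
                               warp_tolerances(max_iterations = 4L)),
               "did not converge")
})

test_that("parcel labels ride with nodes through warps and are near-uniform for equal-area layouts", {
  ph4 <- make_phantom(phantom_spec(n_lat = 21L, n_lon = 32L, grid_mm = 8,
                                   n_parcels = 4L))
  expect_identical(parcel_of_node(ph4, 42L), ph4$parcels[42L])
  m <- measure_head(ph4)
  w <- warp_head_model(ph4, head_measurements(1.05 * m$circumference,
                                              m$ar_cz_al, m$nz_cz_iz))
  expect_identical(parcel_of_node(w$mesh, 42L), parcel_of_node(ph4, 42L))
  expect_error(parcel_of_node(ph4, nrow(ph4$gm$vertices) + 1L),
               "out of range")
  h <- table(ph4$parcels)
  expect_equal(length(h), 4L)
  expect_lt(max(abs(h / mean(h) - 1)), 0.10)
})
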