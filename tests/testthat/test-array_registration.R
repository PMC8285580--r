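# Array specification, placement rules, scalp axes, reference registration,
# full-array layout and channel midpoints.

test_that("array specification matches the bilateral infant array", {
  arr <- array_spec()
  for (h in c("left", "right")) {
    opt <- arr$optodes[arr$optodes$hemisphere == h, ]
    expect_equal(sum(opt$role == "source"), 6L)
    expect_equal(sum(opt$role == "detector"), 7L)
    expect_equal(sum(arr$channels$hemisphere == h), 17L)
  }
  expect_equal(nrow(arr$channels), 34L)
  # every channel pairs a source with a detector
  role <- stats::setNames(arr$optodes$role, arr$optodes$id)
  expect_true(all(role[arr$channels$source] == "source"))
  expect_true(all(role[arr$channels$detector] == "detector"))
})

test_that("placement rules implement the printed thresholds and boundary semantics", {
  keep <- apply_placement_rules(placement_measurement("left", 1.0, 0.5))
  expect_equal(keep$action, "keep")
  shift <- apply_placement_rules(placement_measurement("left", 1.6, 0.0))
  expect_equal(shift$action, "shift_backward")
  expect_equal(abs(shift$shift_mm), 20)
  excl <- apply_placement_rules(placement_measurement("left", 0.0, 1.7))
  expect_equal(excl$action, "exclude")
  # 1.6 is not > 1.6: shifted, not excluded
  edge <- apply_placement_rules(placement_measurement("left", -1.6, 1.6))
  expect_equal(edge$action, "shift_forward")
  expect_equal(edge$shift_mm, 20)
  # superior-only rule keeps a large inferior displacement
  inf_disp <- placement_measurement("left", 0, -1.8)
  expect_equal(apply_placement_rules(inf_disp)$action, "exclude")
  expect_equal(apply_placement_rules(inf_disp, y_rule = "superior")$action,
               "keep")
})

test_that("scalp axes: endpoints, symmetry, and quarter-circumference scale", {
  sp <- get_sphere_phantom()
  pos <- compute_10_5_positions(sp)
  axr <- define_scalp_axes(sp, "right", pos)
  axl <- define_scalp_axes(sp, "left", pos)
  # x-curve endpoints are the Iz and FPz scalp points
  expect_lt(sqrt(sum((axr$x_curve$points[1L, ] - sp$landmarks["Iz", ])^2)), 1)
  n <- nrow(axr$x_curve$points)
  expect_lt(sqrt(sum((axr$x_curve$points[n, ] - pos$sagittal["FPz", ])^2)), 1)
  # left and right x-curves mirror in x on the symmetric phantom
  expect_lt(abs(axr$x_curve$length - axl$x_curve$length), 1)
  # y-curve (preauricular to CCPz) is near a quarter circumference
  quarter <- 2 * pi * 70 / 4
  expect_lt(abs(axr$y_curve$length - quarter) / quarter, 0.06)
})

test_that("reference registration: origin, arc displacement, additivity", {
  sp <- get_sphere_phantom()
  pos <- compute_10_5_positions(sp)
  ax <- define_scalp_axes(sp, "right", pos)
  r0 <- register_reference_optode(sp, ax,
                                  placement_measurement("right", 0, 0))
  expect_lt(sqrt(sum((r0$point - sp$landmarks["Ar", ])^2)), 0.5)
  r1 <- register_reference_optode(sp, ax,
                                  placement_measurement("right", 1, 0))
  d <- sqrt(sum((r1$point - r0$point)^2))
  expect_lt(abs(d - 10), 0.5)  # chord of a 10 mm arc on r = 70
  up <- register_reference_optode(sp, ax,
                                  placement_measurement("right", 0, 1))
  dn <- register_reference_optode(sp, ax,
                                  placement_measurement("right", 0, -1))
  sep <- sqrt(sum((up$point - dn$point)^2))
  expect_lt(abs(sep - 20), 0.6)
  expect_error(register_reference_optode(sp, ax,
    placement_measurement("right", 45, 0)), "curve domain")
})

test_that("array layout: 20 mm arc spacing, chords below arcs, scalp adherence, size invariance", {
  ph <- get_phantom()
  pos <- compute_10_5_positions(ph)
  arr <- array_spec()
  ax <- define_scalp_axes(ph, "right", pos)
  ref <- register_reference_optode(ph, ax,
                                   placement_measurement("right", 0, 0))
  lay <- layout_array(ph, ax, ref, arr, "right")
  opt <- arr$optodes[arr$optodes$hemisphere == "right", ]
  lower <- opt$id[opt$row == "lower"][order(opt$col[opt$row == "lower"])]
  chords <- vapply(seq_len(6), function(i)
    sqrt(sum((lay[lower[i], ] - lay[lower[i + 1L], ])^2)), numeric(1))
  expect_true(all(abs(chords - 20) < 1))
  expect_true(all(chords <= 20 + 1e-9))  # chord never exceeds arc
  # all optodes on the scalp surface
  centre <- colMeans(ph$scalp$vertices)
  for (id in rownames(lay)) {
    p <- dotstream:::nearest_on_polyline(
      curve_walk(ph$scalp, lay[id, ], ph$landmarks["Cz", ],
                 plane_ref = centre)$points, lay[id, ])
    expect_lt(p$dist, 1e-6)
  }
  # doubling the head leaves arc separations at 20 mm
  m <- measure_head(ph)
  big <- warp_head_model(ph, head_measurements(2 * m$circumference,
                                               2 * m$ar_cz_al,
                                               2 * m$nz_cz_iz))$mesh
  pos2 <- compute_10_5_positions(big)
  ax2 <- define_scalp_axes(big, "right", pos2)
  ref2 <- register_reference_optode(big, ax2,
                                    placement_measurement("right", 0, 0))
  lay2 <- layout_array(big, ax2, ref2, arr, "right")
  chords2 <- vapply(seq_len(6), function(i)
    sqrt(sum((lay2[lower[i], ] - lay2[lower[i + 1L], ])^2)), numeric(1))
  expect_true(all(abs(chords2 - 20) < 1))
})

test_that("mirrored placements on a symmetric phantom give mirrored layouts", {
  sp <- get_sphere_phantom()
  pos <- compute_10_5_positions(sp)
  arr <- array_spec()
  axr <- define_scalp_axes(sp, "right", pos)
  axl <- define_scalp_axes(sp, "left", pos)
  pl <- placement_measurement("right", 0.8, 0.5)
  pll <- placement_measurement("left", 0.8, 0.5)
  lr <- layout_array(sp, axr,
                     register_reference_optode(sp, axr, pl), arr, "right")
  ll <- layout_array(sp, axl,
                     register_reference_optode(sp, axl, pll), arr, "left")
  # strip hemisphere prefix to pair optodes, mirror x
  base <- sub("^R", "", rownames(lr))
  mirrored <- lr[, ] * matrix(c(-1, 1, 1), nrow(lr), 3L, byrow = TRUE)
  rownames(mirrored) <- base
  ll_base <- ll
  rownames(ll_base) <- sub("^L", "", rownames(ll))
  expect_lt(max(abs(mirrored[rownames(ll_base), ] - ll_base)), 1.5)
})

test_that("channel midpoints are equidistant from their optodes and on the great circle", {
  sp <- get_sphere_phantom()
  pos <- compute_10_5_positions(sp)
  arr <- array_spec()
  axr <- define_scalp_axes(sp, "right", pos)
  axl <- define_scalp_axes(sp, "left", pos)
  lay <- rbind(
    layout_array(sp, axl, register_reference_optode(
      sp, axl, placement_measurement("left", 0, 0)), arr, "left"),
    layout_array(sp, axr, register_reference_optode(
      sp, axr, placement_measurement("right", 0, 0)), arr, "right"))
  mids <- channel_scalp_midpoints(sp, lay, arr)
  centre <- colMeans(sp$scalp$vertices)
  for (k in seq_len(5)) {
    s <- lay[arr$channels$source[k], ]
    d <- lay[arr$channels$detector[k], ]
    ds <- sqrt(sum((mids[k, ] - s)^2))
    dd <- sqrt(sum((mids[k, ] - d)^2))
    expect_lt(abs(ds - dd), 1)
    # on the sphere the midpoint stays on the great circle through the pair
    n <- dotstream:::cross3(s - centre, d - centre)
    expect_lt(abs(sum((mids[k, ] - centre) * dotstream:::unit(n))), 1.5)
  }
})

test_that("group-mean placements equal a virtual mean subject's registration", {
  ph <- get_phantom()
  pos <- compute_10_5_positions(ph)
  ax <- define_scalp_axes(ph, "right", pos)
  xs <- c(0.4, -0.2, 0.7); ys <- c(0.1, 0.5, -0.3)
  virt <- register_reference_optode(ph, ax,
    placement_measurement("right", mean(xs), mean(ys)))
  direct <- register_reference_optode(ph, ax,
    placement_measurement("right", mean(xs), mean(ys)))
  expect_equal(virt$point, direct$point, tolerance = 1e-12)
  expect_equal(virt$u, 10 * mean(xs))
})
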