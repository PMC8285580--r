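# Analytic diffusion sensitivity, grey-matter masks, Tikhonov
# reconstruction and chromophore image formation.

get_sensitivity_fixture <- function() fx_get("sens", function() {
  ph <- get_phantom()
  pos <- compute_10_5_positions(ph)
  arr <- array_spec()
  lay <- list()
  for (h in c("left", "right")) {
    ax <- define_scalp_axes(ph, h, pos)
    ref <- register_reference_optode(ph, ax, placement_measurement(h, 0, 0))
    lay[[h]] <- layout_array(ph, ax, ref, arr, h)
  }
  opt <- rbind(lay$left, lay$right)
  list(phantom = ph, array = arr, optodes = opt,
       J = compute_sensitivity(ph, opt, arr$channels))
})

test_that("sensitivity rows are non-negative and reciprocal in source/detector", {
  fx <- get_sensitivity_fixture()
  expect_true(all(fx$J$J[["780"]] >= 0))
  expect_true(all(fx$J$J[["850"]] >= 0))
  ch <- fx$array$channels[1L, ]
  swapped <- ch
  swapped$source <- ch$detector; swapped$detector <- ch$source
  Ja <- compute_sensitivity(fx$phantom, fx$optodes, ch)
  Jb <- compute_sensitivity(fx$phantom, fx$optodes, swapped)
  expect_lt(max(abs(Ja$J[["780"]] - Jb$J[["780"]])), 1e-9)
})

test_that("sensitivity concentrates under the channel and decays off-axis", {
  fx <- get_sensitivity_fixture()
  ph <- fx$phantom
  k <- 1L
  ch <- fx$array$channels[k, ]
  s <- fx$optodes[ch$source, ]; d <- fx$optodes[ch$detector, ]
  mid <- (s + d) / 2
  centre <- colMeans(ph$scalp$vertices)
  inward <- dotstream:::unit(centre - mid)
  target <- mid + 10 * inward  # roughly half the separation in depth
  nodes <- ph$vol_nodes
  row <- fx$J$J[["780"]][k, ] / pmax(dotstream:::node_volumes(ph), 1e-9)
  d_target <- sqrt(rowSums(sweep(nodes, 2L, target, `-`)^2))
  near <- which.min(d_target)
  axis_dist <- sqrt(rowSums(sweep(nodes, 2L, mid, `-`)^2))
  far <- which(axis_dist >= 30)
  expect_gt(row[near], max(row[far]))
})

test_that("centre of mass: uniform row gives the centroid; translation invariance in an infinite medium", {
  coords <- matrix(stats::runif(300), 100L, 3L)
  u <- rep(2.5, 100L)
  expect_equal(sensitivity_com(u, coords), colMeans(coords))
  expect_error(sensitivity_com(rep(0, 100L), coords), "all-zero")

  # infinite-medium model: translating optodes translates the CoM
  ph <- get_small_phantom()
  arr <- array_spec()
  ch <- arr$channels[1L, ]
  opt <- matrix(c(30, 60, 40, 30, 80, 40), 2L, 3L, byrow = TRUE)
  rownames(opt) <- c(ch$source, ch$detector)
  J1 <- compute_sensitivity(ph, opt, ch, boundary = "infinite")
  shift <- c(4, -6, 2)
  ph2 <- dotstream:::apply_affine(ph, function(p)
    sweep(p, 2L, shift, `+`))
  opt2 <- sweep(opt, 2L, shift, `+`)
  rownames(opt2) <- rownames(opt)
  J2 <- compute_sensitivity(ph2, opt2, ch, boundary = "infinite")
  c1 <- sensitivity_com(J1$J[["780"]][1L, ], ph$vol_nodes)
  c2 <- sensitivity_com(J2$J[["780"]][1L, ], ph2$vol_nodes)
  expect_lt(max(abs((c2 - c1) - shift)), 1e-6)
})

test_that("individual mask thresholds at 1% of maximum, boundary exact", {
  ph <- get_small_phantom()
  s2v <- dotstream:::gm_surface_to_volume(ph)
  n_surf <- nrow(ph$gm$vertices)
  # synthetic J hitting chosen volume nodes
  vols <- sort(unique(s2v))
  J <- list(J = list(`780` = matrix(0, 1L, nrow(ph$vol_nodes))),
            wavelengths = c(780, 850))
  class(J) <- "sensitivity_matrix"
  J$J[["780"]][1L, s2v[1L]] <- 1
  J$J[["780"]][1L, s2v[2L]] <- 0.009
  J$J[["780"]][1L, s2v[3L]] <- 0.011
  m <- individual_gm_mask(J, ph, surf2vol = s2v)
  expect_true(m[1L])
  expect_false(m[2L])
  expect_true(m[3L])
  # uniform sensitivity includes every gm node
  J$J[["780"]][1L, ] <- 1
  expect_true(all(individual_gm_mask(J, ph, surf2vol = s2v)))
  # no channels -> empty mask
  J$J[["780"]] <- J$J[["780"]][0L, , drop = FALSE]
  expect_false(any(individual_gm_mask(J, ph, surf2vol = s2v)))
  # raising the threshold never adds nodes
  J2 <- list(J = list(`780` = matrix(stats::runif(nrow(ph$vol_nodes)), 1L)),
             wavelengths = c(780, 850))
  class(J2) <- "sensitivity_matrix"
  m1 <- individual_gm_mask(J2, ph, threshold = 0.01, surf2vol = s2v)
  m2 <- individual_gm_mask(J2, ph, threshold = 0.05, surf2vol = s2v)
  expect_true(all(which(m2) %in% which(m1)))
})

test_that("group mask keeps nodes present in at least three quarters of masks", {
  m <- list(c(TRUE, TRUE, FALSE), c(TRUE, FALSE, FALSE),
            c(TRUE, TRUE, FALSE), c(FALSE, TRUE, FALSE))
  g <- group_gm_mask(m)
  expect_identical(g, c(TRUE, TRUE, FALSE))  # 3/4 kept, 2/4 dropped
  expect_identical(group_gm_mask(list(c(TRUE, FALSE))), c(TRUE, FALSE))
  # 30 of 40 is exactly 0.75 and inclusive
  m40 <- c(lapply(1:30, function(i) TRUE), lapply(1:10, function(i) FALSE))
  expect_true(group_gm_mask(m40))
})

test_that("Tikhonov reconstruction matches an independent SVD oracle and is linear", {
  set.seed(9)
  J <- matrix(stats::rnorm(10 * 50), 10L, 50L)
  y1 <- stats::rnorm(10); y2 <- stats::rnorm(10)
  lam <- 0.1
  x <- reconstruct(J, cbind(y1), lam)
  # oracle: explicit SVD solve of x = J'(JJ' + a I)^-1 y
  sv <- svd(J)
  a <- lam^2 * max(diag(tcrossprod(J)))
  xo <- sv$v %*% ((sv$d / (sv$d^2 + a)) * crossprod(sv$u, y1))
  expect_lt(max(abs(x - xo)) / max(abs(xo)), 1e-8)
  # zero data give a zero image
  expect_equal(reconstruct(J, matrix(0, 10L, 3L), lam),
               matrix(0, 50L, 3L))
  # linearity
  xa <- reconstruct(J, cbind(y1), lam)
  xb <- reconstruct(J, cbind(y2), lam)
  xab <- reconstruct(J, cbind(2 * y1 - 3 * y2), lam)
  expect_lt(max(abs(xab - (2 * xa - 3 * xb))), 1e-9)
  expect_error(reconstruct(J[0L, ], matrix(0, 0L, 1L)), "empty")
})

test_that("the reconstruction operator is a single factorization applied per frame", {
  set.seed(10)
  J <- matrix(stats::rnorm(8 * 30), 8L, 30L)
  R <- recon_operator(J, 0.1)
  Y <- matrix(stats::rnorm(8 * 221), 8L, 221L)
  expect_equal(reconstruct(J, Y, 0.1), R %*% Y)
})

test_that("absorption-to-haemoglobin conversion: pure chromophores, round trip, spectral sign", {
  E <- extinction_matrix(units = "ln_uM_mm")
  hbo <- matrix(stats::rnorm(20), 5L)
  hbr <- matrix(stats::rnorm(20), 5L)
  mua7 <- E[1L, 1L] * hbo + E[1L, 2L] * hbr
  mua8 <- E[2L, 1L] * hbo + E[2L, 2L] * hbr
  back <- mua_to_hb(mua7, mua8, E)
  expect_lt(max(abs(back$hbo - hbo)), 1e-9)
  expect_lt(max(abs(back$hbr - hbr)), 1e-9)
  # pure HbO change gives zero recovered HbR
  pure <- mua_to_hb(E[1L, 1L] * hbo, E[2L, 1L] * hbo, E)
  expect_lt(max(abs(pure$hbr)), 1e-9)
  # a positive HbO increase raises mua more at 850 than at 780 nm
  expect_gt(E[2L, 1L], E[1L, 1L])
})

test_that("window averaging is the inclusive temporal mean", {
  time <- block_time_axis()
  m <- matrix(3.5, 4L, 221L)
  expect_equal(window_average_image(m, c(12, 16), time), rep(3.5, 4L))
  idx <- which(time >= 12 & time <= 16)
  expect_length(idx, 41L)
  ramp <- matrix(rep(2 * time, each = 2L), 2L, 221L, byrow = FALSE)
  expect_equal(window_average_image(ramp, c(12, 16), time), rep(2 * 14, 2L))
  expect_error(window_average_image(m, c(30, 40), time), "window")
})
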