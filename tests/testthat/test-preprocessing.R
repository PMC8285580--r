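# Channel pruning, optical density, motion correction, filtering, DPF,
# Beer-Lambert conversions and block averaging.

make_test_scan <- function(n_ch = 4L, dur_s = 300, fs = 10,
                           cardiac_amp = 4e-3, white = 1e-3, seed = 5) {
  set.seed(seed)
  t <- seq(0, dur_s - 1 / fs, by = 1 / fs)
  n_t <- length(t)
  inten <- array(NA_real_, dim = c(n_ch, 2L, n_t))
  card <- sin(2 * pi * 2.0 * t)
  for (k in seq_len(n_ch))
    for (w in 1:2)
      inten[k, w, ] <- exp(-(cardiac_amp * card +
                             stats::rnorm(n_t, 0, white)))
  channels <- data.frame(id = paste0("ch", seq_len(n_ch)),
                         source = "S1", detector = "D1",
                         hemisphere = "left", separation_cm = 2)
  events <- data.frame(onset = c(30, 90, 150, 210),
                       condition = c("V", "V", "V", "NV"))
  raw_scan(inten, fs = fs, channels = channels, events = events,
           looking = rep(1, 4L), subject = list(age_months = 8))
}

test_that("pruning keeps cardiac-coupled channels and drops dead or decoupled ones", {
  raw <- make_test_scan()
  # channel 2: independent noise only (decoupled); channel 3: dead
  set.seed(6)
  n_t <- dim(raw$intensity)[3L]
  raw$intensity[2L, 1L, ] <- exp(stats::rnorm(n_t, 0, 4e-3))
  raw$intensity[2L, 2L, ] <- exp(stats::rnorm(n_t, 0, 4e-3))
  raw$intensity[3L, , ] <- raw$intensity[3L, , ] * 1e-4
  mask <- prune_channels(raw)
  expect_true(mask[1L])
  expect_false(mask[2L])   # index near 0 for independent series
  expect_false(mask[3L])   # below the intensity floor despite cardiac
  expect_true(mask[4L])
})

test_that("independent white-noise wavelengths give a near-zero quality index", {
  set.seed(7)
  n <- 3000
  idx <- dotstream:::cardiac_quality_index(exp(stats::rnorm(n, 0, 2e-3)),
                                           exp(stats::rnorm(n, 0, 2e-3)), 10)
  expect_lt(abs(idx), 0.1)
})

test_that("dataset validity follows the 40% rule at its boundary", {
  expect_false(dataset_valid(c(rep(FALSE, 14L), rep(TRUE, 20L))))  # 41.2%
  expect_true(dataset_valid(c(rep(FALSE, 13L), rep(TRUE, 21L))))   # 38.2%
  expect_true(dataset_valid(rep(TRUE, 34L)))
})

test_that("optical density: zero for constant input, ln 2 for halving, scale invariant", {
  x <- rep(4, 100)
  expect_equal(intensity_to_od(x), rep(0, 100))
  n <- 1000
  y <- rep(1, n); y[500] <- NA
  y[500] <- mean(y, na.rm = TRUE) / 2
  # reference is the temporal mean; adjust analytically
  ref <- mean(y)
  od <- intensity_to_od(y)
  expect_equal(od[500], -log(y[500] / ref))
  set.seed(1)
  z <- exp(stats::rnorm(200, 0, 0.1))
  expect_equal(intensity_to_od(z), intensity_to_od(7.3 * z))
  expect_error(intensity_to_od(c(1, 0, 2)), "non-positive")
})

test_that("motion correction passes clean signals, removes spikes, preserves zero", {
  fs <- 10
  t <- seq(0, 600, by = 1 / fs)
  sig <- 0.01 * sin(2 * pi * 0.04 * t)
  out <- correct_motion(sig, fs)
  expect_lt(sqrt(mean((out - sig)^2)) / sqrt(mean(sig^2)), 0.05)

  spiked <- sig
  spiked[3000:3004] <- spiked[3000:3004] + 0.1  # 10x amplitude transient
  fixed <- correct_motion(spiked, fs)
  rmse_raw <- sqrt(mean((spiked - sig)^2))
  rmse_fix <- sqrt(mean((fixed - sig)^2))
  expect_lt(rmse_fix, 0.5 * rmse_raw)

  expect_equal(correct_motion(rep(0, 1000), fs), rep(0, 1000))
})

test_that("residual-trial flagging excludes exactly the overlapping trials", {
  fs <- 10
  n_t <- 3000
  od <- array(0, dim = c(1L, 2L, n_t))
  events <- data.frame(onset = c(50, 120, 190),
                       condition = rep("V", 3L))
  expect_identical(flag_residual_trials(od, events, fs)[[1L]], integer(0))
  # artifact inside trial 2's block window
  od2 <- od
  od2[1L, 1L, 1250:1255] <- 0.5
  excl <- flag_residual_trials(od2, events, fs)
  expect_identical(excl[[1L]], 2L)
  # artifact between trials 1 and 2 but within the 4 s padding of both:
  # trial 1 block ends at 70 s, trial 2 starts at 118 s; an artifact at
  # 73 s is inside trial 1's padded window only, one at 115.5 s inside
  # trial 2's only; one spanning 73..115.5 s would hit neither unless wide.
  od3 <- od
  od3[1L, 1L, 735:740] <- 0.5   # ~73.5 s, within 4 s of trial 1's end
  excl3 <- flag_residual_trials(od3, events, fs)
  expect_identical(excl3[[1L]], 1L)
  # construct one artifact window overlapping two consecutive padded blocks
  events2 <- data.frame(onset = c(50, 77), condition = c("V", "V"))
  od4 <- od
  od4[1L, 1L, 725:730] <- 0.5   # 72.5 s: < 70+4 and > 75-4
  excl4 <- flag_residual_trials(od4, events2, fs)
  expect_identical(excl4[[1L]], c(1L, 2L))
})

test_that("band-pass rejects DC, passes 0.04 Hz, attenuates cardiac frequencies", {
  fs <- 10
  t <- seq(0, 600, by = 1 / fs)
  expect_lt(max(abs(bandpass(rep(5, 3000), fs))), 5e-6)
  x <- sin(2 * pi * 0.04 * t)
  gain <- stats::sd(bandpass(x, fs)[2000:4000]) / stats::sd(x[2000:4000])
  expect_gt(gain, 0.7)
  expect_lte(gain, 1.0 + 1e-6)
  x2 <- sin(2 * pi * 1.2 * t)
  atten_db <- 20 * log10(stats::sd(x2) / stats::sd(bandpass(x2, fs)))
  expect_gt(atten_db, 20)
})

test_that("DPF decreases with wavelength, increases with age, is deterministic", {
  expect_gt(dpf(780, 0.5), dpf(850, 0.5))
  ages <- c(0.25, 0.5, 1, 2, 10)
  v <- dpf(780, ages)
  expect_true(all(diff(v) > 0))
  expect_identical(dpf(800, 1), dpf(800, 1))
  expect_error(dpf(600, 1), "wavelength")
  expect_error(dpf(780, -1), "age")
})

test_that("Beer-Lambert round trip, zero map, and separation linearity", {
  E <- extinction_matrix()
  d <- dpf(c(780, 850), 0.6)
  z <- matrix(0, 2L, 50L)
  expect_equal(unname(mbll(z, d, 2, E)), z)
  set.seed(2)
  hb <- rbind(stats::rnorm(100), stats::rnorm(100))
  od <- hb_to_od(hb, d, 2, E)
  rec <- mbll(od, d, 2, E)
  expect_lt(max(abs(rec - hb)) / max(abs(hb)), 1e-9)
  # doubling separation halves recovered concentrations for fixed OD
  c1 <- mbll(od, d, 2, E)
  c2 <- mbll(od, d, 4, E)
  expect_equal(unname(c2), unname(c1) / 2, tolerance = 1e-12)
})

test_that("block window arithmetic gives 221 frames spanning 22 s", {
  tt <- block_time_axis()
  expect_length(tt, 221L)
  expect_equal(tt[1L], -2)
  expect_equal(tt[221L], 20)
  expect_equal(diff(range(tt)), 22)
})

test_that("trial selection honours the looking threshold and the three-trial minimum", {
  fs <- 10
  n_t <- 2200
  hb <- array(0, dim = c(1L, 2L, n_t))
  tt <- (seq_len(n_t) - 1L) / fs
  events <- data.frame(onset = c(30, 60, 90, 120, 150),
                       condition = rep("V", 5L))
  for (on in events$onset) {
    m <- tt >= on & tt < on + 20
    hb[1L, 1L, m] <- 1
  }
  look <- c(0.59, 0.60, 1, 1, 1)
  blk <- select_trials_and_average(hb, events, look, fs)
  expect_equal(blk$n_trials[1L], 4L)   # 0.59 excluded, 0.60 included
  expect_true(blk$valid)
  blk2 <- select_trials_and_average(hb, events, c(0.1, 0.2, 0.3, 1, 1), fs)
  expect_equal(blk2$n_trials[1L], 2L)
  expect_false(blk2$valid)
  # averaging identical trials reproduces a single trial
  one <- select_trials_and_average(hb, events[3L, , drop = FALSE], 1, fs,
                                   min_trials = 1L)
  expect_equal(blk$hbo[1L, ], one$hbo[1L, ])
})

test_that("end-to-end intensity scaling leaves the block average unchanged", {
  raw <- make_test_scan()
  p1 <- preprocess_scan(raw)
  raw2 <- raw
  raw2$intensity <- raw2$intensity * 37
  p2 <- preprocess_scan(raw2)
  # the narrow-band zero-phase filter amplifies last-bit rounding, so the
  # mathematically exact invariance holds only to ~1e-6 relative
  expect_equal(p1$block$hbo, p2$block$hbo, tolerance = 1e-5)
  expect_identical(p1$channel_mask, p2$channel_mask)
})

test_that("block average converts back to optical density and inverts exactly", {
  raw <- make_test_scan()
  p <- preprocess_scan(raw)
  od <- block_to_od(p$block, raw$channels, 8 / 12)
  E <- extinction_matrix(units = "ln_uM_cm")
  d <- dpf(c(780, 850), 8 / 12)
  for (k in which(p$channel_mask)) {
    back <- mbll(od[k, , ], d, raw$channels$separation_cm[k], E)
    expect_lt(max(abs(back[1L, ] - p$block$hbo[k, ])), 1e-9)
    expect_lt(max(abs(back[2L, ] - p$block$hbr[k, ])), 1e-9)
  }
})
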