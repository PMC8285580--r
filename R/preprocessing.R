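# Channel-level preprocessing: pruning by intensity and cardiac coupling,
# optical density conversion, motion correction (spline + wavelet),
# residual-trial flagging, band-pass filtering, the modified Beer-Lambert
# law in both directions, and per-condition block averaging.

#' Raw dual-wavelength scan container
#'
#' @param intensity array channel x wavelength x time (arbitrary units)
#' @param wavelengths length-2 numeric (nm), default c(780, 850)
#' @param fs sampling rate (Hz); the acquisition system runs at 10 Hz
#' @param channels data frame with id, source, detector, hemisphere,
#'   separation_cm
#' @param events data frame with onset (s), condition (VS/V/NV/baseline)
#' @param looking per-trial looking-time fraction in [0, 1]
#' @param subject list of subject metadata
#' @export
raw_scan <- function(intensity, wavelengths = c(780, 850), fs = 10,
                     channels, events, looking, subject = list()) {
  stopifnot(length(dim(intensity)) == 3L, dim(intensity)[2L] == 2L,
            dim(intensity)[1L] == nrow(channels),
            nrow(events) == length(looking))
  if (any(intensity < 0)) stop("intensities must be non-negative")
  structure(list(intensity = intensity, wavelengths = wavelengths, fs = fs,
                 channels = channels, events = events, looking = looking,
                 subject = subject),
            class = "raw_scan")
}

#' @export
print.raw_scan <- function(x, ...) {
  cat(sprintf("raw_scan: %d channels x %d wavelengths x %d samples @ %g Hz; %d trials\n",
              dim(x$intensity)[1L], dim(x$intensity)[2L],
              dim(x$intensity)[3L], x$fs, nrow(x$events)))
  invisible(x)
}

butter_filtfilt <- function(x, fs, band, type, order = 3L) {
  w <- band / (fs / 2)
  flt <- signal::butter(order, w, type = type)
  # demean first: filtfilt start-up transients from a DC offset would
  # otherwise dominate (and spuriously correlate) short segments
  as.numeric(signal::filtfilt(flt, x - mean(x)))
}

#' Cardiac-coupling quality index of one channel
#'
#' Zero-lag correlation between the two wavelengths after band-passing to
#' the cardiac band (edge samples trimmed); a well-coupled optode pair
#' shares the pulse waveform across wavelengths.
#' @keywords internal
cardiac_quality_index <- function(x1, x2, fs, band = c(0.5, 2.5)) {
  b1 <- butter_filtfilt(x1, fs, band, "pass")
  b2 <- butter_filtfilt(x2, fs, band, "pass")
  trim <- max(1L, round(2 * fs))
  keep <- seq.int(trim + 1L, length(b1) - trim)
  b1 <- b1[keep]; b2 <- b2[keep]
  if (stats::sd(b1) < 1e-15 || stats::sd(b2) < 1e-15) return(0)
  stats::cor(b1, b2)
}

#' Prune channels by intensity floor and cardiac quality
#'
#' A channel is invalid if its mean intensity falls below the floor at
#' either wavelength (excluded immediately, regardless of cardiac content)
#' or if its cardiac quality index falls below the threshold.
#'
#' @param raw a [raw_scan()]
#' @param intensity_floor minimum mean intensity (same units as the data)
#' @param sci_threshold cardiac-coupling threshold (default 0.75)
#' @param cardiac_band cardiac frequency band (Hz)
#' @return logical valid-channel mask
#' @export
prune_channels <- function(raw, intensity_floor = 0.01, sci_threshold = 0.75,
                           cardiac_band = c(0.5, 2.5)) {
  n_ch <- dim(raw$intensity)[1L]
  if (dim(raw$intensity)[3L] < 30 * raw$fs)
    stop("need at least 30 s of data to assess channels")
  valid <- logical(n_ch)
  for (k in seq_len(n_ch)) {
    m1 <- mean(raw$intensity[k, 1L, ])
    m2 <- mean(raw$intensity[k, 2L, ])
    if (m1 < intensity_floor || m2 < intensity_floor) next
    sci <- cardiac_quality_index(raw$intensity[k, 1L, ],
                                 raw$intensity[k, 2L, ],
                                 raw$fs, cardiac_band)
    valid[k] <- sci >= sci_threshold
  }
  valid
}

#' Whole-dataset validity rule
#'
#' A dataset is excluded when more than 40% of its channels are invalid.
#' @param mask logical valid-channel mask
#' @export
dataset_valid <- function(mask, max_invalid_fraction = 0.40) {
  mean(!mask) <= max_invalid_fraction
}

#' Convert intensity to optical density
#'
#' OD(t) = -ln(I(t) / I_ref) with I_ref the channel temporal mean, so OD is
#' invariant to constant intensity scaling.
#'
#' @param intensity vector, matrix (rows = series) or channel x wavelength x
#'   time array of positive intensities
#' @return optical density in the same shape
#' @export
intensity_to_od <- function(intensity) {
  if (is.array(intensity) && length(dim(intensity)) == 3L) {
    bad <- which(apply(intensity <= 0, 1L, any))
    if (length(bad))
      stop("non-positive intensity samples in channel(s): ",
           paste(bad, collapse = ", "))
    ref <- apply(intensity, c(1L, 2L), mean)
    od <- intensity
    for (w in seq_len(dim(intensity)[2L]))
      od[, w, ] <- -log(intensity[, w, ] / ref[, w])
    return(od)
  }
  x <- as.numeric(intensity)
  if (any(x <= 0)) stop("non-positive intensity samples")
  -log(x / mean(x))
}

# ---- Haar discrete wavelet transform ---------------------------------------
# Periodic single-level Haar analysis/synthesis; used by the wavelet stage of
# motion correction (attenuation of outlying detail coefficients).

haar_dwt <- function(x, levels) {
  details <- vector("list", levels)
  lens <- integer(levels)
  a <- x
  for (j in seq_len(levels)) {
    lens[j] <- length(a)
    n <- length(a)
    if (n %% 2L) { a <- c(a, a[n]); n <- n + 1L }
    even <- a[seq(2L, n, by = 2L)]; odd <- a[seq(1L, n, by = 2L)]
    details[[j]] <- (odd - even) / sqrt(2)
    a <- (odd + even) / sqrt(2)
  }
  list(approx = a, details = details, lens = lens)
}

haar_idwt <- function(dec) {
  a <- dec$approx
  for (j in rev(seq_along(dec$details))) {
    d <- dec$details[[j]]
    a <- a[seq_along(d)]
    odd <- (a + d) / sqrt(2); even <- (a - d) / sqrt(2)
    out <- numeric(2L * length(a))
    out[seq(1L, length(out), by = 2L)] <- odd
    out[seq(2L, length(out), by = 2L)] <- even
    a <- out[seq_len(dec$lens[j])]
  }
  a
}

#' Detect motion-artifact segments in one series
#'
#' Flags samples deviating strongly from a running median. A sample is
#' flagged only when its deviation exceeds both a robust relative threshold
#' (`z_thresh` times the MAD of the residual) and an absolute amplitude
#' floor (`amp_thresh`, optical-density units), so smooth haemodynamic
#' structure is never mistaken for an artifact. Flags are dilated by
#' `pad_s` and merged into segments.
#'
#' @return data frame with columns start, end (seconds), possibly 0 rows
#' @export
detect_motion_segments <- function(x, fs, z_thresh = 8, amp_thresh = 0.02,
                                   pad_s = 0.5) {
  n <- length(x)
  k <- min(n - (1 - n %% 2L), 2L * floor(2 * fs) + 1L)
  base <- if (k >= 3L) stats::runmed(x, k) else rep(stats::median(x), n)
  z <- abs(x - base)
  thr <- max(z_thresh * stats::mad(x - base), amp_thresh)
  # sample-to-sample jumps catch plateau artifacts the running median absorbs
  dz <- c(0, abs(diff(x)))
  thr_d <- max(z_thresh * stats::mad(diff(x)), amp_thresh)
  flag <- z > thr | dz > thr_d
  if (!any(flag)) return(data.frame(start = numeric(0), end = numeric(0)))
  pad <- round(pad_s * fs)
  idx <- which(flag)
  lo <- pmax(idx - pad, 1L); hi <- pmin(idx + pad, n)
  flag2 <- logical(n)
  for (i in seq_along(idx)) flag2[lo[i]:hi[i]] <- TRUE
  r <- rle(flag2)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = (starts[keep] - 1L) / fs, end = (ends[keep] - 1L) / fs)
}

correct_motion_series <- function(x, fs, z_thresh = 8, amp_thresh = 0.02,
                                  wavelet_levels = 4L, iqr_mult = 1.5,
                                  detail_floor = 5e-3) {
  n <- length(x)
  segs <- detect_motion_segments(x, fs, z_thresh, amp_thresh)
  # stage 1: spline-trend removal inside flagged segments
  for (i in seq_len(nrow(segs))) {
    a <- max(1L, round(segs$start[i] * fs) + 1L)
    b <- min(n, round(segs$end[i] * fs) + 1L)
    if (b - a + 1L >= 8L) {
      tt <- a:b
      fit <- stats::smooth.spline(tt, x[tt], spar = 0.6)$y
      line <- seq(fit[1L], fit[length(fit)], length.out = length(tt))
      x[tt] <- x[tt] - fit + line
    } else if (a > 1L && b < n) {
      x[a:b] <- seq(x[a - 1L], x[b + 1L], length.out = b - a + 1L)
    }
  }
  # stage 2: wavelet detail attenuation outside the IQR fences; the absolute
  # detail floor keeps near-noiseless smooth signals untouched
  lev <- min(wavelet_levels, max(1L, floor(log2(n)) - 3L))
  dec <- haar_dwt(x, lev)
  for (j in seq_len(lev)) {
    d <- dec$details[[j]]
    q <- stats::quantile(d, c(0.25, 0.75), names = FALSE)
    iqr <- q[2L] - q[1L]
    out <- (d < q[1L] - iqr_mult * iqr | d > q[2L] + iqr_mult * iqr) &
      abs(d) > detail_floor
    d[out] <- 0
    dec$details[[j]] <- d
  }
  haar_idwt(dec)[seq_len(n)]
}

#' Motion-artifact correction
#'
#' Two-stage correction: spline de-trending of detected artifact segments,
#' then a discrete wavelet decomposition in which detail coefficients
#' outside the interquartile-range fences are zeroed. Clean data passes
#' through near-unchanged.
#'
#' @param od vector, matrix (rows = series) or channel x wavelength x time
#'   array of optical density
#' @param fs sampling rate (Hz)
#' @export
correct_motion <- function(od, fs, z_thresh = 8, amp_thresh = 0.02,
                           wavelet_levels = 4L, iqr_mult = 1.5,
                           detail_floor = 5e-3) {
  fun <- function(x) correct_motion_series(x, fs, z_thresh, amp_thresh,
                                           wavelet_levels, iqr_mult,
                                           detail_floor)
  apply_series(od, fun)
}

apply_series <- function(x, fun) {
  if (is.array(x) && length(dim(x)) == 3L) {
    for (k in seq_len(dim(x)[1L]))
      for (w in seq_len(dim(x)[2L]))
        x[k, w, ] <- fun(x[k, w, ])
    x
  } else if (is.matrix(x)) {
    t(apply(x, 1L, fun))
  } else {
    fun(as.numeric(x))
  }
}

#' Flag trials overlapping residual motion artifacts, per channel
#'
#' Any trial whose block window overlaps a residual-artifact segment padded
#' by `pad_s` on both sides is excluded for that channel (both wavelengths
#' pooled).
#'
#' @param od channel x wavelength x time array after [correct_motion()]
#' @param events trial table with onset (s)
#' @param fs sampling rate (Hz)
#' @param pad_s padding added around each artifact (default 4 s)
#' @param block block window relative to onset (s)
#' @return list (per channel) of excluded trial indices
#' @export
flag_residual_trials <- function(od, events, fs, pad_s = 4,
                                 block = c(-2, 20), z_thresh = 8,
                                 amp_thresh = 0.02) {
  n_ch <- dim(od)[1L]
  out <- vector("list", n_ch)
  for (k in seq_len(n_ch)) {
    segs <- rbind(detect_motion_segments(od[k, 1L, ], fs, z_thresh, amp_thresh),
                  detect_motion_segments(od[k, 2L, ], fs, z_thresh, amp_thresh))
    excl <- integer(0)
    for (i in seq_len(nrow(segs))) {
      lo <- segs$start[i] - pad_s; hi <- segs$end[i] + pad_s
      hit <- which(events$onset + block[2L] >= lo &
                   events$onset + block[1L] <= hi)
      excl <- union(excl, hit)
    }
    out[[k]] <- sort(excl)
  }
  out
}

#' Band-pass filter optical density
#'
#' Zero-phase (forward-backward) 3rd-order Butterworth band-pass; default
#' corners 0.02 and 0.06 Hz remove slow drift and high-frequency
#' physiological noise.
#' @inheritParams correct_motion
#' @export
bandpass <- function(od, fs, f_hp = 0.02, f_lp = 0.06, order = 3L) {
  flt <- signal::butter(order, c(f_hp, f_lp) / (fs / 2), type = "pass")
  apply_series(od, function(x)
    as.numeric(signal::filtfilt(flt, x - mean(x))))
}

# General differential-pathlength-factor equation for the human head:
# cubic in wavelength, power law in age (years).
DPF_COEF <- c(alpha = 223.3, beta = 0.05624, gamma = 0.8493,
              delta = -5.723e-7, epsilon = 0.001245, zeta = -0.9025)

#' Differential pathlength factor
#'
#' Evaluates the published general DPF equation, a cubic polynomial in
#' wavelength combined with a power law in age. Valid for 690-880 nm.
#'
#' @param wavelength nm (690-880)
#' @param age_years age in years (>= 0)
#' @export
dpf <- function(wavelength, age_years) {
  if (any(wavelength < 690 | wavelength > 880))
    stop("wavelength outside the 690-880 nm validity range")
  if (any(age_years < 0)) stop("age must be non-negative")
  co <- DPF_COEF
  co[["alpha"]] + co[["beta"]] * age_years^co[["gamma"]] +
    co[["delta"]] * wavelength^3 + co[["epsilon"]] * wavelength^2 +
    co[["zeta"]] * wavelength
}

#' Haemoglobin extinction coefficient table
#'
#' Tabulated base-10 molar extinction coefficients (cm^-1 / (mol/L)) for
#' oxy- and deoxy-haemoglobin; see the packaged CSV for provenance.
#' @export
extinction_table <- function() {
  path <- system.file("extdata", "extinction_hb.csv", package = "dotstream")
  if (path == "") path <- file.path("inst", "extdata", "extinction_hb.csv")
  utils::read.csv(path, comment.char = "#")
}

#' Extinction matrix for a wavelength pair
#'
#' @param wavelengths numeric vector (nm), rows of the matrix
#' @param units "ln_uM_cm" (natural-log OD per micromolar per cm) or
#'   "ln_uM_mm"
#' @return matrix with columns HbO, HbR
#' @export
extinction_matrix <- function(wavelengths = c(780, 850),
                              units = c("ln_uM_cm", "ln_uM_mm")) {
  units <- match.arg(units)
  tab <- extinction_table()
  i <- match(wavelengths, tab$wavelength_nm)
  if (anyNA(i)) stop("extinction table lacks wavelength(s): ",
                     paste(wavelengths[is.na(i)], collapse = ", "))
  E <- cbind(HbO = tab$eps_hbo[i], HbR = tab$eps_hbr[i]) * log(10) * 1e-6
  if (units == "ln_uM_mm") E <- E / 10
  rownames(E) <- as.character(wavelengths)
  E
}

#' Modified Beer-Lambert law: optical density to concentration change
#'
#' Solves dOD_lambda = (eps_HbO dHbO + eps_HbR dHbR) * d * DPF_lambda per
#' time point for the two chromophores.
#'
#' @param od 2 x T matrix of optical density (rows = wavelengths)
#' @param dpf_values length-2 DPF per wavelength
#' @param separation_cm source-detector distance (cm)
#' @param E extinction matrix from [extinction_matrix()] in ln_uM_cm units
#' @return 2 x T matrix with rows HbO, HbR (micromolar)
#' @export
mbll <- function(od, dpf_values, separation_cm, E = extinction_matrix()) {
  A <- E * separation_cm * dpf_values   # row-wise scaling
  if (abs(det(A)) < 1e-15) stop("singular extinction system")
  out <- solve(A, od)
  rownames(out) <- c("HbO", "HbR")
  out
}

#' Forward modified Beer-Lambert law: concentration change to optical density
#'
#' Exact forward of [mbll()]; `mbll(hb_to_od(x)) == x`.
#' @param hb 2 x T matrix with rows HbO, HbR (micromolar)
#' @inheritParams mbll
#' @export
hb_to_od <- function(hb, dpf_values, separation_cm, E = extinction_matrix()) {
  A <- E * separation_cm * dpf_values
  A %*% hb
}

#' Block-averaged haemoglobin container
#' @export
block_average <- function(hbo, hbr, time, n_trials, channel_mask,
                          valid = TRUE) {
  stopifnot(ncol(hbo) == length(time), all(dim(hbo) == dim(hbr)))
  structure(list(hbo = hbo, hbr = hbr, time = time, n_trials = n_trials,
                 channel_mask = channel_mask, valid = valid),
            class = "block_average")
}

#' Block time axis
#'
#' Inclusive -2..20 s at the given sampling rate; at 10 Hz this is 221
#' frames covering a 22 s block.
#' @export
block_time_axis <- function(fs = 10, block = c(-2, 20)) {
  seq(block[1L], block[2L], by = 1 / fs)
}

#' Select valid trials and block-average
#'
#' Trials with looking fraction below 0.60 are dropped; per-channel motion
#' exclusions are applied on top. The subject is flagged invalid for the
#' condition when fewer than three looking-valid trials remain.
#'
#' @param hb channel x 2 (HbO, HbR) x time array (micromolar)
#' @param events trial table with onset (s) and condition
#' @param looking per-trial looking fractions
#' @param fs sampling rate (Hz)
#' @param exclusions per-channel excluded trial indices
#'   (from [flag_residual_trials()])
#' @param condition condition to average (default the auditory vocal "V")
#' @param min_looking looking-time inclusion threshold (default 0.60)
#' @param min_trials minimum valid trials for subject validity (default 3)
#' @param channel_mask valid-channel mask from [prune_channels()]
#' @return a [block_average()]
#' @export
select_trials_and_average <- function(hb, events, looking, fs,
                                      exclusions = NULL, condition = "V",
                                      block = c(-2, 20), min_looking = 0.60,
                                      min_trials = 3L, channel_mask = NULL) {
  n_ch <- dim(hb)[1L]; n_t <- dim(hb)[3L]
  if (is.null(channel_mask)) channel_mask <- rep(TRUE, n_ch)
  time <- block_time_axis(fs, block)
  n_f <- length(time)
  cond_trials <- which(events$condition == condition)
  look_ok <- cond_trials[looking[cond_trials] >= min_looking]
  # drop trials whose block extends past the recording
  i0 <- round(events$onset[look_ok] * fs) + 1L
  fits <- i0 + round(block[1L] * fs) >= 1L & i0 + round(block[2L] * fs) <= n_t
  look_ok <- look_ok[fits]
  valid <- length(look_ok) >= min_trials
  hbo <- matrix(NA_real_, n_ch, n_f)
  hbr <- matrix(NA_real_, n_ch, n_f)
  n_trials <- integer(n_ch)
  for (k in seq_len(n_ch)) {
    if (!channel_mask[k]) next
    use <- look_ok
    if (!is.null(exclusions)) use <- setdiff(use, exclusions[[k]])
    n_trials[k] <- length(use)
    if (!length(use)) next
    acc_o <- numeric(n_f); acc_r <- numeric(n_f)
    for (tr in use) {
      i0 <- round(events$onset[tr] * fs) + 1L
      idx <- (i0 + round(block[1L] * fs)):(i0 + round(block[2L] * fs))
      acc_o <- acc_o + hb[k, 1L, idx]
      acc_r <- acc_r + hb[k, 2L, idx]
    }
    hbo[k, ] <- acc_o / length(use)
    hbr[k, ] <- acc_r / length(use)
  }
  block_average(hbo, hbr, time, n_trials, channel_mask, valid)
}

#' Run the full channel-level preprocessing pipeline on one scan
#'
#' Prune, convert to optical density, correct motion, flag residual trials,
#' band-pass, apply the modified Beer-Lambert law, and block-average the
#' requested condition.
#'
#' @param raw a [raw_scan()]
#' @param age_years subject age for the DPF (defaults to age in the scan
#'   metadata)
#' @param condition condition to block-average
#' @return list with `block` ([block_average()]), `channel_mask`,
#'   `dataset_ok`, `exclusions`, and a `log` of stage counts
#' @export
preprocess_scan <- function(raw, age_years = NULL, condition = "V",
                            intensity_floor = 0.01, sci_threshold = 0.75,
                            f_hp = 0.02, f_lp = 0.06, pad_s = 4) {
  if (is.null(age_years)) {
    am <- raw$subject$age_months
    age_years <- if (is.null(am)) 0.5 else am / 12
  }
  mask <- prune_channels(raw, intensity_floor, sci_threshold)
  ds_ok <- dataset_valid(mask)
  inten <- raw$intensity
  inten[inten <= 0] <- min(inten[inten > 0])
  od <- intensity_to_od(inten)
  od <- correct_motion(od, raw$fs)
  excl <- flag_residual_trials(od, raw$events, raw$fs, pad_s)
  od <- bandpass(od, raw$fs, f_hp, f_lp)
  dpf_v <- dpf(raw$wavelengths, age_years)
  E <- extinction_matrix(raw$wavelengths, units = "ln_uM_cm")
  hb <- od
  for (k in seq_len(dim(od)[1L]))
    hb[k, , ] <- mbll(od[k, , ], dpf_v, raw$channels$separation_cm[k], E)
  blk <- select_trials_and_average(hb, raw$events, raw$looking, raw$fs,
                                   exclusions = excl, condition = condition,
                                   channel_mask = mask)
  list(block = blk, channel_mask = mask, dataset_ok = ds_ok,
       exclusions = excl,
       log = list(n_pruned = sum(!mask),
                  n_channels = length(mask),
                  n_trials_valid = max(blk$n_trials),
                  subject_valid = blk$valid && ds_ok))
}

#' Convert a block average back to per-wavelength optical density
#'
#' The image-reconstruction streams invert the block-averaged haemoglobin
#' back to optical density with the forward Beer-Lambert law before the
#' Tikhonov inversion.
#'
#' @param block a [block_average()]
#' @param channels channel table with separation_cm
#' @param age_years subject age for the DPF
#' @param wavelengths nm
#' @return 3D array channel x wavelength x frame of optical density
#' @export
block_to_od <- function(block, channels, age_years, wavelengths = c(780, 850)) {
  dpf_v <- dpf(wavelengths, age_years)
  E <- extinction_matrix(wavelengths, units = "ln_uM_cm")
  n_ch <- nrow(block$hbo); n_f <- ncol(block$hbo)
  od <- array(NA_real_, dim = c(n_ch, 2L, n_f))
  for (k in seq_len(n_ch)) {
    if (anyNA(block$hbo[k, ])) next
    od[k, , ] <- hb_to_od(rbind(block$hbo[k, ], block$hbr[k, ]), dpf_v,
                          channels$separation_cm[k], E)
  }
  od
}
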