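# Synthetic-data generators: layered ellipsoid head phantoms, subject
# cohorts with head-size and placement variability, and forward-simulated
# dual-wavelength scans with known ground-truth activation. These stand in
# for the access-controlled infant cohort data and give every pipeline stage
# a testable ground truth.

#' Phantom specification
#'
#' Concentric four-layer ellipsoid: extra-cerebral tissue (scalp+skull,
#' `ect_mm`), CSF, grey matter, white matter interior. Defaults give a head
#' circumference near 45.7 cm, in the range of the 8- to 12-month cohort.
#'
#' @param semi_axes outer semi-axes (x right, y anterior, z superior; mm)
#' @param ect_mm,csf_mm,gm_mm layer thicknesses (mm)
#' @param n_lat,n_lon surface grid resolution (see [uv_sphere()])
#' @param grid_mm volume lattice spacing (mm)
#' @param n_parcels number of equal-area gm-surface parcels
#' @param parcel_seed stored layout seed (parcel sectors are deterministic)
#' @export
phantom_spec <- function(semi_axes = c(65, 80, 60), ect_mm = 7, csf_mm = 2,
                         gm_mm = 4, n_lat = 33L, n_lon = 48L, grid_mm = 6,
                         n_parcels = 16L, parcel_seed = 1L) {
  if (any(semi_axes <= 0) || ect_mm <= 0 || csf_mm <= 0 || gm_mm <= 0)
    stop("phantom dimensions must be positive")
  if (ect_mm + csf_mm + gm_mm >= min(semi_axes))
    stop("layer thicknesses are infeasible for the given semi-axes")
  list(semi_axes = semi_axes, ect_mm = ect_mm, csf_mm = csf_mm, gm_mm = gm_mm,
       n_lat = as.integer(n_lat), n_lon = as.integer(n_lon),
       grid_mm = grid_mm, n_parcels = as.integer(n_parcels),
       parcel_seed = as.integer(parcel_seed))
}

#' Generate a four-layer ellipsoid head phantom
#'
#' The phantom is generated directly in the landmark coordinate frame:
#' Iz at the origin, Nz on the positive y-axis, Cz superior. Landmarks are
#' exact surface vertices. The volume mesh is a body-centred cube lattice
#' split into six tetrahedra per cell; tissue labels follow the concentric
#' layer a tetrahedron centroid falls in. Grey-matter surface parcels are
#' equal-area longitude sectors around the z-axis.
#'
#' @param spec a [phantom_spec()]
#' @return a [head_mesh()]
#' @export
make_phantom <- function(spec = phantom_spec()) {
  sa <- spec$semi_axes
  centre <- c(0, sa[2L], 0)  # puts Iz at the origin
  scalp <- ellipsoid_surface(sa, spec$n_lat, spec$n_lon)
  scalp$vertices <- sweep(scalp$vertices, 2L, centre, `+`)
  gm_out <- sa - (spec$ect_mm + spec$csf_mm)
  gm <- ellipsoid_surface(gm_out, spec$n_lat, spec$n_lon)
  gm$vertices <- sweep(gm$vertices, 2L, centre, `+`)

  # volume lattice
  h <- spec$grid_mm
  gx <- seq(-sa[1L], sa[1L], by = h)
  gy <- seq(-sa[2L], sa[2L], by = h) + centre[2L]
  gz <- seq(-sa[3L], sa[3L], by = h)
  lat <- as.matrix(expand.grid(x = gx, y = gy, z = gz))
  rho2 <- function(p, semi) {
    q <- sweep(p, 2L, centre, `-`)
    (q[, 1L] / semi[1L])^2 + (q[, 2L] / semi[2L])^2 + (q[, 3L] / semi[3L])^2
  }
  inside <- rho2(lat, sa) <= 1
  id <- array(0L, dim = c(length(gx), length(gy), length(gz)))
  id[inside] <- seq_len(sum(inside))
  nodes <- lat[inside, , drop = FALSE]
  nx <- length(gx); ny <- length(gy); nz <- length(gz)
  # cells with all 8 corners inside
  ci <- expand.grid(i = seq_len(nx - 1L), j = seq_len(ny - 1L),
                    k = seq_len(nz - 1L))
  corner <- function(di, dj, dk)
    id[cbind(ci$i + di, ci$j + dj, ci$k + dk)]
  c000 <- corner(0L, 0L, 0L); c100 <- corner(1L, 0L, 0L)
  c010 <- corner(0L, 1L, 0L); c110 <- corner(1L, 1L, 0L)
  c001 <- corner(0L, 0L, 1L); c101 <- corner(1L, 0L, 1L)
  c011 <- corner(0L, 1L, 1L); c111 <- corner(1L, 1L, 1L)
  ok <- c000 > 0L & c100 > 0L & c010 > 0L & c110 > 0L &
        c001 > 0L & c101 > 0L & c011 > 0L & c111 > 0L
  # six tets per cell around the c000-c111 diagonal (edge paths x/y/z perms)
  paths <- list(c("c100", "c110"), c("c100", "c101"), c("c010", "c110"),
                c("c010", "c011"), c("c001", "c101"), c("c001", "c011"))
  cs <- list(c000 = c000[ok], c100 = c100[ok], c010 = c010[ok],
             c110 = c110[ok], c001 = c001[ok], c101 = c101[ok],
             c011 = c011[ok], c111 = c111[ok])
  tets <- do.call(rbind, lapply(paths, function(p)
    cbind(cs$c000, cs[[p[1L]]], cs[[p[2L]]], cs$c111)))

  layer_of <- function(p) {
    r_wm <- rho2(p, sa - (spec$ect_mm + spec$csf_mm + spec$gm_mm))
    r_gm <- rho2(p, gm_out)
    r_csf <- rho2(p, sa - spec$ect_mm)
    ifelse(r_wm <= 1, "WM", ifelse(r_gm <= 1, "GM",
           ifelse(r_csf <= 1, "CSF", "ECT")))
  }
  cent <- (nodes[tets[, 1L], ] + nodes[tets[, 2L], ] +
           nodes[tets[, 3L], ] + nodes[tets[, 4L], ]) / 4
  tissue <- layer_of(cent)
  node_tissue <- layer_of(nodes)

  # equal-area longitude-sector parcels on the gm surface
  q <- sweep(gm$vertices, 2L, centre, `-`)
  phi <- atan2(q[, 2L], q[, 1L])
  # nudge so grid nodes sitting exactly on sector boundaries fall
  # consistently into the upper sector
  frac <- ((phi + pi + 1e-6) %% (2 * pi)) / (2 * pi)
  parcels <- pmin(spec$n_parcels, 1L + as.integer(floor(frac * spec$n_parcels)))

  lm <- rbind(Nz = centre + c(0, sa[2L], 0),
              Iz = centre + c(0, -sa[2L], 0),
              Al = centre + c(-sa[1L], 0, 0),
              Ar = centre + c(sa[1L], 0, 0),
              Cz = centre + c(0, 0, sa[3L]))
  head_mesh(vol_nodes = nodes, tets = tets, tissue = tissue,
            node_tissue = node_tissue, scalp = scalp, gm = gm,
            parcels = parcels, landmarks = lm)
}

#' Cohort specification
#'
#' Defines the study conditions the generator emulates: per-age head
#' measurement distributions, lateral placement displacement spread, a focal
#' cortical response with a gamma-shaped haemodynamic time course peaking in
#' the 12-16 s analysis window, and physiological/instrumental noise.
#' Measurement means are phantom-proportional (Ar-Cz-Al about 0.43 and
#' Nz-Cz-Iz about 0.48 of circumference) so warp targets stay anatomically
#' plausible; at 5 months the Nz-Cz-Iz measurement is not collected.
#'
#' @param n number of subjects
#' @param age_months one of 5, 8, 12
#' @param circumference_mean_cm,circumference_sd_cm head circumference (cm);
#'   default mean 42.6/44.6/46.2 cm at 5/8/12 months
#' @param placement_sd_x_cm,placement_sd_y_cm lateral displacement SDs (cm),
#'   zero-mean; the y spread makes the > 1.6 cm exclusion rule fire for a
#'   small fraction of subjects
#' @param activation_node gm-surface node index of the planted response, or
#'   `NULL` to pick a node under the right-hemisphere array
#' @param amplitude_uM peak oxy-haemoglobin change (micromolar)
#' @param hbr_ratio deoxy peak as a (negative) fraction of the oxy peak
#' @param hrf_peak_s haemodynamic peak latency (s)
#' @param trials_per_condition presentations of each of VS/V/NV
#' @param looking_shape1,looking_shape2 Beta parameters of per-trial looking
#'   fractions
#' @param cardiac_amp_od,cardiac_freq_hz,drift_od,white_od noise levels in
#'   optical-density units
#' @param spike_rate_hz,spike_amp_od,spike_tau_s motion-spike process
#' @param bad_channel_prob probability a channel is dead (low intensity) or
#'   decoupled (no shared cardiac signal)
#' @param seed master seed; all randomness derives from it
#' @export
cohort_spec <- function(n = 20L, age_months = 8,
                        circumference_mean_cm = NULL,
                        circumference_sd_cm = 1.3,
                        ar_cz_al_sd_cm = 0.6, nz_cz_iz_sd_cm = 0.65,
                        placement_sd_x_cm = 0.7, placement_sd_y_cm = 0.8,
                        activation_node = NULL, amplitude_uM = 2.0,
                        hbr_ratio = -0.33, hrf_peak_s = 14,
                        trials_per_condition = 5L,
                        looking_shape1 = 8, looking_shape2 = 1.5,
                        cardiac_amp_od = 4e-3, cardiac_freq_hz = 2.2,
                        drift_od = 3e-3, white_od = 1e-3,
                        spike_rate_hz = 1 / 60, spike_amp_od = 0.05,
                        spike_tau_s = 0.8, bad_channel_prob = 0.06,
                        seed = 1L) {
  if (!age_months %in% c(5, 8, 12)) stop("age_months must be 5, 8 or 12")
  if (is.null(circumference_mean_cm))
    circumference_mean_cm <- c(`5` = 42.6, `8` = 44.6,
                               `12` = 46.2)[[as.character(age_months)]]
  stopifnot(n >= 1L, circumference_sd_cm >= 0, placement_sd_x_cm >= 0,
            placement_sd_y_cm >= 0, is.finite(amplitude_uM))
  list(n = as.integer(n), age_months = age_months,
       circumference_mean_cm = circumference_mean_cm,
       circumference_sd_cm = circumference_sd_cm,
       ar_cz_al_mean_cm = 0.429 * circumference_mean_cm,
       ar_cz_al_sd_cm = ar_cz_al_sd_cm,
       nz_cz_iz_mean_cm = 0.484 * circumference_mean_cm,
       nz_cz_iz_sd_cm = nz_cz_iz_sd_cm,
       placement_sd_x_cm = placement_sd_x_cm,
       placement_sd_y_cm = placement_sd_y_cm,
       activation_node = activation_node, amplitude_uM = amplitude_uM,
       hbr_ratio = hbr_ratio, hrf_peak_s = hrf_peak_s,
       trials_per_condition = as.integer(trials_per_condition),
       looking_shape1 = looking_shape1, looking_shape2 = looking_shape2,
       cardiac_amp_od = cardiac_amp_od, cardiac_freq_hz = cardiac_freq_hz,
       drift_od = drift_od, white_od = white_od,
       spike_rate_hz = spike_rate_hz, spike_amp_od = spike_amp_od,
       spike_tau_s = spike_tau_s, bad_channel_prob = bad_channel_prob,
       seed = as.integer(seed))
}

rnorm_pos <- function(n, mean, sd) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x <= 0)
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- which(x <= 0)
  }
  x
}

#' Default activation site: gm-surface node under the right-hemisphere array
#' @keywords internal
default_activation_node <- function(phantom) {
  centre <- colMeans(phantom$scalp$vertices)
  u <- unit(c(1, 0.1, 0.35))
  q <- sweep(phantom$gm$vertices, 2L, centre, `-`)
  which.max(as.numeric(q %*% u) / sqrt(rowSums(q^2)))
}

#' Sample a synthetic cohort
#'
#' Head measurements are normal (truncated positive) around the age-cohort
#' means; placement displacements are zero-mean normal per hemisphere.
#' Deterministic given the master seed.
#'
#' @param spec a [cohort_spec()]
#' @param phantom a [head_mesh()] used to resolve the default activation node
#' @return list with `subjects` (data frame), `spec`, `activation_node`
#' @export
sample_cohort <- function(spec = cohort_spec(), phantom = NULL) {
  set.seed(spec$seed)
  n <- spec$n
  subjects <- data.frame(
    id = sprintf("S%03d", seq_len(n)),
    age_months = spec$age_months,
    circumference_cm = rnorm_pos(n, spec$circumference_mean_cm,
                                 spec$circumference_sd_cm),
    ar_cz_al_cm = rnorm_pos(n, spec$ar_cz_al_mean_cm, spec$ar_cz_al_sd_cm),
    nz_cz_iz_cm = if (spec$age_months == 5) NA_real_ else
      rnorm_pos(n, spec$nz_cz_iz_mean_cm, spec$nz_cz_iz_sd_cm),
    x_disp_left_cm = stats::rnorm(n, 0, spec$placement_sd_x_cm),
    y_disp_left_cm = stats::rnorm(n, 0, spec$placement_sd_y_cm),
    x_disp_right_cm = stats::rnorm(n, 0, spec$placement_sd_x_cm),
    y_disp_right_cm = stats::rnorm(n, 0, spec$placement_sd_y_cm),
    seed = sample.int(.Machine$integer.max, n),
    stringsAsFactors = FALSE)
  act <- spec$activation_node
  if (is.null(act)) {
    if (is.null(phantom)) stop("phantom needed to choose the activation node")
    act <- default_activation_node(phantom)
  }
  list(subjects = subjects, spec = spec, activation_node = act)
}

#' Gamma-shaped haemodynamic response, unit peak
#'
#' Difference of gammas with the positive lobe peaking at `peak_s` (centred
#' in the 12-16 s analysis window by default) and a small late undershoot.
#' @param t time since stimulus onset (s)
#' @export
hrf_gamma <- function(t, peak_s = 14, undershoot_ratio = 0.15) {
  shape1 <- 8; scale1 <- peak_s / (shape1 - 1)
  shape2 <- 12; scale2 <- (peak_s + 10) / (shape2 - 1)
  f <- function(x) stats::dgamma(x, shape = shape1, scale = scale1) -
    undershoot_ratio * stats::dgamma(x, shape = shape2, scale = scale2)
  h <- f(t)
  h[t < 0] <- 0
  # normalize to a unit peak (the difference peaks slightly before peak_s)
  peak <- max(f(seq(0, peak_s + 10, by = 0.01)))
  h / peak
}

#' Forward-simulate a dual-wavelength scan for one subject
#'
#' Warps the phantom to the subject's true head measurements, registers the
#' arrays at the true placements, forward-projects a focal cortical
#' haemodynamic response through the subject-specific sensitivity matrix to
#' channel optical density, and converts to intensity with cardiac, drift,
#' white and motion-spike noise. The ground truth (activation site, optode
#' positions, events, noise realization parameters) is attached.
#'
#' @param subject one row of `sample_cohort()$subjects` (as a list or
#'   single-row data frame)
#' @param phantom the base [head_mesh()]
#' @param array an [array_spec()]
#' @param spec the [cohort_spec()]
#' @param activation_node gm-surface node index of the true response
#' @return a `raw_scan` object with attribute `truth`
#' @export
simulate_scan <- function(subject, phantom, array = array_spec(),
                          spec = cohort_spec(), activation_node) {
  subject <- as.list(subject)
  set.seed(subject$seed %% .Machine$integer.max)
  fs <- 10
  if (activation_node < 1L || activation_node > nrow(phantom$gm$vertices) ||
      phantom$parcels[activation_node] < 1L)
    stop("activation node outside the grey-matter surface")

  target <- head_measurements(subject$circumference_cm, subject$ar_cz_al_cm,
                              subject$nz_cz_iz_cm)
  warped <- warp_head_model(phantom, target)
  mesh <- warped$mesh
  pos <- compute_10_5_positions(mesh)
  opt_list <- list()
  for (hemi in c("left", "right")) {
    axes <- define_scalp_axes(mesh, hemi, pos)
    pl <- placement_measurement(hemi,
                                subject[[paste0("x_disp_", hemi, "_cm")]],
                                subject[[paste0("y_disp_", hemi, "_cm")]])
    ref <- register_reference_optode(mesh, axes, pl)
    opt_list[[hemi]] <- layout_array(mesh, axes, ref, array, hemi)
  }
  optodes <- rbind(opt_list$left, opt_list$right)
  J <- compute_sensitivity(mesh, optodes, array$channels)

  # activation support: gm volume nodes near the (warped) activation vertex
  act_xyz <- mesh$gm$vertices[activation_node, ]
  gm_vol <- which(mesh$node_tissue == "GM")
  d <- sqrt(rowSums(sweep(mesh$vol_nodes[gm_vol, , drop = FALSE], 2L,
                          act_xyz, `-`)^2))
  act_nodes <- gm_vol[d <= 10]
  if (!length(act_nodes)) act_nodes <- gm_vol[which.min(d)]
  w <- rep(1 / length(act_nodes), length(act_nodes))

  # event schedule: VS, NV, V, VS, V, NV repeated
  pattern <- c("VS", "NV", "V", "VS", "V", "NV")
  n_trials <- 3L * spec$trials_per_condition
  cond <- rep(pattern, length.out = n_trials)
  durs <- stats::runif(n_trials, 9, 12)
  gaps <- 8 + stats::runif(n_trials, 0, 2)
  onsets <- 20 + cumsum(c(0, (durs + gaps)[-n_trials]))
  total_s <- onsets[n_trials] + durs[n_trials] + 30
  n_t <- ceiling(total_s * fs)
  t_axis <- (seq_len(n_t) - 1L) / fs
  looking <- stats::rbeta(n_trials, spec$looking_shape1, spec$looking_shape2)

  # nodal haemoglobin time course (uM) and channel optical density
  amp_of <- c(VS = 0.4, NV = 0.4, V = 1.0)
  hbo_t <- numeric(n_t)
  for (k in seq_len(n_trials))
    hbo_t <- hbo_t + spec$amplitude_uM * amp_of[[cond[k]]] *
      hrf_gamma(t_axis - onsets[k], spec$hrf_peak_s)
  hbr_t <- spec$hbr_ratio * hbo_t
  E <- extinction_matrix(J$wavelengths, units = "ln_uM_mm")
  n_ch <- nrow(array$channels)
  od <- array(0, dim = c(n_ch, 2L, n_t))
  for (wi in seq_along(J$wavelengths)) {
    mua_t <- E[wi, 1L] * hbo_t + E[wi, 2L] * hbr_t       # mm^-1
    gain <- as.numeric(J$J[[wi]][, act_nodes, drop = FALSE] %*% w)
    od[, wi, ] <- outer(gain, mua_t)
  }

  # noise in OD units
  bad <- stats::runif(n_ch) < spec$bad_channel_prob
  bad_type <- ifelse(stats::runif(n_ch) < 0.5, "dead", "decoupled")
  phase <- stats::runif(n_ch, 0, 2 * pi)
  cardiac <- spec$cardiac_amp_od *
    sin(outer(phase, 2 * pi * spec$cardiac_freq_hz * t_axis, `+`))
  n_spikes <- stats::rpois(1L, spec$spike_rate_hz * total_s)
  spike_t <- sort(stats::runif(n_spikes, 0, total_s))
  spike_a <- spec$spike_amp_od * stats::rnorm(n_spikes, 1, 0.3) *
    sample(c(-1, 1), n_spikes, replace = TRUE)
  spike_tr <- numeric(n_t)
  for (k in seq_len(n_spikes)) {
    m <- t_axis >= spike_t[k]
    spike_tr[m] <- spike_tr[m] +
      spike_a[k] * exp(-(t_axis[m] - spike_t[k]) / spec$spike_tau_s)
  }
  spike_scale <- stats::runif(n_ch, 0.5, 1.5)
  drift_slope <- stats::rnorm(n_ch, 0, spec$drift_od / total_s)
  i0 <- exp(stats::rnorm(n_ch, 0, 0.3))
  i0[bad & bad_type == "dead"] <- 1e-4
  intensity <- array(0, dim = c(n_ch, 2L, n_t))
  for (wi in 1:2) {
    wn <- matrix(stats::rnorm(n_ch * n_t, 0, spec$white_od), n_ch, n_t)
    card <- cardiac
    card[bad & bad_type == "decoupled", ] <- 0
    extra <- matrix(0, n_ch, n_t)
    extra[bad & bad_type == "decoupled", ] <-
      matrix(stats::rnorm(sum(bad & bad_type == "decoupled") * n_t,
                          0, 4 * spec$white_od), ncol = n_t)
    tot <- od[, wi, ] + card + wn + extra +
      outer(spike_scale, spike_tr) + outer(drift_slope, t_axis)
    intensity[, wi, ] <- i0 * exp(-tot)
  }

  events <- data.frame(onset = onsets, condition = cond, duration = durs,
                       stringsAsFactors = FALSE)
  scan <- raw_scan(intensity = intensity, wavelengths = J$wavelengths,
                   fs = fs, channels = array$channels, events = events,
                   looking = looking, subject = subject)
  attr(scan, "truth") <- list(
    activation_node = activation_node, activation_xyz_warped = act_xyz,
    activation_vol_nodes = act_nodes, amplitude_uM = spec$amplitude_uM,
    optodes = optodes, warp_factors = warped$factors, bad_channels = bad,
    spikes = data.frame(t = spike_t, amp = spike_a), events = events,
    looking = looking)
  scan
}
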