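# Shared fixtures, built lazily once per test run and cached. All fixtures
# are generated in code at fixed seeds; nothing is stored on disk.

fx <- new.env(parent = emptyenv())

fx_get <- function(name, build) {
  if (is.null(fx[[name]])) fx[[name]] <- build()
  fx[[name]]
}

get_phantom <- function() fx_get("phantom", function() make_phantom())

get_sphere_phantom <- function() fx_get("sphere", function()
  make_phantom(phantom_spec(semi_axes = c(70, 70, 70))))

get_small_phantom <- function() fx_get("small", function()
  make_phantom(phantom_spec(n_lat = 21L, n_lon = 32L, grid_mm = 7)))

# cohort with head-size and placement variability plus one noiseless
# degenerate subject set; used by the acceptance-level pipeline checks
get_pipeline_fixture <- function() fx_get("pipeline", function() {
  phantom <- get_phantom()
  spec <- cohort_spec(n = 16L, seed = 101L)
  cohort <- sample_cohort(spec, phantom)
  arr <- array_spec()
  scans <- lapply(seq_len(spec$n), function(i)
    simulate_scan(cohort$subjects[i, ], phantom, arr, spec,
                  cohort$activation_node))
  prep <- lapply(scans, preprocess_scan, age_years = spec$age_months / 12)
  streams <- c("subject_parameter", "constant_head_warp",
               "constant_array_position", "constant_parameter")
  res <- lapply(streams, function(s)
    run_stream(s, cohort, scans, phantom, arr, prep = prep))
  names(res) <- streams
  list(phantom = phantom, spec = spec, cohort = cohort, array = arr,
       scans = scans, prep = prep, res = res)
})

# individual-level mean peak offsets of each stream vs subject-parameter,
# right hemisphere, in the constant-head-warp reference space
stream_mean_offsets <- function(fixture) {
  res <- fixture$res
  refm <- res$constant_head_warp$reference_mesh
  coords <- refm$gm$vertices
  hemi_right <- coords[, 1L] > 0
  ids <- seq_len(nrow(coords))
  vapply(c("constant_head_warp", "constant_array_position",
           "constant_parameter"), function(s) {
    m <- res$subject_parameter$group_mask & res[[s]]$group_mask & hemi_right
    offs <- vapply(seq_along(res[[1L]]$retained), function(j) {
      pa <- peak_element(res$subject_parameter$window_images[[j]]$hbo,
                         ids = ids, mask = m)
      pb <- peak_element(res[[s]]$window_images[[j]]$hbo, ids = ids, mask = m)
      peak_node_offset(pa, pb, refm)
    }, numeric(1))
    mean(offs)
  }, numeric(1))
}

# a minimal noiseless single-subject pipeline used for parameter recovery
get_recovery_fixture <- function() fx_get("recovery", function() {
  phantom <- get_phantom()
  spec <- cohort_spec(n = 2L, seed = 42L,
                      circumference_sd_cm = 0, ar_cz_al_sd_cm = 0,
                      nz_cz_iz_sd_cm = 0, placement_sd_x_cm = 0,
                      placement_sd_y_cm = 0, drift_od = 0, white_od = 0,
                      spike_rate_hz = 0, bad_channel_prob = 0,
                      looking_shape1 = 1e6, looking_shape2 = 1e-6)
  cohort <- sample_cohort(spec, phantom)
  arr <- array_spec()
  scan <- simulate_scan(cohort$subjects[1L, ], phantom, arr, spec,
                        cohort$activation_node)
  prep <- preprocess_scan(scan, age_years = spec$age_months / 12)
  list(phantom = phantom, spec = spec, cohort = cohort, array = arr,
       scan = scan, prep = prep)
})

# random triangles and rays for intersection oracle checks
random_triangle <- function() {
  matrix(stats::runif(9, -1, 1), 3L, 3L)
}

# brute-force ray/triangle oracle: plane intersection + barycentric inside
# test, independent of the Moller-Trumbore path
brute_force_intersect <- function(origin, direction, tri) {
  n <- dotstream:::cross3(tri[2L, ] - tri[1L, ], tri[3L, ] - tri[1L, ])
  denom <- sum(n * direction)
  if (abs(denom) < 1e-12) return(list(hit = FALSE))
  t <- sum(n * (tri[1L, ] - origin)) / denom
  if (t < 1e-12) return(list(hit = FALSE))
  p <- origin + t * direction
  # barycentric coordinates via normal-projected areas
  area <- function(a, b, c)
    sum(dotstream:::cross3(b - a, c - a) * n) / 2
  a0 <- area(tri[1L, ], tri[2L, ], tri[3L, ])
  w1 <- area(p, tri[2L, ], tri[3L, ]) / a0
  w2 <- area(tri[1L, ], p, tri[3L, ]) / a0
  w3 <- area(tri[1L, ], tri[2L, ], p) / a0
  if (w1 < -1e-9 || w2 < -1e-9 || w3 < -1e-9) return(list(hit = FALSE))
  list(hit = TRUE, t = t, point = p)
}
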