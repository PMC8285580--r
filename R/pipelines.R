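# Orchestration of the five processing streams and the cohort exclusion
# cascade.
#
# Streams (head-measurement source / placement source):
#   subject_parameter       subject / subject   (best practice)
#   constant_head_warp      group   / subject   (isolates head-size effect)
#   constant_array_position subject / group     (isolates placement effect)
#   constant_parameter      group   / group     (image-space equivalent of
#                                                channel space)
#   channel_space           group   / group     (no reconstruction; channel
#                                                stats + cortical projection)

STREAMS <- c("subject_parameter", "constant_head_warp",
             "constant_array_position", "constant_parameter",
             "channel_space")

#' Stream configuration
#'
#' Maps a stream name to its head-measurement and placement sources.
#' @param stream one of the five processing streams
#' @export
stream_config <- function(stream = STREAMS, lambda_reg = 0.1,
                          response = c(12, 16), baseline = c(-2, 0),
                          y_rule = "absolute") {
  stream <- match.arg(stream)
  src <- switch(stream,
    subject_parameter = c("subject", "subject"),
    constant_head_warp = c("group", "subject"),
    constant_array_position = c("subject", "group"),
    constant_parameter = c("group", "group"),
    channel_space = c("group", "group"))
  list(stream = stream, head_source = src[1L], placement_source = src[2L],
       lambda_reg = lambda_reg, response = response, baseline = baseline,
       y_rule = y_rule)
}

#' Ordered exclusion criteria of the cohort cascade
#' @export
exclusion_criteria <- function() {
  c("withdrawn", "missed_visit", "no_nirs", "fussy", "missing_photos",
    "missing_video", "missing_markers", "technical", "poor_placement",
    "pruning_below_threshold", "insufficient_trials",
    "missing_circumference")
}

#' Apply the cohort exclusion cascade
#'
#' Each subject receives exactly one terminal status: the first applicable
#' criterion in the fixed cascade order, or "retained" when no flag is set.
#'
#' @param roster data frame with one row per enrolled dataset and a logical
#'   column per criterion in [exclusion_criteria()] (missing columns are
#'   treated as all-FALSE)
#' @return list with `ledger` (per-subject status), `counts` (per-criterion
#'   exclusive counts), `retained`
#' @export
apply_exclusion_cascade <- function(roster) {
  crit <- exclusion_criteria()
  n <- nrow(roster)
  status <- rep("retained", n)
  for (cn in rev(crit)) {
    if (!cn %in% names(roster)) next
    flag <- isTRUE_vec(roster[[cn]])
    status[flag] <- cn
  }
  counts <- vapply(crit, function(cn) sum(status == cn), 0L)
  list(ledger = data.frame(subject = if ("subject" %in% names(roster))
                             roster$subject else seq_len(n),
                           status = status, stringsAsFactors = FALSE),
       counts = counts, retained = sum(status == "retained"))
}

isTRUE_vec <- function(x) !is.na(x) & as.logical(x)

#' Build a disjoint roster from printed per-criterion exclusion counts
#'
#' Printed cohort reports give exclusive per-criterion counts; this expands
#' them into a per-subject roster that [apply_exclusion_cascade()] can
#' consume.
#'
#' @param counts named integer vector (names from [exclusion_criteria()])
#' @param enrolled total enrolled datasets
#' @export
roster_from_counts <- function(counts, enrolled) {
  crit <- exclusion_criteria()
  if (sum(counts) > enrolled) stop("counts exceed enrolled datasets")
  roster <- as.data.frame(matrix(FALSE, enrolled, length(crit)),
                          stringsAsFactors = FALSE)
  names(roster) <- crit
  i <- 1L
  for (cn in names(counts)) {
    k <- counts[[cn]]
    if (k > 0L) {
      roster[[cn]][i:(i + k - 1L)] <- TRUE
      i <- i + k
    }
  }
  roster$subject <- sprintf("P%03d", seq_len(enrolled))
  roster
}

#' Packaged per-age exclusion counts of the emulated cohort study
#' @return data frame with age_months, enrolled, criterion, n
#' @export
exclusion_counts_table <- function() {
  path <- system.file("extdata", "exclusion_counts.csv",
                      package = "dotstream")
  if (path == "") path <- file.path("inst", "extdata", "exclusion_counts.csv")
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

# ---- stream execution ------------------------------------------------------

subject_geometry <- function(phantom, array, measurements, placements,
                             y_rule = "absolute") {
  warped <- warp_head_model(phantom, measurements)
  mesh <- warped$mesh
  pos <- compute_10_5_positions(mesh)
  opt <- list()
  for (hemi in c("left", "right")) {
    pl <- placements[[hemi]]
    rule <- apply_placement_rules(pl, y_rule = y_rule)
    if (rule$action == "exclude")
      return(list(excluded = TRUE, hemisphere = hemi))
    axes <- define_scalp_axes(mesh, hemi, pos)
    ref <- register_reference_optode(mesh, axes, pl,
                                     shift_mm = rule$shift_mm)
    opt[[hemi]] <- layout_array(mesh, axes, ref, array, hemi)
  }
  list(excluded = FALSE, mesh = mesh, optodes = rbind(opt$left, opt$right),
       warp = warped)
}

placements_of <- function(subj) {
  list(left = placement_measurement("left", subj$x_disp_left_cm,
                                    subj$y_disp_left_cm),
       right = placement_measurement("right", subj$x_disp_right_cm,
                                     subj$y_disp_right_cm))
}

group_mean_inputs <- function(subjects) {
  hm <- head_measurements(mean(subjects$circumference_cm),
                          mean(subjects$ar_cz_al_cm),
                          if (all(is.na(subjects$nz_cz_iz_cm))) NA_real_
                          else mean(subjects$nz_cz_iz_cm, na.rm = TRUE))
  pl <- list(left = placement_measurement("left",
                                          mean(subjects$x_disp_left_cm),
                                          mean(subjects$y_disp_left_cm)),
             right = placement_measurement("right",
                                           mean(subjects$x_disp_right_cm),
                                           mean(subjects$y_disp_right_cm)))
  list(measurements = hm, placements = pl)
}

#' Run one processing stream end-to-end on a synthetic cohort
#'
#' Applies the exclusion rules (placement, channel pruning, minimum trials),
#' computes group-mean head measurements and placements over the retained
#' cohort, executes warp, registration, sensitivity modelling and
#' reconstruction per the stream's sources, and performs group-level
#' statistics. The channel-space stream skips reconstruction and instead
#' computes the channel-wise map plus cortical projections on the
#' group-mean geometry.
#'
#' @param stream one of the five stream names
#' @param cohort output of [sample_cohort()]
#' @param scans list of `raw_scan`s, one per subject
#' @param phantom the base [head_mesh()]
#' @param array an [array_spec()]
#' @param prep optional precomputed list of [preprocess_scan()] outputs
#'   (shared across streams; preprocessing is stream-independent)
#' @param config a [stream_config()] (the stream name argument wins)
#' @return a results bundle: subject table, per-subject images (or channel
#'   map), group mask, group `tstat_map`, window-averaged images, reference
#'   mesh, manifest
#' @export
run_stream <- function(stream, cohort, scans, phantom, array,
                       prep = NULL, config = NULL) {
  cfg <- if (is.null(config)) stream_config(stream) else config
  cfg$stream <- stream <- match.arg(stream, STREAMS)
  subjects <- cohort$subjects
  age_years <- cohort$spec$age_months / 12
  if (is.null(prep))
    prep <- lapply(scans, preprocess_scan, age_years = age_years)

  # exclusion: placement rule, dataset pruning rule, minimum trials
  keep <- logical(nrow(subjects))
  reason <- character(nrow(subjects))
  for (i in seq_len(nrow(subjects))) {
    pls <- placements_of(subjects[i, ])
    placement_ok <- all(vapply(pls, function(p)
      apply_placement_rules(p, y_rule = cfg$y_rule)$action != "exclude",
      logical(1)))
    if (!placement_ok) { reason[i] <- "poor_placement"; next }
    if (!prep[[i]]$dataset_ok) { reason[i] <- "pruning_below_threshold"; next }
    if (!prep[[i]]$block$valid) { reason[i] <- "insufficient_trials"; next }
    keep[i] <- TRUE
  }
  retained <- which(keep)
  if (length(retained) < 2L) stop("fewer than two retained subjects")
  gm_inputs <- group_mean_inputs(subjects[retained, , drop = FALSE])

  # reference space: constant-head-warp model of the age cohort
  ref_mesh <- warp_head_model(phantom, gm_inputs$measurements)$mesh
  surf2vol_cache <- new.env(parent = emptyenv())
  s2v_of <- function(mesh, key) {
    if (is.null(surf2vol_cache[[key]]))
      surf2vol_cache[[key]] <- gm_surface_to_volume(mesh)
    surf2vol_cache[[key]]
  }

  if (stream == "channel_space") {
    geo <- subject_geometry(phantom, array, gm_inputs$measurements,
                            gm_inputs$placements, cfg$y_rule)
    if (geo$excluded) stop("group-mean placement fails the exclusion rule")
    mids <- channel_scalp_midpoints(geo$mesh, geo$optodes, array)
    # plane-fit radius adapted to the mesh resolution (>= the 5 mm default)
    sf <- geo$mesh$scalp
    e1 <- sf$vertices[sf$faces[, 1L], ] - sf$vertices[sf$faces[, 2L], ]
    edge <- stats::median(sqrt(rowSums(e1^2)))
    radius <- max(5, 1.6 * edge)
    proj <- vector("list", nrow(mids))
    for (k in seq_len(nrow(mids)))
      proj[[k]] <- tryCatch(
        project_channel_to_cortex(geo$mesh, mids[k, ], radius_mm = radius),
        error = function(e) NULL)
    tmap <- channel_tmap(lapply(prep[retained], `[[`, "block"),
                         array$channels, cfg$response, cfg$baseline)
    proj_tab <- data.frame(
      channel = array$channels$id,
      hemisphere = array$channels$hemisphere,
      parcel = vapply(proj, function(p) if (is.null(p)) NA_integer_
                      else p$parcel, 0L),
      gm_vertex = vapply(proj, function(p) if (is.null(p)) NA_integer_
                         else p$gm_vertex, 0L))
    return(list(stream = stream, subjects = subjects, retained = retained,
                exclusion_reason = reason, tmap = tmap,
                projection = proj_tab, mesh = geo$mesh,
                reference_mesh = ref_mesh, config = cfg))
  }

  # image streams
  n_gm <- nrow(phantom$gm$vertices)
  images <- vector("list", length(retained))
  masks <- vector("list", length(retained))
  group_pos <- if (cfg$head_source == "group")
    compute_10_5_positions(ref_mesh) else NULL
  group_axes <- if (cfg$head_source == "group")
    list(left = define_scalp_axes(ref_mesh, "left", group_pos),
         right = define_scalp_axes(ref_mesh, "right", group_pos)) else NULL
  shared_J <- NULL  # both sources group: one geometry serves the cohort
  for (j in seq_along(retained)) {
    i <- retained[j]
    meas <- if (cfg$head_source == "subject")
      head_measurements(subjects$circumference_cm[i],
                        subjects$ar_cz_al_cm[i],
                        subjects$nz_cz_iz_cm[i])
    else gm_inputs$measurements
    pls <- if (cfg$placement_source == "subject") placements_of(subjects[i, ])
           else gm_inputs$placements
    if (cfg$head_source == "group") {
      mesh <- ref_mesh
      s2v <- s2v_of(mesh, "group")
      if (is.null(shared_J)) {
        opt <- list()
        for (hemi in c("left", "right")) {
          rule <- apply_placement_rules(pls[[hemi]], y_rule = cfg$y_rule)
          ref <- register_reference_optode(mesh, group_axes[[hemi]],
                                           pls[[hemi]],
                                           shift_mm = rule$shift_mm)
          opt[[hemi]] <- layout_array(mesh, group_axes[[hemi]], ref, array,
                                      hemi)
        }
        geo <- list(mesh = mesh, optodes = rbind(opt$left, opt$right))
        J <- compute_sensitivity(geo$mesh, geo$optodes, array$channels)
        if (cfg$placement_source == "group") shared_J <- J
      } else {
        J <- shared_J
      }
    } else {
      geo <- subject_geometry(phantom, array, meas, pls, cfg$y_rule)
      if (geo$excluded) stop("retained subject failed placement at geometry")
      mesh <- geo$mesh
      s2v <- gm_surface_to_volume(mesh)
      J <- compute_sensitivity(geo$mesh, geo$optodes, array$channels)
    }
    masks[[j]] <- individual_gm_mask(J, mesh, surf2vol = s2v)
    images[[j]] <- reconstruct_image(prep[[i]]$block, J, mesh,
                                     age_years, cfg$lambda_reg,
                                     surf2vol = s2v)
  }
  gmask <- group_gm_mask(masks)
  tmap <- node_tmap(images, gmask, n_comparisons = n_gm,
                    response = cfg$response, baseline = cfg$baseline)
  wavg <- lapply(images, window_average_image, window = cfg$response)
  list(stream = stream, subjects = subjects, retained = retained,
       exclusion_reason = reason, images = images, masks = masks,
       group_mask = gmask, tmap = tmap, window_images = wavg,
       reference_mesh = ref_mesh, config = cfg)
}
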