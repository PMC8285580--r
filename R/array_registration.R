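# Bilateral array registration: scalp x/y axis curves, reference-optode
# registration from lateral displacement measurements, full-array layout at
# 20 mm geodesic spacing, and the placement re-indexing/exclusion rules.

#' Bilateral array specification
#'
#' Default is the bilateral infant array: per hemisphere 6 sources and 7
#' detectors in two rows along the side of the head, nearest-neighbour
#' separation 20 mm, 17 channels per hemisphere (34 in total). The lower row
#' holds 7 optodes (columns numbered from posterior); the reference optode
#' is the third lower optode from the posterior, intended to sit over the
#' tragus. The upper row holds 6 optodes directly above lower columns 1-6.
#'
#' @param nominal_spacing_mm nearest-neighbour source-detector separation
#' @param row_offset_mm superior arc offset of the upper row
#' @return object of class `array_spec` with `optodes` and `channels` tables
#' @export
array_spec <- function(nominal_spacing_mm = 20, row_offset_mm = 20) {
  lower_roles <- c("D", "S", "D", "S", "D", "S", "D")   # columns 1..7
  upper_roles <- c("S", "D", "S", "D", "S", "D")        # columns 1..6
  one_hemi <- function(hemi) {
    lower <- data.frame(
      name = paste0(lower_roles, c(1, 1, 2, 2, 3, 3, 4)),
      role = ifelse(lower_roles == "S", "source", "detector"),
      row = "lower", col = 1:7, stringsAsFactors = FALSE)
    upper <- data.frame(
      name = paste0(upper_roles, c(4, 5, 5, 6, 6, 7)),
      role = ifelse(upper_roles == "S", "source", "detector"),
      row = "upper", col = 1:6, stringsAsFactors = FALSE)
    opt <- rbind(lower, upper)
    opt$hemisphere <- hemi
    opt$id <- paste0(toupper(substr(hemi, 1L, 1L)), opt$name)
    opt
  }
  optodes <- rbind(one_hemi("left"), one_hemi("right"))
  chan_hemi <- function(hemi) {
    p <- toupper(substr(hemi, 1L, 1L))
    lower <- paste0(p, c("D1", "S1", "D2", "S2", "D3", "S3", "D4"))
    upper <- paste0(p, c("S4", "D5", "S5", "D6", "S6", "D7"))
    pairs <- rbind(
      cbind(lower[-7L], lower[-1L]),          # 6 within lower row
      cbind(upper[-6L], upper[-1L]),          # 5 within upper row
      cbind(lower[1:6], upper[1:6]))          # 6 vertical
    df <- data.frame(a = pairs[, 1L], b = pairs[, 2L],
                     stringsAsFactors = FALSE)
    role_of <- stats::setNames(optodes$role, optodes$id)
    data.frame(
      source = ifelse(role_of[df$a] == "source", df$a, df$b),
      detector = ifelse(role_of[df$a] == "source", df$b, df$a),
      hemisphere = hemi, stringsAsFactors = FALSE)
  }
  channels <- rbind(chan_hemi("left"), chan_hemi("right"))
  channels$id <- paste0("ch", seq_len(nrow(channels)))
  channels$separation_cm <- nominal_spacing_mm / 10
  stopifnot(sum(optodes$role == "source") == 12L,
            sum(optodes$role == "detector") == 14L,
            nrow(channels) == 34L)
  structure(list(optodes = optodes, channels = channels,
                 nominal_spacing_mm = nominal_spacing_mm,
                 row_offset_mm = row_offset_mm,
                 reference_optode = "lower column 3 (third from posterior)",
                 reference_col = 3L),
            class = "array_spec")
}

#' Lateral placement measurement of the reference optode
#'
#' Anterior (x) and superior (y) displacements are positive; posterior and
#' inferior are negative.
#' @param hemisphere "left" or "right"
#' @param x_disp_cm,y_disp_cm displacement of the reference optode (cm)
#' @export
placement_measurement <- function(hemisphere, x_disp_cm, y_disp_cm) {
  hemisphere <- match.arg(hemisphere, c("left", "right"))
  list(hemisphere = hemisphere, x_disp_cm = x_disp_cm, y_disp_cm = y_disp_cm)
}

#' Placement re-indexing and exclusion rules
#'
#' An absolute x-displacement of at least 1.6 cm shifts the array by one
#' full channel space (20 mm), in the direction opposing the displacement; a
#' y-displacement beyond 1.6 cm excludes the subject. By default the
#' exclusion tests |y| ("absolute"); set `y_rule = "superior"` to exclude on
#' superior displacement only.
#'
#' @param placement a [placement_measurement()]
#' @return list with `action` (keep / shift_forward / shift_backward /
#'   exclude) and `shift_mm` (signed arc shift to apply to the array)
#' @export
apply_placement_rules <- function(placement, threshold_cm = 1.6,
                                  y_rule = c("absolute", "superior")) {
  y_rule <- match.arg(y_rule)
  y <- placement$y_disp_cm
  y_test <- if (y_rule == "absolute") abs(y) else y
  if (y_test > threshold_cm)
    return(list(action = "exclude", shift_mm = 0))
  x <- placement$x_disp_cm
  if (abs(x) >= threshold_cm) {
    if (x > 0)  # displaced anterior -> shift array back
      list(action = "shift_backward", shift_mm = -20)
    else
      list(action = "shift_forward", shift_mm = 20)
  } else {
    list(action = "keep", shift_mm = 0)
  }
}

#' Scalp x- and y-axis curves for one hemisphere
#'
#' The x-axis is the scalp curve from Iz to FPz along the lateral side of
#' the head (cutting plane through Iz, FPz and the preauricular point); the
#' y-axis runs from the preauricular point to CCPz. Both carry arc-length
#' parameterization with the origin at the preauricular point, which is the
#' intended reference-optode location (over the tragus).
#'
#' @param mesh an aligned `head_mesh`
#' @param hemisphere "left" or "right"
#' @param positions output of [compute_10_5_positions()]
#' @return object of class `scalp_axes`
#' @export
define_scalp_axes <- function(mesh, hemisphere,
                              positions = compute_10_5_positions(mesh)) {
  hemisphere <- match.arg(hemisphere, c("left", "right"))
  lm <- mesh$landmarks
  au <- if (hemisphere == "right") lm["Ar", ] else lm["Al", ]
  fpz <- positions$sagittal["FPz", ]
  ccpz <- positions$sagittal["CCPz", ]
  iz <- lm["Iz", ]
  centre <- colMeans(mesh$scalp$vertices)
  x_curve <- curve_walk(mesh$scalp, iz, fpz, plane_ref = au, guide = au)
  y_curve <- curve_walk(mesh$scalp, au, ccpz, plane_ref = centre, guide = NA)
  # x-plane normal oriented superior
  n0 <- unit(cross3(fpz - iz, au - iz))
  if (sum((lm["Cz", ] - au) * n0) < 0) n0 <- -n0
  # full closed loop of the y-plane, signed arc origin at the preauricular
  ny <- unit(cross3(ccpz - au, centre - au))
  y_loop <- closed_section_loop(mesh$scalp, au, ny)
  s_au <- nearest_on_polyline(y_loop$points, au, closed = TRUE)$s
  s_cc <- nearest_on_polyline(y_loop$points, ccpz, closed = TRUE)$s
  L <- y_loop$length
  up_forward <- ((s_cc - s_au) %% L) <= L / 2  # CCPz reached walking forward?
  structure(list(hemisphere = hemisphere, x_curve = x_curve,
                 y_curve = y_curve, n0 = n0, origin = au,
                 anterior_dir = unit(fpz - iz), y_loop = y_loop,
                 s_au = s_au, y_up_forward = up_forward,
                 centre = centre, scalp = mesh$scalp),
            class = "scalp_axes")
}

#' Scalp point at (u, v) arc coordinates
#'
#' `u` is the anterior-positive arc displacement (mm) along the curve band
#' parallel to the Iz-FPz curve; `v` is the superior-positive arc
#' displacement (mm) along the preauricular-to-CCPz curve. The point at
#' (0, 0) is the preauricular origin.
#' @param axes a `scalp_axes` object
#' @keywords internal
scalp_point_uv <- function(axes, u_mm, v_mm) {
  L <- axes$y_loop$length
  if (abs(v_mm) > 0.45 * L)
    stop("y displacement walks off the curve domain")
  sv <- if (axes$y_up_forward) axes$s_au + v_mm else axes$s_au - v_mm
  q <- point_at_arc(axes$y_loop$points, sv, closed = TRUE)
  h <- sum((q - axes$origin) * axes$n0)
  band <- closed_section_loop(axes$scalp, axes$origin + h * axes$n0, axes$n0)
  nq <- nearest_on_polyline(band$points, q, closed = TRUE)
  if (abs(u_mm) > 0.45 * band$length)
    stop("x displacement walks off the curve domain")
  # local tangent, oriented anterior
  eps <- min(2, 0.01 * band$length)
  p1 <- point_at_arc(band$points, nq$s + eps, closed = TRUE)
  tang <- p1 - nq$point
  forward_is_anterior <- sum(tang * axes$anterior_dir) >= 0
  su <- if (forward_is_anterior) nq$s + u_mm else nq$s - u_mm
  point_at_arc(band$points, su, closed = TRUE)
}

#' Register the reference optode from placement measurements
#'
#' Displaces the intended reference location (the preauricular origin of the
#' scalp axes) by the measured x- and y-displacements, both as scalp arc
#' lengths.
#'
#' @param mesh an aligned `head_mesh`
#' @param axes a `scalp_axes` for the matching hemisphere
#' @param placement a [placement_measurement()]
#' @param shift_mm additional arc shift from the re-indexing rule
#' @return list with `point` (scalp, mm) and the `u`, `v` arc coordinates
#' @export
register_reference_optode <- function(mesh, axes, placement, shift_mm = 0) {
  if (placement$hemisphere != axes$hemisphere)
    stop("placement and axes hemispheres differ")
  u <- 10 * placement$x_disp_cm + shift_mm
  v <- 10 * placement$y_disp_cm
  list(point = scalp_point_uv(axes, u, v), u = u, v = v)
}

#' Lay out the full array from the registered reference optode
#'
#' Lower-row optodes step along the scalp band through the reference point
#' in 20 mm arcs; upper-row optodes sit on a parallel band offset superiorly
#' by the row separation. All positions lie on the scalp surface.
#'
#' @param mesh an aligned `head_mesh`
#' @param axes a `scalp_axes`
#' @param reference output of [register_reference_optode()]
#' @param spec an [array_spec()]
#' @param hemisphere "left" or "right"
#' @return matrix of optode positions (rows named by optode id, mm)
#' @export
layout_array <- function(mesh, axes, reference, spec, hemisphere) {
  opt <- spec$optodes[spec$optodes$hemisphere == hemisphere, , drop = FALSE]
  sp <- spec$nominal_spacing_mm
  pos <- matrix(NA_real_, nrow(opt), 3L, dimnames = list(opt$id, NULL))
  for (k in seq_len(nrow(opt))) {
    du <- (opt$col[k] - spec$reference_col) * sp
    dv <- if (opt$row[k] == "upper") spec$row_offset_mm else 0
    pos[k, ] <- scalp_point_uv(axes, reference$u + du, reference$v + dv)
  }
  pos
}

#' Scalp midpoints of all channels
#'
#' The midpoint is the half-arc point of the scalp trace between source and
#' detector (plane through the two optodes and the head centre).
#'
#' @param mesh an aligned `head_mesh`
#' @param optode_positions matrix with rownames matching optode ids
#' @param spec an [array_spec()]
#' @return matrix of midpoints (rows = channel ids, mm)
#' @export
channel_scalp_midpoints <- function(mesh, optode_positions, spec) {
  centre <- colMeans(mesh$scalp$vertices)
  ch <- spec$channels
  mid <- matrix(NA_real_, nrow(ch), 3L, dimnames = list(ch$id, NULL))
  for (k in seq_len(nrow(ch))) {
    s <- optode_positions[ch$source[k], ]
    d <- optode_positions[ch$detector[k], ]
    if (sqrt(sum((s - d)^2)) < 1e-9) {
      mid[k, ] <- s
    } else {
      arc <- curve_walk(mesh$scalp, s, d, plane_ref = centre, guide = NA)
      mid[k, ] <- point_at_arc(arc$points, arc$length / 2)
    }
  }
  mid
}
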