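# Four-layer head-model geometry: landmark coordinate frame, scalp
# curve-walks and 10-5 positions, tape-measure extraction, and the iterative
# measurement-driven warping algorithm. Meshes are stored in mm; head
# measurements cross the API boundary in cm.

TISSUES <- c("WM", "GM", "CSF", "ECT")

#' Construct a four-layer head mesh
#'
#' @param vol_nodes volume node coordinates (n x 3, mm)
#' @param tets tetrahedron node indices (m x 4)
#' @param tissue tissue label per tetrahedron, one of WM/GM/CSF/ECT
#' @param node_tissue tissue label per volume node
#' @param scalp outer scalp surface, list(vertices, faces)
#' @param gm grey-matter surface, list(vertices, faces)
#' @param parcels integer parcel label per gm-surface vertex
#' @param landmarks 5 x 3 matrix with rownames Nz, Iz, Al, Ar, Cz (mm)
#' @return object of class `head_mesh`
#' @export
head_mesh <- function(vol_nodes, tets, tissue, node_tissue, scalp, gm,
                      parcels, landmarks) {
  stopifnot(ncol(vol_nodes) == 3L, ncol(tets) == 4L,
            nrow(tets) == length(tissue),
            length(node_tissue) == nrow(vol_nodes),
            length(parcels) == nrow(gm$vertices))
  if (!all(tissue %in% TISSUES))
    stop("tissue labels must be one of ", paste(TISSUES, collapse = ", "))
  if (max(tets) > nrow(vol_nodes) || min(tets) < 1L)
    stop("tetrahedra reference invalid node indices")
  need <- c("Nz", "Iz", "Al", "Ar", "Cz")
  missing_lm <- setdiff(need, rownames(landmarks))
  if (length(missing_lm))
    stop("missing landmark(s): ", paste(missing_lm, collapse = ", "))
  structure(list(vol_nodes = vol_nodes, tets = tets, tissue = tissue,
                 node_tissue = node_tissue, scalp = scalp, gm = gm,
                 parcels = as.integer(parcels),
                 landmarks = landmarks[need, , drop = FALSE]),
            class = "head_mesh")
}

#' @export
print.head_mesh <- function(x, ...) {
  cat("Four-layer head mesh\n")
  cat("  volume nodes:", nrow(x$vol_nodes), " tetrahedra:", nrow(x$tets), "\n")
  cat("  tissue tets :", paste(sprintf("%s=%d", TISSUES,
      vapply(TISSUES, function(t) sum(x$tissue == t), 0L)), collapse = " "), "\n")
  cat("  scalp:", nrow(x$scalp$vertices), "vertices;  gm surface:",
      nrow(x$gm$vertices), "vertices,", length(unique(x$parcels)), "parcels\n")
  invisible(x)
}

apply_affine <- function(mesh, fun) {
  mesh$vol_nodes <- fun(mesh$vol_nodes)
  mesh$scalp$vertices <- fun(mesh$scalp$vertices)
  mesh$gm$vertices <- fun(mesh$gm$vertices)
  lm <- fun(mesh$landmarks)
  rownames(lm) <- rownames(mesh$landmarks)
  mesh$landmarks <- lm
  mesh
}

#' Align a head mesh to the landmark coordinate frame
#'
#' Translates and rotates the mesh so that Iz sits at the origin, the
#' Iz-to-Nz line is the positive y-axis, and the preauricular points Ar and
#' Al have equal z after a final rotation about y (Cz kept superior, z > 0).
#'
#' @param mesh a `head_mesh`
#' @return the aligned `head_mesh`
#' @export
align_to_landmark_frame <- function(mesh) {
  lm <- mesh$landmarks
  if (anyNA(lm)) {
    bad <- rownames(lm)[apply(is.na(lm), 1L, any)]
    stop("missing landmark(s): ", paste(bad, collapse = ", "))
  }
  iz <- lm["Iz", ]
  u <- unit(lm["Nz", ] - iz)
  ey <- c(0, 1, 0)
  ax <- cross3(u, ey)
  sa <- sqrt(sum(ax^2))
  ca <- sum(u * ey)
  if (sa < 1e-12) {
    R1 <- if (ca > 0) diag(3) else diag(c(-1, 1, -1))
  } else {
    k <- ax / sa
    K <- matrix(c(0, -k[3], k[2], k[3], 0, -k[1], -k[2], k[1], 0),
                3L, 3L, byrow = TRUE)
    ang <- atan2(sa, ca)
    R1 <- diag(3) + sin(ang) * K + (1 - cos(ang)) * (K %*% K)
  }
  step1 <- function(p) sweep(p, 2L, iz, `-`) %*% t(R1)
  ar <- drop(step1(lm["Ar", , drop = FALSE]))
  al <- drop(step1(lm["Al", , drop = FALSE]))
  theta <- atan2(ar[3L] - al[3L], ar[1L] - al[1L])
  roty <- function(th) matrix(c(cos(th), 0, sin(th), 0, 1, 0,
                                -sin(th), 0, cos(th)), 3L, 3L, byrow = TRUE)
  R2 <- roty(theta)
  cz <- drop(step1(lm["Cz", , drop = FALSE]) %*% t(R2))
  if (cz[3L] < 0) R2 <- roty(theta + pi)
  apply_affine(mesh, function(p) step1(p) %*% t(R2))
}

#' Head measurements container
#'
#' @param circumference head circumference (cm)
#' @param ar_cz_al tragus-to-tragus distance via Cz (cm), or `NA` if absent
#' @param nz_cz_iz nasion-to-inion distance via Cz (cm), or `NA` if absent
#'   (not collected at the 5-month visit)
#' @export
head_measurements <- function(circumference, ar_cz_al = NA_real_,
                              nz_cz_iz = NA_real_) {
  vals <- c(circumference = circumference, ar_cz_al = ar_cz_al,
            nz_cz_iz = nz_cz_iz)
  if (any(!is.na(vals) & vals <= 0))
    stop("head measurements must be strictly positive")
  structure(as.list(vals), class = "head_measurements")
}

#' @export
print.head_measurements <- function(x, ...) {
  cat(sprintf("Head measurements (cm): circumference %.2f, Ar-Cz-Al %s, Nz-Cz-Iz %s\n",
              x$circumference,
              ifelse(is.na(x$ar_cz_al), "absent", sprintf("%.2f", x$ar_cz_al)),
              ifelse(is.na(x$nz_cz_iz), "absent", sprintf("%.2f", x$nz_cz_iz))))
  invisible(x)
}

#' Tape-measure extraction from a head mesh
#'
#' Computes the three scalp measurements used to drive warping:
#' circumference (closed scalp trace of the plane through Nz and Iz parallel
#' to the Al-Ar axis), Ar-Cz-Al and Nz-Cz-Iz (curve walks via Cz).
#'
#' @param mesh an aligned `head_mesh`
#' @return a `head_measurements` object (cm)
#' @export
measure_head <- function(mesh) {
  lm <- mesh$landmarks
  sag <- curve_walk(mesh$scalp, lm["Nz", ], lm["Iz", ],
                    plane_ref = lm["Cz", ], guide = lm["Cz", ])
  cor <- curve_walk(mesh$scalp, lm["Ar", ], lm["Al", ],
                    plane_ref = lm["Cz", ], guide = lm["Cz", ])
  n <- cross3(lm["Nz", ] - lm["Iz", ], lm["Ar", ] - lm["Al", ])
  circ <- closed_section_loop(mesh$scalp, lm["Nz", ], n)
  head_measurements(circumference = circ$length / 10,
                    ar_cz_al = cor$length / 10,
                    nz_cz_iz = sag$length / 10)
}

#' Warp tolerances
#'
#' Defaults follow the warping convergence criteria: 6 mm on the two
#' over-the-head distances and 3 mm on circumference. Tolerance (rather than
#' exact fitting) avoids over-fitting the warp to tape measurements, which
#' can produce anatomically implausible head shapes.
#' @export
warp_tolerances <- function(tol_ar_cz_al = 6, tol_nz_cz_iz = 6,
                            tol_circumference = 3, max_iterations = 50L) {
  vals <- c(tol_ar_cz_al, tol_nz_cz_iz, tol_circumference, max_iterations)
  if (any(vals <= 0)) stop("warp tolerances must be positive")
  list(tol_ar_cz_al = tol_ar_cz_al, tol_nz_cz_iz = tol_nz_cz_iz,
       tol_circumference = tol_circumference,
       max_iterations = as.integer(max_iterations))
}

#' Iteratively warp a head model to target head measurements
#'
#' First scales all axes by target/model circumference; then repeatedly
#' re-measures, picks the measurement with the greatest absolute error, and
#' multiplies the axis subset tied to that measurement (Ar-Cz-Al: x,z;
#' Nz-Cz-Iz: y,z; circumference: x,y,z) by target/measured, until all
#' available measurements are within tolerance. When the Nz-Cz-Iz target is
#' absent (5-month visit) only circumference and Ar-Cz-Al drive the warp.
#' The grey-matter surface, volume nodes and landmarks are warped by the
#' identical factor sequence, preserving one-to-one nodal correspondence.
#'
#' @param mesh an aligned `head_mesh`
#' @param target a `head_measurements` object (cm)
#' @param tol a `warp_tolerances` list
#' @return list with `mesh` (warped), `factors` (cumulative per-axis scale),
#'   `log` (data frame of iteration history), `converged`
#' @export
warp_head_model <- function(mesh, target, tol = warp_tolerances()) {
  tgt_mm <- c(circumference = target$circumference,
              ar_cz_al = target$ar_cz_al,
              nz_cz_iz = target$nz_cz_iz) * 10
  if (any(!is.na(tgt_mm) & tgt_mm <= 0)) stop("non-positive warp target")
  if (is.na(tgt_mm["circumference"])) stop("circumference target is required")
  use <- names(tgt_mm)[!is.na(tgt_mm)]
  tols <- c(circumference = tol$tol_circumference,
            ar_cz_al = tol$tol_ar_cz_al, nz_cz_iz = tol$tol_nz_cz_iz)
  axes_of <- list(circumference = 1:3, ar_cz_al = c(1L, 3L),
                  nz_cz_iz = c(2L, 3L))
  cum <- c(1, 1, 1)
  scale_by <- function(m, fac) apply_affine(m, function(p) sweep(p, 2L, fac, `*`))
  meas_mm <- function(m) {
    hm <- measure_head(m)
    c(circumference = hm$circumference, ar_cz_al = hm$ar_cz_al,
      nz_cz_iz = hm$nz_cz_iz) * 10
  }
  m0 <- meas_mm(mesh)
  f0 <- tgt_mm["circumference"] / m0["circumference"]
  fac <- rep(unname(f0), 3L)
  mesh <- scale_by(mesh, fac)
  cum <- cum * fac
  log <- data.frame(iteration = 0L, measurement = "circumference",
                    factor = unname(f0), stringsAsFactors = FALSE)
  errs <- NULL
  for (it in seq_len(tol$max_iterations)) {
    cur <- meas_mm(mesh)
    errs <- abs(cur[use] - tgt_mm[use])
    if (all(errs <= tols[use] - 1e-9)) {
      return(list(mesh = mesh, factors = cum, log = log, converged = TRUE,
                  residuals_mm = errs))
    }
    pick <- use[which.max(errs)]
    f <- unname(tgt_mm[pick] / cur[pick])
    fac <- c(1, 1, 1)
    fac[axes_of[[pick]]] <- f
    mesh <- scale_by(mesh, fac)
    cum <- cum * fac
    log <- rbind(log, data.frame(iteration = it, measurement = pick,
                                 factor = f, stringsAsFactors = FALSE))
  }
  stop(sprintf(
    "head warp did not converge in %d iterations; residuals (mm): %s",
    tol$max_iterations,
    paste(sprintf("%s=%.2f", names(errs), errs), collapse = ", ")))
}

#' Parcel label of a grey-matter surface node
#'
#' Labels are node attributes and ride with nodes through warping.
#' @param mesh a `head_mesh`
#' @param gm_node_index index into the gm-surface vertices
#' @export
parcel_of_node <- function(mesh, gm_node_index) {
  n <- nrow(mesh$gm$vertices)
  if (any(gm_node_index < 1L | gm_node_index > n))
    stop("gm node index out of range 1..", n)
  mesh$parcels[gm_node_index]
}

SAGITTAL_10_5 <- c("Nz", "NFPz", "FPz", "AFPz", "AFz", "AFFz", "Fz", "FFCz",
                   "FCz", "FCCz", "Cz", "CCPz", "CPz", "CPPz", "Pz", "PPOz",
                   "POz", "POOz", "Oz", "OIz", "Iz")

#' Compute scalp 10-5 positions
#'
#' Refines Cz as the mutual midpoint of the Nz-Cz-Iz and Al-Cz-Ar scalp
#' curves (two fixed-point sweeps), then returns the 5%-spaced positions
#' along the midsagittal curve (Nz at 0% through Iz at 100%, so FPz sits at
#' 10% and CCPz at 55%) and along the coronal Ar-to-Al curve.
#'
#' @param mesh an aligned `head_mesh`
#' @return list with `sagittal` (named 21 x 3 matrix), `coronal`
#'   (21 x 3, Ar at 0% to Al at 100%), `Cz` (refined vertex point), and the
#'   two curves
#' @export
compute_10_5_positions <- function(mesh) {
  lm <- mesh$landmarks
  cz <- lm["Cz", ]
  for (i in 1:2) {
    sag <- curve_walk(mesh$scalp, lm["Nz", ], lm["Iz", ],
                      plane_ref = cz, guide = cz)
    if (sag$length < 1e-6) stop("degenerate sagittal curve")
    cz_s <- point_at_arc(sag$points, 0.5 * sag$length)
    cor <- curve_walk(mesh$scalp, lm["Ar", ], lm["Al", ],
                      plane_ref = cz_s, guide = cz_s)
    if (cor$length < 1e-6) stop("degenerate coronal curve")
    cz <- point_at_arc(cor$points, 0.5 * cor$length)
  }
  sag <- curve_walk(mesh$scalp, lm["Nz", ], lm["Iz", ],
                    plane_ref = cz, guide = cz)
  cor <- curve_walk(mesh$scalp, lm["Ar", ], lm["Al", ],
                    plane_ref = cz, guide = cz)
  fr <- seq(0, 1, by = 0.05)
  sag_pts <- t(vapply(fr, function(f) point_at_arc(sag$points, f * sag$length),
                      numeric(3)))
  rownames(sag_pts) <- SAGITTAL_10_5
  cor_pts <- t(vapply(fr, function(f) point_at_arc(cor$points, f * cor$length),
                      numeric(3)))
  rownames(cor_pts) <- paste0("ArAl_", round(100 * fr))
  list(sagittal = sag_pts, coronal = cor_pts, Cz = cz,
       sagittal_curve = sag, coronal_curve = cor)
}
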