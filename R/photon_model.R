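# Channel-wise sensitivity modelling, grey-matter masks, cortically
# constrained zeroth-order Tikhonov reconstruction, and chromophore image
# formation. The default forward engine is an analytic
# diffusion-approximation Green's-function product (Rytov form) for a
# homogeneous medium with a locally planar boundary handled by image
# sources; a numerical solver can be substituted through the same contract.

#' Homogeneous tissue optical properties
#' @return data frame with wavelength_nm, mua_mm, musp_mm
#' @export
optical_properties <- function() {
  path <- system.file("extdata", "optical_properties.csv",
                      package = "dotstream")
  if (path == "") path <- file.path("inst", "extdata", "optical_properties.csv")
  utils::read.csv(path, comment.char = "#")
}

diffusion_green <- function(dist, mua, musp) {
  D <- 1 / (3 * (mua + musp))
  mu_eff <- sqrt(3 * mua * (mua + musp))
  dist <- pmax(dist, 0.5)  # clip below half a millimetre
  exp(-mu_eff * dist) / (4 * pi * D * dist)
}

node_volumes <- function(mesh) {
  v <- mesh$vol_nodes; tt <- mesh$tets
  a <- v[tt[, 1L], , drop = FALSE]
  e1 <- v[tt[, 2L], , drop = FALSE] - a
  e2 <- v[tt[, 3L], , drop = FALSE] - a
  e3 <- v[tt[, 4L], , drop = FALSE] - a
  cx <- e1[, 2L] * e2[, 3L] - e1[, 3L] * e2[, 2L]
  cy <- e1[, 3L] * e2[, 1L] - e1[, 1L] * e2[, 3L]
  cz <- e1[, 1L] * e2[, 2L] - e1[, 2L] * e2[, 1L]
  vol <- abs(cx * e3[, 1L] + cy * e3[, 2L] + cz * e3[, 3L]) / 6
  nv <- numeric(nrow(v))
  for (k in 1:4) {
    t <- tapply(vol / 4, tt[, k], sum)
    nv[as.integer(names(t))] <- nv[as.integer(names(t))] + t
  }
  nv
}

#' Compute the channel sensitivity matrix (forward model)
#'
#' For each channel the sensitivity of the measured optical density to a
#' local absorption change at node r follows the Rytov product
#' G(source->r) G(r->detector) / G(source->detector), with
#' diffusion-approximation Green's functions. With the default
#' `boundary = "semi_infinite"`, each channel uses a locally planar boundary
#' through the optode pair (outward normal from the head centre) and an
#' image source enforcing the extrapolated-boundary condition;
#' `boundary = "infinite"` uses free-space Green's functions (useful for
#' translation-invariance checks). Rows are scaled by nodal volume so
#' entries are OD change per unit absorption change.
#'
#' @param mesh a `head_mesh`
#' @param optode_positions matrix (rows named by optode id, mm), on the scalp
#' @param channels channel table with source, detector, id
#' @param props optical properties table (per wavelength)
#' @param wavelengths nm
#' @param boundary "semi_infinite" or "infinite"
#' @return object of class `sensitivity_matrix`: list of per-wavelength
#'   channel x volume-node matrices plus metadata
#' @export
compute_sensitivity <- function(mesh, optode_positions, channels,
                                props = optical_properties(),
                                wavelengths = c(780, 850),
                                boundary = c("semi_infinite", "infinite")) {
  boundary <- match.arg(boundary)
  if (any(props$mua_mm <= 0) || any(props$musp_mm <= 0))
    stop("optical properties must be positive")
  miss <- setdiff(unique(c(channels$source, channels$detector)),
                  rownames(optode_positions))
  if (length(miss))
    stop("optode positions missing for: ", paste(miss, collapse = ", "))
  # optodes must sit on the scalp
  sa <- surface_areas(mesh$scalp)
  centre <- colMeans(mesh$scalp$vertices)
  for (id in rownames(optode_positions)) {
    d <- sqrt(rowSums(sweep(mesh$scalp$vertices, 2L,
                            optode_positions[id, ], `-`)^2))
    if (min(d) > 15) stop("optode ", id, " is not on the scalp surface")
  }
  nodes <- mesh$vol_nodes
  nv <- node_volumes(mesh)
  n_ch <- nrow(channels)
  J <- lapply(wavelengths, function(w) matrix(0, n_ch, nrow(nodes)))
  names(J) <- as.character(wavelengths)
  for (wi in seq_along(wavelengths)) {
    pr <- props[match(wavelengths[wi], props$wavelength_nm), ]
    if (anyNA(pr)) stop("no optical properties for ", wavelengths[wi], " nm")
    mua <- pr$mua_mm; musp <- pr$musp_mm
    z0 <- 1 / musp
    D <- 1 / (3 * (mua + musp))
    reff <- 0.493
    zb <- 2 * D * (1 + reff) / (1 - reff)
    for (k in seq_len(n_ch)) {
      s <- optode_positions[channels$source[k], ]
      d <- optode_positions[channels$detector[k], ]
      if (boundary == "infinite") {
        phi_s <- diffusion_green(sqrt(rowSums(sweep(nodes, 2L, s, `-`)^2)),
                                 mua, musp)
        phi_d <- diffusion_green(sqrt(rowSums(sweep(nodes, 2L, d, `-`)^2)),
                                 mua, musp)
        phi_sd <- diffusion_green(sqrt(sum((s - d)^2)), mua, musp)
      } else {
        mid <- (s + d) / 2
        n_out <- unit(mid - centre)
        proj <- function(p) p - sum((p - mid) * n_out) * n_out
        sp <- proj(s); dp <- proj(d)
        s_eff <- sp - z0 * n_out
        s_img <- sp + (z0 + 2 * zb) * n_out
        d_eff <- dp - z0 * n_out
        d_img <- dp + (z0 + 2 * zb) * n_out
        g <- function(p_eff, p_img) {
          diffusion_green(sqrt(rowSums(sweep(nodes, 2L, p_eff, `-`)^2)),
                          mua, musp) -
            diffusion_green(sqrt(rowSums(sweep(nodes, 2L, p_img, `-`)^2)),
                            mua, musp)
        }
        phi_s <- pmax(g(s_eff, s_img), 0)
        phi_d <- pmax(g(d_eff, d_img), 0)
        phi_sd <- diffusion_green(sqrt(sum((dp - s_eff)^2)), mua, musp) -
          diffusion_green(sqrt(sum((dp - s_img)^2)), mua, musp)
      }
      J[[wi]][k, ] <- phi_s * phi_d / phi_sd * nv
    }
  }
  structure(list(J = J, wavelengths = wavelengths, channels = channels,
                 optodes = optode_positions, props = props,
                 model = "analytic_diffusion", boundary = boundary),
            class = "sensitivity_matrix")
}

#' @export
print.sensitivity_matrix <- function(x, ...) {
  cat(sprintf("sensitivity_matrix (%s, %s): %d channels x %d nodes at %s nm\n",
              x$model, x$boundary, nrow(x$J[[1L]]), ncol(x$J[[1L]]),
              paste(x$wavelengths, collapse = "/")))
  invisible(x)
}

#' Sensitivity-weighted centre of mass of one channel
#'
#' @param row one row of a sensitivity matrix (per-node weights)
#' @param coords node coordinates (n x 3)
#' @export
sensitivity_com <- function(row, coords) {
  s <- sum(row)
  if (s <= 0) stop("all-zero sensitivity row")
  as.numeric(crossprod(coords, row) / s)
}

#' Nearest grey-matter volume node for each gm-surface vertex
#'
#' Surface nodes take values from their nearest GM volume node; nodes with
#' no GM volume node inside `radius_mm` fall back to the unconditionally
#' nearest one (guards coarse phantom lattices).
#' @keywords internal
gm_surface_to_volume <- function(mesh, radius_mm = 3) {
  gm_vol <- which(mesh$node_tissue == "GM")
  if (!length(gm_vol)) stop("mesh has no grey-matter volume nodes")
  vv <- mesh$vol_nodes[gm_vol, , drop = FALSE]
  sv <- mesh$gm$vertices
  idx <- integer(nrow(sv))
  for (k in seq_len(nrow(sv))) {
    d2 <- (vv[, 1L] - sv[k, 1L])^2 + (vv[, 2L] - sv[k, 2L])^2 +
      (vv[, 3L] - sv[k, 3L])^2
    j <- which.min(d2)
    idx[k] <- gm_vol[j]
  }
  idx
}

#' Individual grey-matter sensitivity mask
#'
#' Aggregate sensitivity (column sums of |J| across channels at the first
#' wavelength) mapped to the gm surface and thresholded at `threshold`
#' (default 1%) of its maximum.
#'
#' @param J a `sensitivity_matrix`
#' @param mesh the matching `head_mesh`
#' @param threshold fraction of the maximum aggregate sensitivity
#' @param wavelength which wavelength's matrix to aggregate
#' @return logical mask over gm-surface vertices
#' @export
individual_gm_mask <- function(J, mesh, threshold = 0.01,
                               wavelength = NULL, surf2vol = NULL) {
  wl <- if (is.null(wavelength)) as.character(J$wavelengths[1L])
        else as.character(wavelength)
  M <- J$J[[wl]]
  if (is.null(M)) stop("no sensitivity at wavelength ", wl)
  if (nrow(M) == 0L) return(rep(FALSE, nrow(mesh$gm$vertices)))
  agg <- colSums(abs(M))
  if (is.null(surf2vol)) surf2vol <- gm_surface_to_volume(mesh)
  sv <- agg[surf2vol]
  if (max(sv) <= 0) return(rep(FALSE, length(sv)))
  sv >= threshold * max(sv)
}

#' Group grey-matter mask
#'
#' A node is kept when present in the individual masks of at least three
#' quarters of participants (boundary inclusive).
#'
#' @param masks list of logical vectors (same length)
#' @export
group_gm_mask <- function(masks, quorum = 0.75) {
  if (!length(masks)) stop("need at least one individual mask")
  m <- do.call(rbind, masks)
  colMeans(m) >= quorum - 1e-12
}

#' Zeroth-order Tikhonov reconstruction operator
#'
#' Underdetermined form: x = J' (J J' + lambda^2 max(diag(J J')) I)^-1 y.
#' The operator is factored once and applied to every frame.
#'
#' @param J channel x node sensitivity matrix (restricted to the
#'   reconstruction support)
#' @param lambda_reg regularization hyperparameter (default 0.1)
#' @return node x channel reconstruction matrix
#' @export
recon_operator <- function(J, lambda_reg = 0.1) {
  if (nrow(J) == 0L) stop("empty channel set")
  M <- tcrossprod(J)
  A <- M + lambda_reg^2 * max(diag(M)) * diag(nrow(M))
  t(solve(A, J))
}

#' Reconstruct absorption-change images
#'
#' @param J channel x node sensitivity matrix
#' @param y channel x frame optical-density data
#' @inheritParams recon_operator
#' @return node x frame matrix of absorption changes
#' @export
reconstruct <- function(J, y, lambda_reg = 0.1) {
  y <- as.matrix(y)
  if (nrow(J) != nrow(y)) stop("channel dimensions of J and y differ")
  recon_operator(J, lambda_reg) %*% y
}

#' Convert per-node absorption changes to haemoglobin changes
#'
#' Per-node 2x2 extinction solve (the Beer-Lambert spectral system without
#' pathlength terms).
#'
#' @param mua_780,mua_850 node x frame absorption changes (mm^-1)
#' @param E extinction matrix in ln_uM_mm units
#' @return list with `hbo`, `hbr` (node x frame, micromolar)
#' @export
mua_to_hb <- function(mua_780, mua_850, E = extinction_matrix(units = "ln_uM_mm")) {
  if (abs(det(E)) < 1e-18) stop("singular extinction system")
  Ei <- solve(E)
  list(hbo = Ei[1L, 1L] * mua_780 + Ei[1L, 2L] * mua_850,
       hbr = Ei[2L, 1L] * mua_780 + Ei[2L, 2L] * mua_850)
}

#' Cortical image container
#'
#' Per-gm-surface-node HbO/HbR time courses (221 frames at 10 Hz for the
#' -2..20 s block).
#' @export
cortical_image <- function(hbo, hbr, node_ids, time, lambda_reg = 0.1,
                           group_mask_applied = FALSE) {
  stopifnot(nrow(hbo) == length(node_ids), ncol(hbo) == length(time))
  structure(list(hbo = hbo, hbr = hbr, node_ids = node_ids, time = time,
                 lambda_reg = lambda_reg,
                 group_mask_applied = group_mask_applied),
            class = "cortical_image")
}

#' Reconstruct a cortical image from a block average
#'
#' Converts the block-averaged haemoglobin back to optical density, runs the
#' per-wavelength Tikhonov reconstruction restricted to grey-matter volume
#' nodes, converts absorption to haemoglobin, and maps to the gm surface.
#'
#' @param block a [block_average()]
#' @param J a `sensitivity_matrix` for the subject geometry
#' @param mesh the matching `head_mesh`
#' @param age_years for the Beer-Lambert forward step
#' @param node_ids gm-surface nodes to image (default: all)
#' @export
reconstruct_image <- function(block, J, mesh, age_years, lambda_reg = 0.1,
                              node_ids = NULL, surf2vol = NULL) {
  if (is.null(surf2vol)) surf2vol <- gm_surface_to_volume(mesh)
  if (is.null(node_ids)) node_ids <- seq_len(nrow(mesh$gm$vertices))
  keep <- which(block$channel_mask & !is.na(block$hbo[, 1L]))
  if (!length(keep)) stop("no surviving channels to reconstruct from")
  od <- block_to_od(block, J$channels, age_years, J$wavelengths)
  gm_vol <- sort(unique(surf2vol))
  mua <- list()
  for (wl in as.character(J$wavelengths)) {
    Jg <- J$J[[wl]][keep, gm_vol, drop = FALSE]
    wi <- match(wl, as.character(J$wavelengths))
    yi <- matrix(od[keep, wi, ], nrow = length(keep))
    mua[[wl]] <- reconstruct(Jg, yi, lambda_reg)
  }
  hb <- mua_to_hb(mua[[1L]], mua[[2L]],
                  extinction_matrix(J$wavelengths, units = "ln_uM_mm"))
  row_of <- match(surf2vol[node_ids], gm_vol)
  cortical_image(hbo = hb$hbo[row_of, , drop = FALSE],
                 hbr = hb$hbr[row_of, , drop = FALSE],
                 node_ids = node_ids, time = block$time, lambda_reg)
}

#' Window-average a cortical image
#'
#' Temporal mean of each node over the response window (inclusive
#' endpoints; 12-16 s at 10 Hz averages 41 frames).
#'
#' @param image a [cortical_image()] (or a node x frame matrix with a
#'   matching `time`)
#' @param window two-element window (s)
#' @return list with `hbo`, `hbr` per-node means (or a vector for a matrix
#'   input)
#' @export
window_average_image <- function(image, window = c(12, 16), time = NULL) {
  if (is.matrix(image)) {
    idx <- which(time >= window[1L] - 1e-9 & time <= window[2L] + 1e-9)
    if (!length(idx)) stop("window outside the block")
    return(rowMeans(image[, idx, drop = FALSE]))
  }
  idx <- which(image$time >= window[1L] - 1e-9 &
               image$time <= window[2L] + 1e-9)
  if (!length(idx)) stop("window outside the block")
  list(hbo = rowMeans(image$hbo[, idx, drop = FALSE]),
       hbr = rowMeans(image$hbr[, idx, drop = FALSE]),
       node_ids = image$node_ids)
}
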