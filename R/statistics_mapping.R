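# Group-level node-wise and channel-wise T-statistic maps with Bonferroni
# correction, plus cortical projection of channel midpoints via
# Moller-Trumbore ray-triangle intersection.
#
# The concatenated two-sample t treats frames within the response and
# baseline windows of every participant as exchangeable observations.
# Successive frames are autocorrelated, so the effective sample size is
# overstated; no correction is applied, by design, to match the analysis
# convention this package reproduces. See the methods vignette.

#' T-statistic map container
#' @export
tstat_map <- function(domain = c("node", "channel"), ids, t, df, alpha,
                      significant, chromophore = "hbo", meta = list()) {
  domain <- match.arg(domain)
  structure(list(domain = domain, ids = ids, t = t, df = df, alpha = alpha,
                 significant = significant, chromophore = chromophore,
                 meta = meta),
            class = "tstat_map")
}

#' @export
print.tstat_map <- function(x, ...) {
  cat(sprintf("tstat_map (%s-wise, %s): %d elements, df=%d, corrected alpha=%.3g, %d significant\n",
              x$domain, x$chromophore, length(x$t), x$df, x$alpha,
              sum(x$significant, na.rm = TRUE)))
  invisible(x)
}

#' Per-subject window summary statistics
#'
#' Sufficient statistics (n, sum, sum of squares) of the response- and
#' baseline-window frames of each node, used by [node_tmap()] and the
#' combinatorial analysis.
#' @param values node x frame matrix
#' @param time frame times (s)
#' @export
window_summaries <- function(values, time, response = c(12, 16),
                             baseline = c(-2, 0)) {
  ri <- which(time >= response[1L] - 1e-9 & time <= response[2L] + 1e-9)
  bi <- which(time >= baseline[1L] - 1e-9 & time <= baseline[2L] + 1e-9)
  if (!length(ri) || !length(bi)) stop("windows outside the block")
  r <- values[, ri, drop = FALSE]; b <- values[, bi, drop = FALSE]
  list(n_r = length(ri), sum_r = rowSums(r), ss_r = rowSums(r^2),
       n_b = length(bi), sum_b = rowSums(b), ss_b = rowSums(b^2))
}

#' Pooled two-sample t from aggregated summaries
#' @keywords internal
t_from_summaries <- function(agg, var_equal = TRUE) {
  m1 <- agg$sum_r / agg$n_r; m2 <- agg$sum_b / agg$n_b
  v1 <- (agg$ss_r - agg$n_r * m1^2) / (agg$n_r - 1L)
  v2 <- (agg$ss_b - agg$n_b * m2^2) / (agg$n_b - 1L)
  v1 <- pmax(v1, 0); v2 <- pmax(v2, 0)
  if (var_equal) {
    sp2 <- ((agg$n_r - 1L) * v1 + (agg$n_b - 1L) * v2) /
      (agg$n_r + agg$n_b - 2L)
    se <- sqrt(sp2 * (1 / agg$n_r + 1 / agg$n_b))
    df <- rep(agg$n_r + agg$n_b - 2L, length(m1))
  } else {
    se <- sqrt(v1 / agg$n_r + v2 / agg$n_b)
    df <- se^4 / ((v1 / agg$n_r)^2 / (agg$n_r - 1L) +
                  (v2 / agg$n_b)^2 / (agg$n_b - 1L))
  }
  t <- (m1 - m2) / se
  t[se <= 0] <- NA_real_
  list(t = t, df = df)
}

aggregate_summaries <- function(summaries, subset = NULL) {
  if (is.null(subset)) subset <- seq_along(summaries)
  agg <- list(n_r = 0L, sum_r = 0, ss_r = 0, n_b = 0L, sum_b = 0, ss_b = 0)
  for (i in subset) {
    s <- summaries[[i]]
    agg$n_r <- agg$n_r + s$n_r; agg$sum_r <- agg$sum_r + s$sum_r
    agg$ss_r <- agg$ss_r + s$ss_r
    agg$n_b <- agg$n_b + s$n_b; agg$sum_b <- agg$sum_b + s$sum_b
    agg$ss_b <- agg$ss_b + s$ss_b
  }
  agg
}

#' Node-wise group T-statistic map
#'
#' For each node in the group mask, concatenates all response-window frames
#' across participants into one vector, likewise for the baseline window,
#' and compares them with a two-tailed two-sample t-test (pooled variance by
#' default). Bonferroni correction uses the total gm-surface node count.
#'
#' @param images list of [cortical_image()]s on a common node set
#' @param group_mask logical over the images' node ids
#' @param n_comparisons number of gm-surface mesh nodes for Bonferroni
#' @param chromophore "hbo" or "hbr"
#' @export
node_tmap <- function(images, group_mask, n_comparisons,
                      response = c(12, 16), baseline = c(-2, 0),
                      chromophore = c("hbo", "hbr"), alpha = 0.05,
                      var_equal = TRUE) {
  chromophore <- match.arg(chromophore)
  if (length(images) < 2L) stop("need at least two participants")
  summaries <- lapply(images, function(im)
    window_summaries(im[[chromophore]], im$time, response, baseline))
  agg <- aggregate_summaries(summaries)
  ts <- t_from_summaries(agg, var_equal)
  t <- ts$t; df <- ts$df[1L]
  t[!group_mask] <- NA_real_
  if (anyNA(t[group_mask]))
    warning("zero-variance nodes: t undefined, reported not significant")
  a_corr <- alpha / n_comparisons
  p <- 2 * stats::pt(-abs(t), df)
  sig <- !is.na(p) & p < a_corr & group_mask
  tstat_map("node", ids = images[[1L]]$node_ids, t = t, df = df,
            alpha = a_corr, significant = sig, chromophore = chromophore,
            meta = list(response = response, baseline = baseline,
                        n_subjects = length(images)))
}

#' Channel-wise group T-statistic map
#'
#' Channels must be present (not pruned) in at least three quarters of
#' participants to enter the analysis; Bonferroni correction uses the total
#' channel count of the array (34 for the bilateral infant array).
#'
#' @param blocks list of [block_average()]s
#' @param channels channel table
#' @export
channel_tmap <- function(blocks, channels, response = c(12, 16),
                         baseline = c(-2, 0), chromophore = c("hbo", "hbr"),
                         presence_quorum = 0.75, alpha = 0.05,
                         var_equal = TRUE) {
  chromophore <- match.arg(chromophore)
  if (length(blocks) < 2L) stop("need at least two participants")
  n_ch <- nrow(channels)
  field <- if (chromophore == "hbo") "hbo" else "hbr"
  present <- vapply(blocks, function(b)
    b$channel_mask & !is.na(b$hbo[, 1L]), logical(n_ch))
  frac <- rowMeans(present)
  keep <- frac >= presence_quorum - 1e-12
  t <- rep(NA_real_, n_ch); df <- NA_integer_
  for (k in which(keep)) {
    subs <- which(present[k, ])
    summaries <- lapply(blocks[subs], function(b)
      window_summaries(b[[field]][k, , drop = FALSE], b$time,
                       response, baseline))
    ts <- t_from_summaries(aggregate_summaries(summaries), var_equal)
    t[k] <- ts$t; df <- ts$df[1L]
  }
  a_corr <- alpha / n_ch
  p <- 2 * stats::pt(-abs(t), df)
  sig <- !is.na(p) & p < a_corr
  tstat_map("channel", ids = channels$id, t = t,
            df = if (is.na(df)) 0L else df, alpha = a_corr,
            significant = sig, chromophore = chromophore,
            meta = list(presence_fraction = frac, included = keep,
                        hemisphere = channels$hemisphere))
}

#' Moller-Trumbore ray-triangle intersection
#'
#' @param origin,direction ray (direction need not be unit)
#' @param v0,v1,v2 triangle vertices
#' @param eps parallelism tolerance
#' @return list with `hit`, `t` (ray parameter), `point`; a miss gives
#'   `hit = FALSE`
#' @export
ray_triangle_intersect <- function(origin, direction, v0, v1, v2,
                                   eps = 1e-12) {
  e1 <- v1 - v0; e2 <- v2 - v0
  p <- cross3(direction, e2)
  det <- sum(e1 * p)
  if (abs(det) < eps) return(list(hit = FALSE, t = NA_real_, point = NULL))
  inv <- 1 / det
  tv <- origin - v0
  u <- sum(tv * p) * inv
  if (u < -1e-12 || u > 1 + 1e-12)
    return(list(hit = FALSE, t = NA_real_, point = NULL))
  q <- cross3(tv, e1)
  v <- sum(direction * q) * inv
  if (v < -1e-12 || u + v > 1 + 1e-12)
    return(list(hit = FALSE, t = NA_real_, point = NULL))
  t <- sum(e2 * q) * inv
  if (t < eps) return(list(hit = FALSE, t = NA_real_, point = NULL))
  list(hit = TRUE, t = t, point = origin + t * direction)
}

# vectorized first positive hit over all faces of a surface
mt_first_hit <- function(origin, direction, surface) {
  v <- surface$vertices; f <- surface$faces
  v0 <- v[f[, 1L], , drop = FALSE]
  e1 <- v[f[, 2L], , drop = FALSE] - v0
  e2 <- v[f[, 3L], , drop = FALSE] - v0
  dmat <- matrix(direction, nrow(f), 3L, byrow = TRUE)
  p <- cbind(dmat[, 2L] * e2[, 3L] - dmat[, 3L] * e2[, 2L],
             dmat[, 3L] * e2[, 1L] - dmat[, 1L] * e2[, 3L],
             dmat[, 1L] * e2[, 2L] - dmat[, 2L] * e2[, 1L])
  det <- rowSums(e1 * p)
  tv <- sweep(-v0, 2L, origin, `+`)
  u <- rowSums(tv * p) / det
  q <- cbind(tv[, 2L] * e1[, 3L] - tv[, 3L] * e1[, 2L],
             tv[, 3L] * e1[, 1L] - tv[, 1L] * e1[, 3L],
             tv[, 1L] * e1[, 2L] - tv[, 2L] * e1[, 1L])
  vv <- rowSums(q * dmat) / det
  tt <- rowSums(e2 * q) / det
  ok <- is.finite(tt) & abs(det) > 1e-12 & u >= -1e-9 & vv >= -1e-9 &
    (u + vv) <= 1 + 1e-9 & tt > 1e-9
  if (!any(ok)) return(NULL)
  i <- which(ok)[which.min(tt[ok])]
  list(face = i, t = tt[i], point = origin + tt[i] * direction)
}

#' Project a channel's scalp midpoint to the cortical surface
#'
#' Fits a least-squares plane through the scalp nodes within `radius_mm` of
#' the midpoint, casts a ray along the plane normal, and takes the first
#' grey-matter surface face it intersects (Moller-Trumbore). The inward
#' direction is disambiguated by whichever of the two normal directions
#' actually hits the gm surface, so the result does not depend on mesh
#' orientation. The returned parcel label is that of the nearest gm vertex.
#'
#' @param mesh a `head_mesh`
#' @param midpoint channel scalp midpoint (mm)
#' @param radius_mm plane-fit neighbourhood radius (default 5)
#' @return list with `point`, `parcel`, `depth_mm`, `gm_vertex`
#' @export
project_channel_to_cortex <- function(mesh, midpoint, radius_mm = 5) {
  sv <- mesh$scalp$vertices
  d <- sqrt(rowSums(sweep(sv, 2L, midpoint, `-`)^2))
  near <- which(d <= radius_mm)
  if (length(near) < 3L)
    stop("fewer than 3 scalp nodes within ", radius_mm, " mm of the midpoint")
  pts <- sv[near, , drop = FALSE]
  ctr <- colMeans(pts)
  n <- svd(sweep(pts, 2L, ctr, `-`))$v[, 3L]
  hit1 <- mt_first_hit(midpoint, n, mesh$gm)
  hit2 <- mt_first_hit(midpoint, -n, mesh$gm)
  hit <- if (is.null(hit1)) hit2 else if (is.null(hit2)) hit1
         else if (hit1$t <= hit2$t) hit1 else hit2
  if (is.null(hit))
    stop("projection ray does not intersect the grey-matter surface")
  gd <- rowSums(sweep(mesh$gm$vertices, 2L, hit$point, `-`)^2)
  gi <- which.min(gd)
  list(point = hit$point, parcel = mesh$parcels[gi],
       depth_mm = hit$t, gm_vertex = gi)
}

#' @export
plot.tstat_map <- function(x, ...) {
  t <- x$t
  graphics::plot(seq_along(t), t, type = "h",
                 xlab = paste0(x$domain, " index"), ylab = "t", ...)
  thr <- stats::qt(1 - x$alpha / 2, x$df)
  graphics::abline(h = c(-thr, thr), lty = 2, col = "red3")
  sig <- which(x$significant)
  if (length(sig)) graphics::points(sig, t[sig], pch = 16, col = "red3")
  invisible(x)
}
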