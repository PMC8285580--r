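# Cross-stream comparison metrics: peak element extraction, peak node
# offset in a common reference space, Jaccard overlap of thresholded maps,
# focality curves, per-region |T| maxima, head-size correlations, and the
# combinatorial group-size analysis.

#' Peak element of a statistical or window-averaged map
#'
#' For oxy-haemoglobin the peak is the maximum positive value; for
#' deoxy-haemoglobin the maximum negative value. Ties break to the lowest
#' element id, deterministically.
#'
#' @param values per-element statistic (t or concentration change)
#' @param ids element ids (node indices or channel ids)
#' @param hemisphere_of per-element hemisphere ("left"/"right"), or `NULL`
#'   to search all elements
#' @param hemisphere restrict the search to one hemisphere
#' @param chromophore "hbo" (argmax) or "hbr" (argmin)
#' @param mask logical inclusion mask
#' @param coords optional element coordinates carried into the result
#' @param parcels optional per-element parcel labels
#' @return list of class `peak_result`
#' @export
peak_element <- function(values, ids = seq_along(values),
                         hemisphere_of = NULL, hemisphere = NULL,
                         chromophore = c("hbo", "hbr"), mask = NULL,
                         coords = NULL, parcels = NULL) {
  chromophore <- match.arg(chromophore)
  use <- !is.na(values)
  if (!is.null(mask)) use <- use & mask
  if (!is.null(hemisphere) && !is.null(hemisphere_of))
    use <- use & hemisphere_of == hemisphere
  if (!any(use)) stop("empty masked domain")
  v <- ifelse(use, values, NA_real_)
  target <- if (chromophore == "hbo") max(v, na.rm = TRUE)
            else min(v, na.rm = TRUE)
  cand <- which(!is.na(v) & abs(v - target) < 1e-15)
  i <- cand[which.min(ids[cand])]
  structure(list(element = ids[i], index = i, value = values[i],
                 chromophore = chromophore, hemisphere = hemisphere,
                 coords = if (!is.null(coords)) coords[i, ] else NULL,
                 parcel = if (!is.null(parcels)) parcels[i] else NULL),
            class = "peak_result")
}

#' Euclidean offset between two peak nodes in a reference space
#'
#' Both peaks are node ids on the common-topology mesh; the distance is
#' measured between those nodes' coordinates in the reference mesh (the
#' age-cohort constant-head-warp model).
#'
#' @param peak_a,peak_b `peak_result`s (or bare node ids)
#' @param reference_mesh a `head_mesh` supplying gm-surface coordinates
#' @return offset in mm
#' @export
peak_node_offset <- function(peak_a, peak_b, reference_mesh) {
  id_of <- function(p) if (inherits(p, "peak_result")) p$element else p
  a <- id_of(peak_a); b <- id_of(peak_b)
  n <- nrow(reference_mesh$gm$vertices)
  if (a < 1L || a > n || b < 1L || b > n)
    stop("peak node id outside the reference mesh gm surface")
  sqrt(sum((reference_mesh$gm$vertices[a, ] -
            reference_mesh$gm$vertices[b, ])^2))
}

#' Jaccard overlap of two thresholded maps (percent)
#'
#' Each map is thresholded at `threshold_fraction` of its own maximum
#' (default 50%); the Jaccard index is |A intersect B| / |A union B| x 100.
#'
#' @param map_a,map_b per-node values on the same node domain
#' @export
jaccard_overlap <- function(map_a, map_b, threshold_fraction = 0.5) {
  stopifnot(length(map_a) == length(map_b))
  sup <- function(v) {
    m <- max(v, na.rm = TRUE)
    !is.na(v) & v >= threshold_fraction * m
  }
  a <- sup(map_a); b <- sup(map_b)
  u <- sum(a | b)
  if (u == 0L) {
    warning("empty union: Jaccard undefined")
    return(NA_real_)
  }
  100 * sum(a & b) / u
}

#' Focality curve: supra-threshold surface area vs normalized threshold
#'
#' The map is normalized to its maximum; for each threshold the areas of
#' nodes at or above it are summed (node area = one third of adjacent face
#' areas). The curve is non-increasing in the threshold.
#'
#' @param values per-node map values
#' @param node_areas per-node areas (mm^2), e.g. `surface_areas(gm)$vertex`
#' @param thresholds normalized thresholds (default 0.50..0.90 step 0.05)
#' @return data frame with threshold, area_mm2
#' @export
focality_curve <- function(values, node_areas,
                           thresholds = seq(0.5, 0.9, by = 0.05)) {
  m <- max(values, na.rm = TRUE)
  norm <- values / m
  area <- vapply(thresholds, function(th)
    sum(node_areas[!is.na(norm) & norm >= th - 1e-12]), numeric(1))
  data.frame(threshold = thresholds, area_mm2 = area)
}

#' Per-region maximum |T| and paired stream difference
#'
#' @param t_values per-element |T| source values
#' @param region_of per-element region label
#' @param regions regions to report (default: all observed)
#' @return named vector of per-region max |t|; regions with no elements are
#'   absent
#' @export
regional_max_abs_t <- function(t_values, region_of, regions = NULL) {
  ok <- !is.na(t_values) & !is.na(region_of)
  if (is.null(regions)) regions <- sort(unique(region_of[ok]))
  out <- vapply(regions, function(r) {
    v <- abs(t_values[ok & region_of == r])
    if (!length(v)) NA_real_ else max(v)
  }, numeric(1))
  names(out) <- regions
  out[!is.na(out)]
}

#' Difference in per-region maxima between two streams
#'
#' Positive values mean stream A exceeds stream B in that region (the
#' channel-space-minus-image convention when A is channel space).
#' @export
regional_max_difference <- function(max_a, max_b) {
  common <- intersect(names(max_a), names(max_b))
  max_a[common] - max_b[common]
}

#' Head-size and growth-trajectory associations of peak node offset
#'
#' Pearson correlations (two-sided) between individual-level peak node
#' offset and: the signed circumference deviation from the group mean, its
#' absolute value, the change in circumference z-score, and its absolute
#' value.
#'
#' @param offsets per-subject peak node offsets (mm)
#' @param circumference_dev signed deviation from group mean (cm)
#' @param z_change change in circumference z-score (may be NULL)
#' @return data frame with comparison, r, p, n
#' @export
headsize_associations <- function(offsets, circumference_dev,
                                  z_change = NULL) {
  one <- function(x, y, label) {
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) < 3L)
      return(data.frame(comparison = label, r = NA_real_, p = NA_real_,
                        n = sum(ok)))
    if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
      warning("zero-variance input for ", label)
      return(data.frame(comparison = label, r = NA_real_, p = NA_real_,
                        n = sum(ok)))
    }
    ct <- stats::cor.test(x[ok], y[ok])
    data.frame(comparison = label, r = unname(ct$estimate),
               p = ct$p.value, n = sum(ok))
  }
  out <- rbind(one(offsets, circumference_dev, "circumference_dev"),
               one(offsets, abs(circumference_dev), "abs_circumference_dev"))
  if (!is.null(z_change))
    out <- rbind(out, one(offsets, z_change, "z_change"),
                 one(offsets, abs(z_change), "abs_z_change"))
  rownames(out) <- NULL
  out
}

#' Combinatorial group-size analysis
#'
#' For each sub-cohort size, draws replicates of subjects without
#' replacement, recomputes the group T-statistic map per stream from the
#' per-subject window summaries, and records the peak node offset between
#' the two streams and whether their peak cortical labels match. At the
#' full cohort size there is a single distinct combination, so one
#' replicate is used.
#'
#' @param summaries_a,summaries_b per-subject [window_summaries()] lists for
#'   the two streams (same subject ordering)
#' @param node_ids gm-surface node ids the summaries are defined on
#' @param group_mask logical over `node_ids`
#' @param reference_mesh `head_mesh` supplying reference coordinates
#' @param hemisphere "left" or "right" (nodes split by the sign of x)
#' @param sizes sub-cohort sizes (default 10..N)
#' @param reps replicates per size (default 100)
#' @param seed master seed; per-size streams derive from it
#' @param chromophore "hbo" or "hbr"
#' @return data frame of class `combinatorial_result`: size, mean_offset,
#'   se_offset, mismatch_prop, n_reps
#' @export
combinatorial_analysis <- function(summaries_a, summaries_b, node_ids,
                                   group_mask, reference_mesh,
                                   hemisphere = "right", sizes = NULL,
                                   reps = 100L, seed = 1L,
                                   chromophore = "hbo") {
  n <- length(summaries_a)
  if (length(summaries_b) != n) stop("stream subject lists differ in length")
  if (n < 10L) stop("cohort size must be at least 10")
  if (is.null(sizes)) sizes <- 10:n
  if (any(sizes > n)) stop("sub-cohort size exceeds the cohort size")
  coords <- reference_mesh$gm$vertices[node_ids, , drop = FALSE]
  hemi_of <- ifelse(coords[, 1L] > 0, "right", "left")
  parc <- reference_mesh$parcels[node_ids]
  use <- group_mask & hemi_of == hemisphere
  if (!any(use)) stop("empty masked domain in hemisphere ", hemisphere)
  peak_of <- function(summ, subset) {
    agg <- aggregate_summaries(summ, subset)
    t <- t_from_summaries(agg)$t
    peak_element(t, ids = node_ids, chromophore = chromophore, mask = use,
                 parcels = parc)
  }
  rows <- lapply(seq_along(sizes), function(si) {
    sz <- sizes[si]
    nr <- if (sz >= n) 1L else as.integer(reps)
    set.seed((seed + 7919L * si) %% .Machine$integer.max)
    off <- numeric(nr); mism <- logical(nr)
    for (r in seq_len(nr)) {
      subset <- if (sz >= n) seq_len(n) else sample.int(n, sz)
      pa <- peak_of(summaries_a, subset)
      pb <- peak_of(summaries_b, subset)
      off[r] <- peak_node_offset(pa, pb, reference_mesh)
      mism[r] <- !identical(pa$parcel, pb$parcel)
    }
    data.frame(size = sz, mean_offset = mean(off),
               se_offset = if (nr > 1L) stats::sd(off) / sqrt(nr) else 0,
               mismatch_prop = mean(mism), n_reps = nr)
  })
  out <- do.call(rbind, rows)
  attr(out, "seed") <- seed
  attr(out, "hemisphere") <- hemisphere
  class(out) <- c("combinatorial_result", "data.frame")
  out
}

#' @export
plot.combinatorial_result <- function(x, ...) {
  graphics::plot(x$size, x$mean_offset, type = "b", pch = 16,
                 xlab = "sub-cohort size", ylab = "mean peak node offset (mm)",
                 ylim = range(0, x$mean_offset + x$se_offset), ...)
  graphics::arrows(x$size, x$mean_offset - x$se_offset,
                   x$size, x$mean_offset + x$se_offset,
                   angle = 90, code = 3, length = 0.03, col = "red3")
  invisible(x)
}
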