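# Low-level triangulated-surface geometry: lat-long sphere meshes, planar
# sections of closed surfaces, and arc-length parameterized polylines.
# All coordinates are in mm.

#' Unit lat-long sphere mesh
#'
#' Builds a triangulated unit sphere on a latitude/longitude grid. With
#' `n_lon` a multiple of 4 the six axis points (+-x, +-y, +-z) are exact
#' vertices, which keeps phantom landmarks on the mesh.
#'
#' @param n_lat number of latitude rings including both poles (>= 5, odd so
#'   the equator is a ring)
#' @param n_lon number of longitude steps (multiple of 4 recommended)
#' @return list with `vertices` (n x 3) and `faces` (m x 3, 1-based)
#' @keywords internal
uv_sphere <- function(n_lat = 33L, n_lon = 48L) {
  stopifnot(n_lat >= 5L, n_lon >= 8L)
  theta <- seq(0, pi, length.out = n_lat)       # 0 = +z pole
  phi <- seq(0, 2 * pi, length.out = n_lon + 1L)[-(n_lon + 1L)]
  rings <- theta[-c(1L, n_lat)]
  v <- matrix(0, nrow = 2L + length(rings) * n_lon, ncol = 3L)
  v[1L, ] <- c(0, 0, 1)
  idx <- 2L
  for (th in rings) {
    v[idx:(idx + n_lon - 1L), ] <- cbind(sin(th) * cos(phi),
                                         sin(th) * sin(phi),
                                         rep(cos(th), n_lon))
    idx <- idx + n_lon
  }
  v[idx, ] <- c(0, 0, -1)
  south <- idx
  ring_start <- function(i) 2L + (i - 1L) * n_lon  # i-th interior ring
  faces <- list()
  # top cap
  r1 <- ring_start(1L)
  j <- seq_len(n_lon)
  jn <- c(seq_len(n_lon)[-1L], 1L)
  faces[[1L]] <- cbind(1L, r1 + j - 1L, r1 + jn - 1L)
  # bands
  nb <- length(rings)
  if (nb > 1L) {
    for (i in seq_len(nb - 1L)) {
      a <- ring_start(i); b <- ring_start(i + 1L)
      faces[[length(faces) + 1L]] <- cbind(a + j - 1L, b + j - 1L, b + jn - 1L)
      faces[[length(faces) + 1L]] <- cbind(a + j - 1L, b + jn - 1L, a + jn - 1L)
    }
  }
  # bottom cap
  rl <- ring_start(nb)
  faces[[length(faces) + 1L]] <- cbind(south, rl + jn - 1L, rl + j - 1L)
  list(vertices = v, faces = do.call(rbind, faces))
}

#' Triangulated ellipsoid surface
#' @param semi_axes length-3 positive semi-axes (mm)
#' @inheritParams uv_sphere
#' @keywords internal
ellipsoid_surface <- function(semi_axes, n_lat = 33L, n_lon = 48L) {
  s <- uv_sphere(n_lat, n_lon)
  s$vertices <- sweep(s$vertices, 2L, semi_axes, `*`)
  s
}

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("cannot normalize a near-zero vector")
  v / n
}

#' Per-face and per-vertex areas of a triangulated surface
#'
#' Vertex area is one third of the summed areas of adjacent faces, the usual
#' barycentric lumping.
#' @keywords internal
surface_areas <- function(surface) {
  v <- surface$vertices; f <- surface$faces
  e1 <- v[f[, 2L], , drop = FALSE] - v[f[, 1L], , drop = FALSE]
  e2 <- v[f[, 3L], , drop = FALSE] - v[f[, 1L], , drop = FALSE]
  cx <- e1[, 2L] * e2[, 3L] - e1[, 3L] * e2[, 2L]
  cy <- e1[, 3L] * e2[, 1L] - e1[, 1L] * e2[, 3L]
  cz <- e1[, 1L] * e2[, 2L] - e1[, 2L] * e2[, 1L]
  fa <- 0.5 * sqrt(cx^2 + cy^2 + cz^2)
  va <- numeric(nrow(v))
  for (k in 1:3) {
    t <- tapply(fa, f[, k], sum)
    va[as.integer(names(t))] <- va[as.integer(names(t))] + t
  }
  list(face = fa, vertex = va / 3)
}

#' Intersection of a closed triangulated surface with a plane
#'
#' Returns the section as one or more closed polyline loops. Segment
#' endpoints are matched through shared mesh edges so loops are exact.
#'
#' @param surface list(vertices, faces)
#' @param p0 a point on the plane
#' @param normal plane normal (any length)
#' @return list of loops; each loop is a closed point matrix (last row not
#'   repeating the first)
#' @keywords internal
surface_section <- function(surface, p0, normal) {
  v <- surface$vertices; f <- surface$faces
  n <- unit(normal)
  d <- as.numeric(v %*% n) - sum(p0 * n)
  d[abs(d) < 1e-12] <- 1e-12
  s <- d > 0
  cr <- (s[f[, 1L]] + s[f[, 2L]] + s[f[, 3L]])
  crossed <- which(cr == 1L | cr == 2L)
  if (!length(crossed)) return(list())
  edge_key <- function(i, j) paste0(pmin(i, j), "_", pmax(i, j))
  seg_keys <- matrix("", nrow = length(crossed), ncol = 2L)
  pts <- new.env(parent = emptyenv())
  for (k in seq_along(crossed)) {
    tri <- f[crossed[k], ]
    ij <- combn(tri, 2L)
    keys <- character(0)
    for (e in 1:3) {
      i <- ij[1L, e]; j <- ij[2L, e]
      if (s[i] != s[j]) {
        key <- edge_key(i, j)
        keys <- c(keys, key)
        if (is.null(pts[[key]])) {
          t <- d[i] / (d[i] - d[j])
          pts[[key]] <- v[i, ] + t * (v[j, ] - v[i, ])
        }
      }
    }
    seg_keys[k, ] <- keys[1:2]
  }
  # adjacency: each key borders exactly two crossed faces on a closed surface
  key_to_segs <- split(rep(seq_len(nrow(seg_keys)), 2L), as.vector(seg_keys))
  used <- logical(nrow(seg_keys))
  loops <- list()
  for (start in seq_len(nrow(seg_keys))) {
    if (used[start]) next
    used[start] <- TRUE
    chain <- c(seg_keys[start, 1L], seg_keys[start, 2L])
    repeat {
      cur <- chain[length(chain)]
      cands <- key_to_segs[[cur]]
      nxt <- cands[!used[cands]]
      if (!length(nxt)) break
      nxt <- nxt[1L]
      used[nxt] <- TRUE
      other <- setdiff(seg_keys[nxt, ], cur)
      if (!length(other)) other <- cur  # degenerate segment
      chain <- c(chain, other[1L])
    }
    if (chain[1L] == chain[length(chain)]) chain <- chain[-length(chain)]
    loop <- do.call(rbind, lapply(chain, function(k) pts[[k]]))
    if (nrow(loop) >= 3L) loops[[length(loops) + 1L]] <- loop
  }
  loops
}

# ---- polyline helpers -------------------------------------------------------

polyline_cumlen <- function(pts, closed = FALSE) {
  if (closed) pts <- rbind(pts, pts[1L, ])
  d <- sqrt(rowSums((pts[-1L, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE])^2))
  c(0, cumsum(d))
}

polyline_length <- function(pts, closed = FALSE) {
  cl <- polyline_cumlen(pts, closed)
  cl[length(cl)]
}

#' Point at arc length s along an open polyline
#' @keywords internal
point_at_arc <- function(pts, s, closed = FALSE) {
  cl <- polyline_cumlen(pts, closed)
  L <- cl[length(cl)]
  if (closed) {
    s <- s %% L
    pts <- rbind(pts, pts[1L, ])
  } else {
    if (s < -1e-9 || s > L + 1e-9)
      stop("arc position outside the curve domain")
    s <- min(max(s, 0), L)
  }
  i <- findInterval(s, cl, rightmost.closed = TRUE)
  i <- min(max(i, 1L), nrow(pts) - 1L)
  seg <- cl[i + 1L] - cl[i]
  t <- if (seg > 0) (s - cl[i]) / seg else 0
  pts[i, ] + t * (pts[i + 1L, ] - pts[i, ])
}

#' Nearest point on a polyline, with its arc-length position
#' @keywords internal
nearest_on_polyline <- function(pts, p, closed = FALSE) {
  work <- if (closed) rbind(pts, pts[1L, ]) else pts
  a <- work[-nrow(work), , drop = FALSE]
  b <- work[-1L, , drop = FALSE]
  ab <- b - a
  ap <- sweep(-a, 2L, p, `+`)
  len2 <- rowSums(ab^2)
  t <- ifelse(len2 > 0, rowSums(ap * ab) / len2, 0)
  t <- pmin(pmax(t, 0), 1)
  proj <- a + ab * t
  d2 <- rowSums(sweep(proj, 2L, p, `-`)^2)
  i <- which.min(d2)
  cl <- polyline_cumlen(pts, closed)
  seg <- sqrt(len2[i])
  list(point = proj[i, ], s = cl[i] + t[i] * seg, dist = sqrt(d2[i]), index = i)
}

#' Extract the sub-polyline of a closed loop between two arc positions
#'
#' Walks forward from `sa` to `sb` (wrapping); returns the open polyline
#' including both endpoints.
#' @keywords internal
subpolyline <- function(loop, sa, sb) {
  cl <- polyline_cumlen(loop, closed = TRUE)
  L <- cl[length(cl)]
  sa <- sa %% L; sb <- sb %% L
  pa <- point_at_arc(loop, sa, closed = TRUE)
  pb <- point_at_arc(loop, sb, closed = TRUE)
  if (abs(sa - sb) < 1e-12) return(rbind(pa, pb))
  span <- (sb - sa) %% L
  cl_v <- cl[seq_len(nrow(loop))]
  inner <- which(cl_v > sa + 1e-9 & cl_v < sa + span - 1e-9)
  mid <- loop[inner, , drop = FALSE]
  if (sa + span > L) {  # wrapped: also take points from the start
    inner2 <- which(cl_v + L > sa + 1e-9 & cl_v + L < sa + span - 1e-9)
    mid <- rbind(mid, loop[inner2, , drop = FALSE])
  }
  rbind(pa, mid, pb)
}

#' Trace the scalp curve between two points (curve walk)
#'
#' Realized as the planar-section trace: the cutting plane contains `start`,
#' `end` and `plane_ref`. The section of a closed surface is a closed loop;
#' the returned path is the arc between `start` and `end` passing nearest
#' `guide` (default `plane_ref`), or the shorter arc when `guide` is `NA`.
#'
#' @param surface list(vertices, faces), a closed triangulated surface
#' @param start,end 3D points on (or near) the surface
#' @param plane_ref third point defining the cutting plane
#' @param guide point used to disambiguate the two arcs, or `NA` for the
#'   shorter arc
#' @return list with `points`, `cumlen`, `length` (mm)
#' @export
curve_walk <- function(surface, start, end, plane_ref, guide = plane_ref) {
  start <- as.numeric(start); end <- as.numeric(end)
  if (sqrt(sum((start - end)^2)) < 1e-9) {
    pts <- rbind(start, end)
    return(list(points = pts, cumlen = c(0, 0), length = 0))
  }
  n <- cross3(end - start, as.numeric(plane_ref) - start)
  if (sqrt(sum(n^2)) < 1e-9)
    stop("plane reference point is collinear with start and end")
  loops <- surface_section(surface, start, n)
  if (!length(loops))
    stop("surface section is empty; surface may be disconnected between endpoints")
  score <- vapply(loops, function(lp) {
    min(rowSums(sweep(lp, 2L, start, `-`)^2)) +
      min(rowSums(sweep(lp, 2L, end, `-`)^2))
  }, numeric(1))
  loop <- loops[[which.min(score)]]
  na <- nearest_on_polyline(loop, start, closed = TRUE)
  nb <- nearest_on_polyline(loop, end, closed = TRUE)
  arc1 <- subpolyline(loop, na$s, nb$s)
  arc2 <- subpolyline(loop, nb$s, na$s)
  arc2 <- arc2[rev(seq_len(nrow(arc2))), , drop = FALSE]
  pick <- if (length(guide) == 1L && is.na(guide[1L])) {
    if (polyline_length(arc1) <= polyline_length(arc2)) arc1 else arc2
  } else {
    g <- as.numeric(guide)
    d1 <- min(rowSums(sweep(arc1, 2L, g, `-`)^2))
    d2 <- min(rowSums(sweep(arc2, 2L, g, `-`)^2))
    if (d1 <= d2) arc1 else arc2
  }
  cl <- polyline_cumlen(pick)
  list(points = pick, cumlen = cl, length = cl[length(cl)])
}

#' Closed section loop through a point
#'
#' Full closed scalp trace of the plane through `p0` with the given normal;
#' used for circumference measurement and for the optode placement curves.
#' @return list with `points` (closed loop), `length` (closed length, mm)
#' @keywords internal
closed_section_loop <- function(surface, p0, normal) {
  loops <- surface_section(surface, p0, normal)
  if (!length(loops)) stop("surface section is empty")
  score <- vapply(loops, function(lp)
    min(rowSums(sweep(lp, 2L, as.numeric(p0), `-`)^2)), numeric(1))
  loop <- loops[[which.min(score)]]
  list(points = loop, length = polyline_length(loop, closed = TRUE))
}
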