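# Plain-text serialization of the package's containers: PLY surfaces with a
# sidecar parcel CSV, landmark/placement CSV dialects, and a directory-based
# scan format (CSV matrices + JSON manifest).

#' Write a triangulated surface as ASCII PLY
#'
#' @param surface list(vertices, faces)
#' @param path output file
#' @param parcels optional per-vertex labels written to a sidecar CSV
#'   (`<path>.parcels.csv`)
#' @export
write_surface_ply <- function(surface, path, parcels = NULL) {
  v <- surface$vertices; f <- surface$faces
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               paste("element vertex", nrow(v)),
               "property float x", "property float y", "property float z",
               paste("element face", nrow(f)),
               "property list uchar int vertex_indices", "end_header"), con)
  utils::write.table(format(v, trim = TRUE, scientific = FALSE), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  utils::write.table(cbind(3L, f - 1L), con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  if (!is.null(parcels))
    utils::write.csv(data.frame(vertex = seq_len(nrow(v)), parcel = parcels),
                     paste0(path, ".parcels.csv"), row.names = FALSE)
  invisible(path)
}

#' Read an ASCII PLY surface written by [write_surface_ply()]
#' @export
read_surface_ply <- function(path) {
  lines <- readLines(path)
  nv <- as.integer(sub("element vertex ", "",
                       grep("^element vertex", lines, value = TRUE)))
  nf <- as.integer(sub("element face ", "",
                       grep("^element face", lines, value = TRUE)))
  hdr <- which(lines == "end_header")
  v <- matrix(scan(text = lines[(hdr + 1L):(hdr + nv)], quiet = TRUE),
              nv, 3L, byrow = TRUE)
  fr <- matrix(scan(text = lines[(hdr + nv + 1L):(hdr + nv + nf)],
                    quiet = TRUE), nf, 4L, byrow = TRUE)
  out <- list(vertices = v, faces = fr[, 2:4] + 1L)
  pf <- paste0(path, ".parcels.csv")
  if (file.exists(pf)) attr(out, "parcels") <- utils::read.csv(pf)$parcel
  out
}

#' Write landmarks as the 5-row CSV dialect (name, x, y, z in mm)
#' @export
write_landmarks_csv <- function(landmarks, path) {
  utils::write.csv(data.frame(name = rownames(landmarks),
                              x = landmarks[, 1L], y = landmarks[, 2L],
                              z = landmarks[, 3L]),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read a landmarks CSV
#' @export
read_landmarks_csv <- function(path) {
  d <- utils::read.csv(path)
  m <- as.matrix(d[, c("x", "y", "z")])
  rownames(m) <- d$name
  m
}

#' Write per-subject placement measurements as CSV
#' @param placements data frame with subject, hemisphere, x_disp_cm,
#'   y_disp_cm
#' @export
write_placements_csv <- function(placements, path) {
  utils::write.csv(placements, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_placements_csv
#' @export
read_placements_csv <- function(path) utils::read.csv(path)

#' Write a raw scan to a directory (CSV matrices + JSON manifest)
#'
#' @param scan a [raw_scan()]
#' @param dir output directory (created if needed)
#' @export
write_scan <- function(scan, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (w in seq_along(scan$wavelengths))
    utils::write.table(
      scan$intensity[, w, ],
      file.path(dir, sprintf("intensity_%dnm.csv", scan$wavelengths[w])),
      sep = ",", row.names = FALSE, col.names = FALSE)
  utils::write.csv(scan$channels, file.path(dir, "channels.csv"),
                   row.names = FALSE)
  ev <- scan$events
  ev$looking <- scan$looking
  utils::write.csv(ev, file.path(dir, "events.csv"), row.names = FALSE)
  manifest <- list(wavelengths = scan$wavelengths, fs = scan$fs,
                   n_channels = dim(scan$intensity)[1L],
                   n_samples = dim(scan$intensity)[3L],
                   subject = scan$subject)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a scan directory written by [write_scan()]
#' @export
read_scan <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  channels <- utils::read.csv(file.path(dir, "channels.csv"),
                              stringsAsFactors = FALSE)
  ev <- utils::read.csv(file.path(dir, "events.csv"),
                        stringsAsFactors = FALSE)
  looking <- ev$looking
  ev$looking <- NULL
  inten <- array(NA_real_,
                 dim = c(man$n_channels, length(man$wavelengths),
                         man$n_samples))
  for (w in seq_along(man$wavelengths))
    inten[, w, ] <- as.matrix(utils::read.table(
      file.path(dir, sprintf("intensity_%dnm.csv", man$wavelengths[w])),
      sep = ","))
  raw_scan(intensity = inten, wavelengths = man$wavelengths, fs = man$fs,
           channels = channels, events = ev, looking = looking,
           subject = as.list(man$subject))
}
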