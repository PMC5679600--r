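# Formatting is pinned so identical runs produce byte-identical files:
# CSV/VTK/PLY use 9 significant digits; OBJ stores full (17-digit) precision
# so a resumed phase sees bit-exact vertex coordinates.

#' Write a mesh as Wavefront OBJ
#'
#' Plain `v`/`f` records with 1-based vertex indices; coordinates at full
#' double precision so that [readOBJ()] round-trips bit-exactly.
#'
#' @param mesh a [SurfaceMesh-class].
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeOBJ <- function(mesh, path) {
  stopifnot(is(mesh, "SurfaceMesh"))
  v <- mesh@vertices; tr <- mesh@triangles
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("v %.17g %.17g %.17g", v[, 1], v[, 2], v[, 3]), con)
  if (nrow(tr))
    writeLines(sprintf("f %d %d %d", tr[, 1], tr[, 2], tr[, 3]), con)
  invisible(path)
}

#' Read a Wavefront OBJ mesh
#'
#' Supports the `v`/`f` subset written by [writeOBJ()] (triangular faces,
#' plain indices); rebuilds first-ring adjacency.
#'
#' @param path OBJ file.
#' @return a [SurfaceMesh-class].
#' @export
readOBJ <- function(path) {
  if (!file.exists(path)) stop("mesh file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  vl <- lines[startsWith(lines, "v ")]
  fl <- lines[startsWith(lines, "f ")]
  vs <- do.call(rbind, lapply(strsplit(vl, "[[:space:]]+"), function(t)
    as.numeric(t[2:4])))
  fs <- do.call(rbind, lapply(strsplit(fl, "[[:space:]]+"), function(t)
    as.integer(sub("/.*", "", t[2:4]))))
  if (is.null(fs)) fs <- matrix(0L, 0, 3)
  new("SurfaceMesh", vertices = vs, triangles = fs,
      adjacency = .buildAdjacency(nrow(vs), fs))
}

#' Write a mesh with per-vertex attributes as ASCII PLY
#'
#' Vertex properties beyond x/y/z come from the optional attribute
#' data.frame (numeric columns only; e.g. curvatures for color-mapped
#' inspection in a viewer).
#'
#' @param mesh a [SurfaceMesh-class].
#' @param path output file.
#' @param attrs optional data.frame with one row per vertex.
#' @param columns which attribute columns to include (default: all numeric).
#' @return \code{path}, invisibly.
#' @export
writePLY <- function(mesh, path, attrs = NULL, columns = NULL) {
  stopifnot(is(mesh, "SurfaceMesh"))
  v <- mesh@vertices; tr <- mesh@triangles
  extra <- NULL
  if (!is.null(attrs)) {
    columns <- columns %||% names(attrs)[vapply(attrs, is.numeric,
                                                logical(1))]
    extra <- attrs[, columns, drop = FALSE]
    stopifnot(nrow(extra) == nrow(v))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               paste("element vertex", nrow(v)),
               "property float x", "property float y", "property float z",
               if (!is.null(extra))
                 paste("property float", gsub("[^A-Za-z0-9_]", "_",
                                              names(extra))),
               paste("element face", nrow(tr)),
               "property list uchar int vertex_indices", "end_header"), con)
  vmat <- if (is.null(extra)) v else cbind(v, as.matrix(extra))
  writeLines(apply(vmat, 1, function(r)
    paste(sprintf("%.9g", r), collapse = " ")), con)
  if (nrow(tr))
    writeLines(sprintf("3 %d %d %d", tr[, 1] - 1L, tr[, 2] - 1L,
                       tr[, 3] - 1L), con)
  invisible(path)
}

#' Write crest polylines as VTK legacy POLYDATA
#'
#' POINTS are the crest points; LINES are the linked polylines (0-based
#' indices), readable by ParaView and friends.
#'
#' @param crest a [CrestSet-class] with polylines linked.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeVTKLines <- function(crest, path) {
  stopifnot(is(crest, "CrestSet"))
  p <- crest@points
  pl <- crest@polylines
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "crest lines", "ASCII",
               "DATASET POLYDATA", paste("POINTS", nrow(p), "float")), con)
  writeLines(sprintf("%.9g %.9g %.9g", p[, 1], p[, 2], p[, 3]), con)
  total <- sum(lengths(pl)) + length(pl)
  writeLines(paste("LINES", length(pl), total), con)
  for (ch in pl)
    writeLines(paste(c(length(ch), ch - 1L), collapse = " "), con)
  writeLines(c(paste("POINT_DATA", nrow(p)),
               "SCALARS gaussian_curvature float 1",
               "LOOKUP_TABLE default"), con)
  writeLines(sprintf("%.9g", crest@info$K), con)
  writeLines(c("SCALARS curvedness float 1", "LOOKUP_TABLE default"), con)
  writeLines(sprintf("%.9g", crest@info$C), con)
  invisible(path)
}

#' Write crest points as CSV
#'
#' Columns: point id, coordinates, interpolated Gaussian curvature and
#' curvedness, and the id of the polyline the point belongs to (NA for
#' points in no chain).
#'
#' @param crest a [CrestSet-class].
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeCrestCSV <- function(crest, path) {
  stopifnot(is(crest, "CrestSet"))
  np <- nrow(crest@points)
  poly <- rep(NA_integer_, np)
  for (i in seq_along(crest@polylines))
    poly[crest@polylines[[i]]] <- i
  df <- data.frame(point = seq_len(np),
                   x = .fmtNum(crest@points[, 1]),
                   y = .fmtNum(crest@points[, 2]),
                   z = .fmtNum(crest@points[, 3]),
                   K = .fmtNum(crest@info$K), C = .fmtNum(crest@info$C),
                   polyline = poly)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write landmarks as CSV and JSON
#'
#' The CSV has one row per landmark (columns \code{landmark, x, y, z, K, C,
#' cluster, candidate}); the JSON additionally embeds the full provenance
#' block (thresholds, seeds, chosen K, silhouette table) so a result is
#' self-describing.
#'
#' @param lms a [LandmarkSet-class].
#' @param path output file; \code{writeLandmarksJSON} replaces the
#'   extension with \code{.json} if given a csv path.
#' @return \code{path}, invisibly.
#' @export
writeLandmarksCSV <- function(lms, path) {
  stopifnot(is(lms, "LandmarkSet"))
  lm <- lms@landmarks
  df <- data.frame(landmark = seq_len(nrow(lm)),
                   x = .fmtNum(lm$x), y = .fmtNum(lm$y), z = .fmtNum(lm$z),
                   K = .fmtNum(lm$K), C = .fmtNum(lm$C),
                   cluster = lm$cluster, candidate = lm$candidate)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeLandmarksCSV
#' @export
writeLandmarksJSON <- function(lms, path) {
  stopifnot(is(lms, "LandmarkSet"))
  obj <- list(landmarks = lms@landmarks,
              chosen_k = lms@chosenK,
              silhouette_by_k = as.list(lms@silhouettes),
              provenance = lms@provenance)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
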