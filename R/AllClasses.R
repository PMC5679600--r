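#' @import methods
NULL

#' VolumeGrid: a regular 3D scalar grid
#'
#' Container for a discrete scalar volume \eqn{p = v(x, y, z)}: a dense 3D
#' array of intensities on a regular lattice, with per-axis voxel spacing and
#' a world-space origin. Index coordinates are 0-based; lattice node
#' \eqn{(i, j, k)} sits at world position \code{origin + c(i, j, k) * spacing},
#' so anisotropic voxels (e.g. CT with coarser slice spacing) are handled by
#' doing all geometry in world space.
#'
#' @slot data 3D numeric array, dimensions \code{(nx, ny, nz)}, all >= 2.
#' @slot spacing numeric(3), positive voxel edge lengths per axis.
#' @slot origin numeric(3), world position of lattice node (0, 0, 0).
#'
#' @seealso [volumeGrid()], [readAsciiVolume()], [scalarField()]
#' @exportClass VolumeGrid
setClass("VolumeGrid",
  representation(data = "array", spacing = "numeric", origin = "numeric"),
  prototype(spacing = c(1, 1, 1), origin = c(0, 0, 0))
)

setValidity("VolumeGrid", function(object) {
  d <- dim(object@data)
  if (length(d) != 3L)
    return("'data' must be a 3D array")
  if (any(d < 2L))
    return("all grid dimensions must be >= 2")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    return("'spacing' must be 3 positive finite numbers")
  if (length(object@origin) != 3L || any(!is.finite(object@origin)))
    return("'origin' must be 3 finite numbers")
  if (!is.numeric(object@data) || anyNA(object@data))
    return("'data' must be numeric with no missing values")
  TRUE
})

#' ScalarField: a continuous implicit field with an isovalue
#'
#' Virtual parent of the two field flavours used throughout the pipeline.
#' A field evaluates as \eqn{F(q) = value(q) - p_c}; the isosurface of
#' interest is the zero set of \eqn{F}. The sign convention everywhere is
#' inside-positive: \eqn{F > 0} in the interior of the object.
#'
#' \code{GridField} wraps a [VolumeGrid-class] and evaluates by full 8-corner
#' tri-linear interpolation of the containing cell, so \eqn{F} at a lattice
#' node equals the stored intensity minus the isovalue exactly.
#' \code{AnalyticField} wraps a vectorized function of an n-by-3 matrix of
#' world coordinates.
#'
#' @slot isovalue scalar \eqn{p_c} subtracted from the raw field value.
#' @slot lower,upper numeric(3) world-space bounds of the evaluable domain.
#'
#' @aliases GridField-class AnalyticField-class
#' @seealso [scalarField()], [fieldValue()]
#' @exportClass ScalarField
setClass("ScalarField",
  representation("VIRTUAL", isovalue = "numeric",
                 lower = "numeric", upper = "numeric"))

#' @exportClass GridField
setClass("GridField", contains = "ScalarField",
  representation(grid = "VolumeGrid"))

#' @exportClass AnalyticField
setClass("AnalyticField", contains = "ScalarField",
  representation(fun = "function"))

setValidity("ScalarField", function(object) {
  if (length(object@isovalue) != 1L || !is.finite(object@isovalue))
    return("'isovalue' must be a single finite number")
  if (length(object@lower) != 3L || length(object@upper) != 3L)
    return("'lower' and 'upper' must be numeric(3)")
  if (any(object@upper <= object@lower))
    return("'upper' must exceed 'lower' on every axis")
  TRUE
})

#' AnalyticShape: a closed surface with known differential geometry
#'
#' Parametric description of a synthetic test shape whose implicit field and
#' closed-form curvatures are available: sphere, ellipsoid, superellipsoid
#' (the "smooth cube": corners and edges rounded by an even exponent), or
#' torus. Used to generate fixtures with a known answer for every stage of
#' the pipeline.
#'
#' @slot kind one of \code{"sphere"}, \code{"ellipsoid"},
#'   \code{"superellipsoid"}, \code{"torus"}.
#' @slot center numeric(3) world-space center.
#' @slot parameters named list; see [analyticShape()].
#'
#' @seealso [analyticShape()], [analyticField()], [voxelize()],
#'   [expectedGeometry()]
#' @exportClass AnalyticShape
setClass("AnalyticShape",
  representation(kind = "character", center = "numeric", parameters = "list"))

setValidity("AnalyticShape", function(object) {
  kinds <- c("sphere", "ellipsoid", "superellipsoid", "torus")
  if (length(object@kind) != 1L || !(object@kind %in% kinds))
    return(paste0("'kind' must be one of: ", paste(kinds, collapse = ", ")))
  if (length(object@center) != 3L || any(!is.finite(object@center)))
    return("'center' must be numeric(3)")
  p <- object@parameters
  sizes <- unlist(p[names(p) %in% c("radius", "semiaxes", "halfwidth",
                                    "ring", "tube")])
  if (any(sizes <= 0))
    return("all size parameters must be positive")
  if (object@kind == "superellipsoid" &&
      (is.null(p$exponent) || p$exponent < 2))
    return("superellipsoid exponent must be >= 2")
  TRUE
})

#' SurfaceMesh: a welded triangle mesh with first-ring adjacency
#'
#' Triangle mesh produced by the continuation polygonizer: world-space
#' vertices, 1-based triangle index triples, and the per-vertex first-ring
#' neighbourhood (all vertices sharing an edge). Vertices on shared cube
#' edges are welded exactly by lattice edge key, so a closed genus-0 mesh
#' satisfies V - E + F = 2 and T = 2V - 4.
#'
#' @slot vertices n-by-3 numeric matrix of vertex positions.
#' @slot triangles m-by-3 integer matrix of vertex indices.
#' @slot adjacency list of length n; element v is the sorted integer vector
#'   of first-ring neighbours of vertex v.
#'
#' @seealso [extractSurface()], [meshStats()], [firstRing()]
#' @exportClass SurfaceMesh
setClass("SurfaceMesh",
  representation(vertices = "matrix", triangles = "matrix",
                 adjacency = "list"))

setValidity("SurfaceMesh", function(object) {
  nv <- nrow(object@vertices)
  if (ncol(object@vertices) != 3L)
    return("'vertices' must have 3 columns")
  if (nrow(object@triangles) > 0L) {
    if (ncol(object@triangles) != 3L)
      return("'triangles' must have 3 columns")
    tr <- object@triangles
    if (any(tr < 1L) || any(tr > nv))
      return("triangle indices out of range")
    if (any(tr[, 1] == tr[, 2] | tr[, 2] == tr[, 3] | tr[, 1] == tr[, 3]))
      return("degenerate triangle with repeated vertex index")
  }
  if (length(object@adjacency) != nv)
    return("'adjacency' must have one entry per vertex")
  TRUE
})

#' CrestSet: crest points, segments and polylines on a mesh
#'
#' Zero-crossings of the extremality \eqn{e_{max} = \nabla k_{max} \cdot
#' t_{max}} located on mesh edges, the within-triangle segments joining them,
#' and the polylines obtained by chaining segments that share a crest point.
#' Each crest point carries Gaussian curvature and curvedness linearly
#' interpolated from the edge endpoints.
#'
#' @slot points p-by-3 matrix of crest point positions.
#' @slot info data.frame with one row per crest point: \code{edge1},
#'   \code{edge2} (mesh vertex ids of the supporting edge), \code{t}
#'   (interpolation parameter from edge1), \code{K} (Gaussian curvature),
#'   \code{C} (curvedness).
#' @slot segments s-by-2 integer matrix of crest point ids (one segment per
#'   crossed triangle).
#' @slot polylines list of integer vectors, each an ordered chain of crest
#'   point ids.
#' @slot meta list of bookkeeping counts (skipped triangles etc.).
#'
#' @seealso [extractCrestLines()], [triangleZeroCrossings()],
#'   [linkPolylines()]
#' @exportClass CrestSet
setClass("CrestSet",
  representation(points = "matrix", info = "data.frame",
                 segments = "matrix", polylines = "list", meta = "list"))

setValidity("CrestSet", function(object) {
  np <- nrow(object@points)
  if (np > 0 && ncol(object@points) != 3L)
    return("'points' must have 3 columns")
  if (nrow(object@info) != np)
    return("'info' must have one row per crest point")
  if (nrow(object@segments) > 0L &&
      (any(object@segments < 1L) || any(object@segments > np)))
    return("segment point ids out of range")
  TRUE
})

#' LandmarkSet: the final landmarks with full provenance
#'
#' Result of the landmark-identification phase: the thresholded candidate
#' crest points, their K-means cluster labels and centroids, the silhouette
#' score per tried K, the chosen K, and one landmark per cluster (the member
#' of maximal curvedness). Landmarks are actual candidate points, never
#' centroids.
#'
#' @slot candidates data.frame: \code{x,y,z,K,C,point} (crest point id).
#' @slot labels integer cluster label per candidate.
#' @slot centroids chosenK-by-3 matrix of cluster centroids.
#' @slot landmarks data.frame: \code{x,y,z,K,C,cluster,candidate}.
#' @slot chosenK integer number of clusters used.
#' @slot silhouettes named numeric: mean silhouette per tried K (empty when
#'   K was fixed by the caller).
#' @slot provenance list echoing thresholds, seeds and selection mode.
#'
#' @seealso [identifyLandmarks()], [selectKBySilhouette()]
#' @exportClass LandmarkSet
setClass("LandmarkSet",
  representation(candidates = "data.frame", labels = "integer",
                 centroids = "matrix", landmarks = "data.frame",
                 chosenK = "integer", silhouettes = "numeric",
                 provenance = "list"))

setValidity("LandmarkSet", function(object) {
  if (length(object@labels) != nrow(object@candidates))
    return("one label per candidate required")
  if (nrow(object@landmarks) > object@chosenK)
    return("more landmarks than clusters")
  if (length(object@silhouettes) &&
      any(object@silhouettes < -1 | object@silhouettes > 1))
    return("silhouette values must lie in [-1, 1]")
  TRUE
})
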