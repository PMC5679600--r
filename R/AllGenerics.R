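#' Evaluate the implicit field at world-space points
#'
#' Returns \eqn{F(q) = value(q) - p_c} for each query point. For a
#' [GridField-class] this is the full 8-corner tri-linear interpolant of the
#' containing cell, exact at lattice nodes and linear along any axis-aligned
#' line within a cell; for an [AnalyticField-class] the wrapped function.
#'
#' A point exactly on the top face of the domain belongs to the last cell
#' (half-open cell ownership), so the whole closed domain is evaluable.
#'
#' @param field a [ScalarField-class].
#' @param pts n-by-3 numeric matrix of world coordinates (a bare numeric(3)
#'   is accepted for a single point).
#' @param outside \code{"error"} (default) to fail on out-of-domain points,
#'   \code{"na"} to return NA for them.
#' @return numeric(n) of field values.
#' @examples
#' g <- volumeGrid(array(seq_len(8) - 1, c(2, 2, 2)))
#' f <- scalarField(g, isovalue = 0)
#' fieldValue(f, c(0, 0, 0))   # == data[1,1,1]
#' fieldValue(f, c(0.5, 0.5, 0.5))  # mean of the 8 corners
#' @export
setGeneric("fieldValue", function(field, pts, outside = c("error", "na"))
  standardGeneric("fieldValue"))

#' @rdname accessors
#' @export
setGeneric("vertices", function(x) standardGeneric("vertices"))

#' @rdname accessors
#' @export
setGeneric("triangles", function(x) standardGeneric("triangles"))

#' @rdname accessors
#' @export
setGeneric("adjacency", function(x) standardGeneric("adjacency"))

#' @rdname accessors
#' @export
setGeneric("crestPoints", function(x) standardGeneric("crestPoints"))

#' @rdname accessors
#' @export
setGeneric("crestSegments", function(x) standardGeneric("crestSegments"))

#' @rdname accessors
#' @export
setGeneric("polylines", function(x) standardGeneric("polylines"))

#' @rdname accessors
#' @export
setGeneric("landmarks", function(x) standardGeneric("landmarks"))

#' @rdname accessors
#' @export
setGeneric("candidates", function(x) standardGeneric("candidates"))

#' @rdname accessors
#' @export
setGeneric("chosenK", function(x) standardGeneric("chosenK"))

#' @rdname accessors
#' @export
setGeneric("silhouettes", function(x) standardGeneric("silhouettes"))

#' Accessors for pipeline objects
#'
#' Read-only accessors for the S4 containers: mesh vertices/triangles and
#' first-ring adjacency, crest points/segments/polylines, landmark-set
#' candidates, landmarks, chosen K and the silhouette table.
#'
#' @param x a [SurfaceMesh-class], [CrestSet-class] or [LandmarkSet-class].
#' @name accessors
#' @return the corresponding slot, unmodified.
NULL

#' @rdname accessors
#' @export
setMethod("vertices", "SurfaceMesh", function(x) x@vertices)
#' @rdname accessors
#' @export
setMethod("triangles", "SurfaceMesh", function(x) x@triangles)
#' @rdname accessors
#' @export
setMethod("adjacency", "SurfaceMesh", function(x) x@adjacency)
#' @rdname accessors
#' @export
setMethod("crestPoints", "CrestSet", function(x) x@points)
#' @rdname accessors
#' @export
setMethod("crestSegments", "CrestSet", function(x) x@segments)
#' @rdname accessors
#' @export
setMethod("polylines", "CrestSet", function(x) x@polylines)
#' @rdname accessors
#' @export
setMethod("landmarks", "LandmarkSet", function(x) x@landmarks)
#' @rdname accessors
#' @export
setMethod("candidates", "LandmarkSet", function(x) x@candidates)
#' @rdname accessors
#' @export
setMethod("chosenK", "LandmarkSet", function(x) x@chosenK)
#' @rdname accessors
#' @export
setMethod("silhouettes", "LandmarkSet", function(x) x@silhouettes)
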