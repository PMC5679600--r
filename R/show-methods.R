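#' @describeIn VolumeGrid-class compact summary
#' @param object a VolumeGrid
#' @export
setMethod("show", "VolumeGrid", function(object) {
  d <- dim(object@data)
  cat("VolumeGrid", paste(d, collapse = " x "),
      sprintf("| spacing %s | origin %s\n",
              paste(format(object@spacing), collapse = " x "),
              paste(format(object@origin), collapse = ", ")))
  cat("  intensity range:", paste(format(range(object@data)), collapse = " .. "),
      "\n")
  invisible(NULL)
})

#' @export
setMethod("show", "GridField", function(object) {
  cat("GridField (tri-linear) | isovalue", format(object@isovalue), "\n")
  cat("  domain:", .fmtBounds(object), "\n")
  invisible(NULL)
})

#' @export
setMethod("show", "AnalyticField", function(object) {
  cat("AnalyticField | isovalue", format(object@isovalue), "\n")
  cat("  domain:", .fmtBounds(object), "\n")
  invisible(NULL)
})

.fmtBounds <- function(field) {
  paste0("[", paste(format(field@lower), collapse = ", "), "] .. [",
         paste(format(field@upper), collapse = ", "), "]")
}

#' @export
setMethod("show", "AnalyticShape", function(object) {
  p <- object@parameters
  cat("AnalyticShape:", object@kind, "| center",
      paste(format(object@center), collapse = ", "), "\n")
  cat(" ", paste(names(p), vapply(p, function(x)
    paste(format(x), collapse = ","), ""), sep = "=", collapse = " "), "\n")
  invisible(NULL)
})

#' @export
setMethod("show", "SurfaceMesh", function(object) {
  cat("SurfaceMesh:", nrow(object@vertices), "vertices,",
      nrow(object@triangles), "triangles\n")
  st <- try(meshStats(object), silent = TRUE)
  if (!inherits(st, "try-error"))
    cat("  triangles per vertex:", format(st$ratio, digits = 4), "\n")
  invisible(NULL)
})

#' @export
setMethod("show", "CrestSet", function(object) {
  cat("CrestSet:", nrow(object@points), "crest points,",
      nrow(object@segments), "segments,",
      length(object@polylines), "polylines\n")
  invisible(NULL)
})

#' @export
setMethod("show", "LandmarkSet", function(object) {
  cat("LandmarkSet:", nrow(object@landmarks), "landmarks from",
      nrow(object@candidates), "candidates (K =", object@chosenK, ")\n")
  if (length(object@silhouettes)) {
    best <- names(object@silhouettes)[which.max(object@silhouettes)]
    cat("  mean silhouette by K, best at K =", best, "\n")
  }
  invisible(NULL)
})
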