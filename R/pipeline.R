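#' Configuration of the full pipeline
#'
#' Bundles every tunable of the three phases. All values are serialized
#' verbatim into the run manifest and each output's provenance, because the
#' free parameters (cube size, finite-difference step, lambda, thresholds,
#' K selection) are exactly what make results hard to reproduce otherwise.
#'
#' @param isovalue intensity \eqn{p_c} defining the isosurface.
#' @param cube_size,cube_frac continuation cube size (see
#'   [extractSurface()]).
#' @param start seed-search start: numeric(3) or \code{"random"}.
#' @param rng_seed integer seed used by every stochastic step.
#' @param h finite-difference step for derivatives (default half a voxel).
#' @param lambda,cot_cap weight-function settings (see [weightConfig()]).
#' @param oriented align principal-direction signs per triangle.
#' @param threshold_mode,threshold_value,use_abs candidate thresholding
#'   (see [thresholdCandidates()]).
#' @param k,k_range cluster-count selection (see [identifyLandmarks()]).
#' @param restarts K-means restarts.
#' @return list of class \code{"pipelineConfig"}.
#' @export
pipelineConfig <- function(isovalue = 0, cube_size = NULL, cube_frac = NULL,
                           start = "random", rng_seed = 0L, h = NULL,
                           lambda = 0.5, cot_cap = 1e3, oriented = TRUE,
                           threshold_mode = "percentile",
                           threshold_value = 90, use_abs = FALSE,
                           k = "silhouette", k_range = NULL,
                           restarts = 10L) {
  structure(list(isovalue = isovalue, cube_size = cube_size,
                 cube_frac = cube_frac, start = start,
                 rng_seed = as.integer(rng_seed), h = h, lambda = lambda,
                 cot_cap = cot_cap, oriented = oriented,
                 threshold_mode = threshold_mode,
                 threshold_value = threshold_value, use_abs = use_abs,
                 k = k, k_range = k_range, restarts = as.integer(restarts)),
            class = "pipelineConfig")
}

#' Run the three-phase pipeline
#'
#' Volume in, landmarks out: surface construction (continuation
#' polygonizer), crest-line extraction (volume-based curvature +
#' first-ring gradient estimator + extremality zero-crossings) and landmark
#' identification (threshold, K-means with silhouette-selected K,
#' per-cluster maximal curvedness). Each phase is a black box that consumes
#' the previous phase's output, so any phase can be re-run from saved
#' files.
#'
#' When \code{outdir} is given, writes \code{mesh.obj},
#' \code{attributes.csv}, \code{crest.vtk}, \code{crest.csv},
#' \code{landmarks.csv}, \code{landmarks.json} and \code{manifest.json}
#' (config, counts and caveat metrics: degenerate vertices, skipped
#' triangles).
#'
#' @param input a [VolumeGrid-class], [ScalarField-class],
#'   [AnalyticShape-class], or path to an ASCII volume file.
#' @param config a [pipelineConfig()].
#' @param outdir optional output directory (created if missing).
#' @param dims,spacing passed to [readAsciiVolume()] for headerless files.
#' @return invisibly, a list with \code{mesh}, \code{attrs}, \code{crest},
#'   \code{landmarks} and \code{manifest}.
#' @examples
#' \donttest{
#' cube <- analyticShape("superellipsoid", halfwidth = 20, exponent = 6,
#'                       center = rep(31.5, 3))
#' vol <- voxelize(cube, dims = c(64, 64, 64))
#' res <- runPipeline(vol, pipelineConfig(start = rep(31.5, 3)))
#' res$manifest$counts
#' }
#' @export
runPipeline <- function(input, config = pipelineConfig(), outdir = NULL,
                        dims = NULL, spacing = NULL) {
  field <- if (is(input, "ScalarField")) input
    else if (is(input, "VolumeGrid"))
      scalarField(input, isovalue = config$isovalue)
    else if (is(input, "AnalyticShape")) analyticField(input)
    else if (is.character(input))
      scalarField(readAsciiVolume(input, dims = dims, spacing = spacing),
                  isovalue = config$isovalue)
    else stop("unsupported input type: ", class(input)[1])

  mesh <- extractSurface(field, cube_size = config$cube_size,
                         cube_frac = config$cube_frac,
                         start = config$start, rng_seed = config$rng_seed)
  wts <- weightConfig(lambda = config$lambda, cot_cap = config$cot_cap)
  attrs <- attachAttributes(mesh, field, h = config$h, weights = wts)
  crest <- linkPolylines(
    triangleZeroCrossings(mesh, attrs, oriented = config$oriented))
  lms <- identifyLandmarks(crest, threshold_mode = config$threshold_mode,
                           threshold_value = config$threshold_value,
                           use_abs = config$use_abs, k = config$k,
                           k_range = config$k_range,
                           rng_seed = config$rng_seed,
                           restarts = config$restarts)
  st <- meshStats(mesh)
  manifest <- list(
    config = unclass(config),
    counts = list(vertices = st$n_vertices, triangles = st$n_triangles,
                  ratio = st$ratio, cubes = attr(mesh, "n_cubes"),
                  crest_points = nrow(crest@points),
                  crest_segments = nrow(crest@segments),
                  candidates = nrow(lms@candidates),
                  chosen_k = lms@chosenK,
                  landmarks = nrow(lms@landmarks)),
    caveats = list(degenerate_vertices = sum(attrs$degenerate),
                   skipped_triangles = crest@meta$skipped),
    silhouette_by_k = as.list(lms@silhouettes))
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    writeOBJ(mesh, file.path(outdir, "mesh.obj"))
    adf <- attrs
    for (cn in names(adf)) if (is.numeric(adf[[cn]]))
      adf[[cn]] <- .fmtNum(adf[[cn]])
    utils::write.csv(cbind(vertex = seq_len(nrow(attrs)), adf),
                     file.path(outdir, "attributes.csv"),
                     row.names = FALSE, quote = FALSE)
    writeVTKLines(crest, file.path(outdir, "crest.vtk"))
    writeCrestCSV(crest, file.path(outdir, "crest.csv"))
    writeLandmarksCSV(lms, file.path(outdir, "landmarks.csv"))
    writeLandmarksJSON(lms, file.path(outdir, "landmarks.json"))
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
  }
  invisible(list(mesh = mesh, attrs = attrs, crest = crest,
                 landmarks = lms, manifest = manifest))
}
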