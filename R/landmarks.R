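#' Threshold crest points by Gaussian curvature
#'
#' Step two of the landmark phase: keep the crest points whose interpolated
#' Gaussian curvature is high. \code{mode = "percentile"} keeps points
#' strictly above the \code{value}-th percentile of K over the crest set
#' (the default, \code{value = 90}, keeps the top 10%; scale-free across
#' datasets). \code{mode = "absolute"} keeps points with \code{K > value}.
#' Thresholding is on signed K (dome-like corners are large positive);
#' set \code{use_abs = TRUE} to rank by |K| instead.
#'
#' @param crest a [CrestSet-class].
#' @param mode \code{"percentile"} or \code{"absolute"}.
#' @param value percentile in [0, 100], or the absolute threshold.
#' @param use_abs threshold on |K| rather than signed K.
#' @return data.frame of candidates: \code{x,y,z,K,C,point} (crest point
#'   id). Errors with "no candidates" when nothing passes.
#' @export
thresholdCandidates <- function(crest, mode = c("percentile", "absolute"),
                                value = 90, use_abs = FALSE) {
  mode <- match.arg(mode)
  stopifnot(is(crest, "CrestSet"))
  K <- crest@info$K
  if (use_abs) K <- abs(K)
  keep <- if (mode == "percentile") {
    stopifnot(value >= 0, value <= 100)
    if (value == 0) rep(TRUE, length(K))
    else K > stats::quantile(K, value / 100, names = FALSE, na.rm = TRUE)
  } else K > value
  keep <- keep & !is.na(K)
  if (!any(keep))
    stop("no candidates: no crest point exceeds the ", mode,
         " Gaussian-curvature threshold ", value)
  data.frame(x = crest@points[keep, 1], y = crest@points[keep, 2],
             z = crest@points[keep, 3], K = crest@info$K[keep],
             C = crest@info$C[keep], point = which(keep))
}

#' Rule-of-thumb number of clusters
#'
#' The simple estimate \eqn{k \approx \sqrt{n/2}} for the number of K-means
#' clusters given n points.
#'
#' @param n number of data points (>= 1).
#' @return unrounded \eqn{\sqrt{n/2}}.
#' @examples
#' ruleOfThumbK(118)          # 7.68...
#' roundedRuleOfThumbK(118)   # 8
#' @export
ruleOfThumbK <- function(n) {
  if (length(n) != 1L || !is.finite(n) || n < 1)
    stop("'n' must be a single integer >= 1")
  sqrt(n / 2)
}

#' @rdname ruleOfThumbK
#' @return \code{roundedRuleOfThumbK}: the nearest integer, at least 1.
#' @export
roundedRuleOfThumbK <- function(n) max(1L, as.integer(round(ruleOfThumbK(n))))

# k-means++ initial centers (deterministic given the active RNG state)
.kmeansppInit <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  centers[1, ] <- x[sample.int(n, 1), ]
  d2 <- rowSums(sweep(x, 2, centers[1, ])^2)
  for (j in seq_len(k - 1L)) {
    if (all(d2 <= 0)) {
      centers[j + 1L, ] <- x[sample.int(n, 1), ]
    } else {
      centers[j + 1L, ] <- x[sample.int(n, 1, prob = d2), ]
    }
    d2 <- pmin(d2, rowSums(sweep(x, 2, centers[j + 1L, ])^2))
  }
  centers
}

#' K-means clustering of landmark candidates
#'
#' Lloyd K-means on the candidates' spatial coordinates with k-means++-style
#' seeding, \code{restarts} re-initializations and the best total
#' within-cluster sum of squares kept. Deterministic for a fixed
#' \code{rng_seed}.
#'
#' @param cand candidate data.frame from [thresholdCandidates()] (columns
#'   x, y, z), or a plain n-by-3 matrix.
#' @param k number of clusters, \code{1 <= k <= n}.
#' @param rng_seed integer seed.
#' @param restarts number of k-means++ restarts (default 10).
#' @return list with \code{labels} (integer(n)), \code{centroids}
#'   (k-by-3) and \code{inertia} (total within-cluster SS).
#' @export
clusterCandidates <- function(cand, k, rng_seed = 0L, restarts = 10L) {
  x <- if (is.data.frame(cand)) as.matrix(cand[, c("x", "y", "z")])
       else .asPoints(cand)
  n <- nrow(x)
  if (k < 1 || k > n)
    stop("'k' must be between 1 and the number of candidates (", n, ")")
  if (k == n) {
    return(list(labels = seq_len(n), centroids = x, inertia = 0))
  }
  best <- NULL
  withr::with_seed(as.integer(rng_seed), {
    for (r in seq_len(max(1L, restarts))) {
      init <- .kmeanspp(x, k)
      km <- suppressWarnings(
        stats::kmeans(x, centers = init, iter.max = 100L,
                      algorithm = "Lloyd"))
      if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
    }
  })
  list(labels = as.integer(best$cluster),
       centroids = unname(best$centers),
       inertia = best$tot.withinss)
}

.kmeanspp <- function(x, k) {
  init <- .kmeansppInit(x, k)
  # Lloyd with duplicate centers fails; nudge exact duplicates apart
  while (anyDuplicated(init)) {
    dup <- duplicated(init)
    init[dup, ] <- init[dup, , drop = FALSE] +
      matrix(stats::rnorm(sum(dup) * ncol(x), 0, 1e-8), sum(dup))
  }
  init
}

#' Choose the number of clusters by mean silhouette
#'
#' Runs [clusterCandidates()] for every K in \code{k_range}, scores each
#' clustering by the mean silhouette coefficient \eqn{s = (b - a) /
#' \max(a, b)} (Euclidean distances; \code{cluster::silhouette}), and
#' returns the K with the highest mean. The coefficient lies in [-1, 1];
#' values near 1 indicate compact, well-separated clusters. Ties go to the
#' smaller K.
#'
#' @inheritParams clusterCandidates
#' @param k_range integer vector of K values to try, each in
#'   \code{[2, n - 1]}. Default \code{2:min(15, n - 1)}.
#' @return list with \code{chosen_k} and \code{silhouette_by_k} (named
#'   numeric).
#' @export
selectKBySilhouette <- function(cand, k_range = NULL, rng_seed = 0L,
                                restarts = 10L) {
  x <- if (is.data.frame(cand)) as.matrix(cand[, c("x", "y", "z")])
       else .asPoints(cand)
  n <- nrow(x)
  if (n < 3)
    stop("silhouette selection needs at least 3 candidates")
  k_range <- sort(unique(as.integer(k_range %||% 2:min(15L, n - 1L))))
  if (any(k_range < 2L) || any(k_range > n - 1L))
    stop("every K must lie in [2, n-1]")
  d <- stats::dist(x)
  sil <- vapply(k_range, function(k) {
    cl <- clusterCandidates(x, k, rng_seed = rng_seed, restarts = restarts)
    mean(cluster::silhouette(cl$labels, d)[, "sil_width"])
  }, 0)
  names(sil) <- k_range
  list(chosen_k = k_range[which.max(sil)],   # which.max: first max = smaller K
       silhouette_by_k = sil)
}

#' One landmark per cluster by maximal curvedness
#'
#' The landmark of each cluster is its member with the highest curvedness
#' C (ties: lowest candidate index); the landmark keeps the candidate's own
#' coordinates, never the centroid. Empty clusters (possible after a
#' degenerate K-means) are skipped with a warning.
#'
#' @param cand candidate data.frame (columns x, y, z, K, C).
#' @param labels integer cluster label per candidate.
#' @return data.frame of landmarks: \code{x,y,z,K,C,cluster,candidate}.
#' @export
selectLandmarks <- function(cand, labels) {
  stopifnot(nrow(cand) == length(labels))
  ks <- sort(unique(labels))
  all_k <- seq_len(max(labels))
  if (length(ks) < length(all_k))
    warning("empty cluster(s) skipped: ",
            paste(setdiff(all_k, ks), collapse = ", "))
  rows <- vapply(ks, function(cl) {
    idx <- which(labels == cl)
    idx[which.max(cand$C[idx])]    # which.max takes the first (lowest index)
  }, 0L)
  out <- cand[rows, c("x", "y", "z", "K", "C"), drop = FALSE]
  out$cluster <- ks
  out$candidate <- rows
  rownames(out) <- NULL
  out
}

#' Identify landmarks on a crest set
#'
#' Composes the four steps of the landmark phase: Gaussian-curvature
#' thresholding, choice of K (mean silhouette by default, the
#' \eqn{\sqrt{n/2}} rule of thumb, or a fixed K), K-means clustering, and
#' per-cluster maximal-curvedness selection. All settings and the
#' silhouette table are echoed in the result's provenance.
#'
#' @param crest a [CrestSet-class].
#' @param threshold_mode,threshold_value,use_abs see
#'   [thresholdCandidates()].
#' @param k number of clusters: \code{"silhouette"} (default),
#'   \code{"rule"}, or a fixed integer.
#' @param k_range K values tried by the silhouette selection.
#' @param rng_seed integer seed for seeding/restarts.
#' @param restarts K-means restarts.
#' @return a [LandmarkSet-class].
#' @export
identifyLandmarks <- function(crest, threshold_mode = "percentile",
                              threshold_value = 90, use_abs = FALSE,
                              k = "silhouette", k_range = NULL,
                              rng_seed = 0L, restarts = 10L) {
  cand <- thresholdCandidates(crest, mode = threshold_mode,
                              value = threshold_value, use_abs = use_abs)
  sil <- numeric(0)
  if (identical(k, "silhouette")) {
    ks <- selectKBySilhouette(cand, k_range = k_range, rng_seed = rng_seed,
                              restarts = restarts)
    chosen <- ks$chosen_k
    sil <- ks$silhouette_by_k
  } else if (identical(k, "rule")) {
    chosen <- roundedRuleOfThumbK(nrow(cand))
  } else {
    chosen <- as.integer(k)
  }
  cl <- clusterCandidates(cand, chosen, rng_seed = rng_seed,
                          restarts = restarts)
  lm <- selectLandmarks(cand, cl$labels)
  new("LandmarkSet", candidates = cand, labels = cl$labels,
      centroids = cl$centroids, landmarks = lm,
      chosenK = as.integer(chosen), silhouettes = sil,
      provenance = list(threshold_mode = threshold_mode,
                        threshold_value = threshold_value,
                        use_abs = use_abs, k_mode = if (is.character(k)) k
                        else "fixed", rng_seed = as.integer(rng_seed),
                        restarts = as.integer(restarts),
                        n_candidates = nrow(cand)))
}
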