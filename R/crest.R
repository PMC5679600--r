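#' Configuration of the first-ring weight function
#'
#' The gradient of the maximal principal curvature at a vertex is estimated
#' from its first-ring neighbours with per-axis weights
#' \deqn{W_{i.x} = \lambda W_{i.a.x} + (1 - \lambda) W_{i.d.x},}
#' mixing an angle term (the signed cotangent of the angle between the edge
#' and the axis) and a distance term (edge lengths normalized to sum to 1).
#'
#' @param lambda mixing parameter \eqn{\lambda \in [0, 1]}; 1 = pure angle
#'   weights, 0 = pure distance weights. Default 0.5 (equal mix).
#' @param cot_cap clamp for the cotangent magnitude; the angle weight is
#'   singular for neighbours lying exactly along the axis. Default 1e3.
#' @return list of class \code{"weightConfig"}.
#' @export
weightConfig <- function(lambda = 0.5, cot_cap = 1e3) {
  stopifnot(lambda >= 0, lambda <= 1, cot_cap > 0)
  structure(list(lambda = lambda, cot_cap = cot_cap),
            class = "weightConfig")
}

#' First-ring neighbourhood of a mesh vertex
#'
#' All vertices sharing an edge with \code{v}, each once, in ascending
#' index order. An isolated vertex yields an empty vector with attribute
#' \code{"isolated" = TRUE}.
#'
#' @param mesh a [SurfaceMesh-class].
#' @param v vertex index (1-based).
#' @return integer vector of neighbour indices.
#' @export
firstRing <- function(mesh, v) {
  stopifnot(v >= 1L, v <= length(mesh@adjacency))
  nb <- mesh@adjacency[[v]]
  if (!length(nb)) attr(nb, "isolated") <- TRUE
  nb
}

#' Axis-angle weight of one neighbour
#'
#' The signed cotangent of the angle between the target-to-neighbour edge
#' and the given axis:
#' \deqn{W_{i.a.x} = \cot\theta =
#'   \frac{x_i - x_0}{\sqrt{(y_i - y_0)^2 + (z_i - z_0)^2}}}
#' (cyclically permuted for the y and z axes). The magnitude is clamped to
#' \code{cot_cap}; a neighbour lying exactly along the axis (zero
#' denominator) returns \code{sign(delta) * cot_cap}.
#'
#' @param target numeric(3) target vertex position.
#' @param nbr numeric(3) neighbour position (distinct from target).
#' @param axis \code{"x"}, \code{"y"} or \code{"z"} (or 1:3).
#' @param cot_cap clamp magnitude.
#' @return signed, clamped cotangent weight.
#' @export
angleWeight <- function(target, nbr, axis = "x", cot_cap = 1e3) {
  ax <- if (is.character(axis)) match(axis, c("x", "y", "z")) else as.integer(axis)
  stopifnot(ax %in% 1:3)
  d <- nbr - target
  if (all(d == 0)) stop("neighbour coincides with target vertex")
  num <- d[ax]
  den <- sqrt(sum(d[-ax]^2))
  if (den < 1e-12) return(sign(num) * cot_cap)
  max(-cot_cap, min(cot_cap, num / den))
}

#' Normalized distance weights of a first ring
#'
#' Euclidean distances from the target to each neighbour, normalized to sum
#' to one:
#' \deqn{W_{i.d} = Dist_i / \sum_j Dist_j.}
#' The same distance weight is used for all three axes.
#'
#' @param target numeric(3) target vertex position.
#' @param neighbors m-by-3 matrix of neighbour positions.
#' @return numeric(m) weights summing to 1.
#' @export
distanceWeight <- function(target, neighbors) {
  neighbors <- .asPoints(neighbors)
  d <- .rowNorm(sweep(neighbors, 2, target))
  tot <- sum(d)
  if (tot < 1e-300) stop("all neighbours coincide with the target vertex")
  d / tot
}

#' First-ring weighted estimate of the curvature gradient at one vertex
#'
#' The per-axis estimator
#' \deqn{\frac{\partial k_0}{\partial x} =
#'   \frac{\sum_i W_{i.x} (k_i - k_0)}{\sum_i |W_{i.x}|}}
#' over the usable (non-degenerate) first-ring neighbours, with
#' \eqn{W_{i.x}} the \eqn{\lambda}-mix of angle and distance weights (see
#' [weightConfig()]). A component whose weight magnitudes sum below 1e-12
#' is returned as 0 and flagged.
#'
#' @param mesh a [SurfaceMesh-class].
#' @param attrs per-vertex attributes from [attachAttributes()] (columns
#'   \code{kmax} and \code{degenerate} are used).
#' @param v target vertex index.
#' @param cfg a [weightConfig()].
#' @return numeric(3) gradient estimate with logical attribute
#'   \code{"flagged"} (per component) and \code{"degenerate"} (no usable
#'   neighbours).
#' @export
curvatureGradient <- function(mesh, attrs, v, cfg = weightConfig()) {
  nb <- firstRing(mesh, v)
  nb <- nb[!attrs$degenerate[nb]]
  out <- c(0, 0, 0)
  if (!length(nb) || attrs$degenerate[v]) {
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  p0 <- mesh@vertices[v, ]
  pn <- mesh@vertices[nb, , drop = FALSE]
  dk <- attrs$kmax[nb] - attrs$kmax[v]
  wd <- distanceWeight(p0, pn)
  d <- sweep(pn, 2, p0)
  d2 <- d * d
  flagged <- logical(3)
  for (ax in 1:3) {
    # vectorized form of angleWeight() over the ring
    den <- sqrt(rowSums(d2[, -ax, drop = FALSE]))
    wa <- ifelse(den < 1e-12, sign(d[, ax]) * cfg$cot_cap,
                 pmax(-cfg$cot_cap, pmin(cfg$cot_cap, d[, ax] / den)))
    w <- cfg$lambda * wa + (1 - cfg$lambda) * wd
    dsum <- sum(abs(w))
    if (dsum < 1e-12) flagged[ax] <- TRUE
    else out[ax] <- sum(w * dk) / dsum
  }
  attr(out, "flagged") <- flagged
  out
}

#' Curvature gradient for every mesh vertex
#'
#' Vectorized application of [curvatureGradient()]; rows for degenerate
#' vertices are NA.
#'
#' @inheritParams curvatureGradient
#' @return n-by-3 matrix of gradient estimates.
#' @export
curvatureGradientAll <- function(mesh, attrs, cfg = weightConfig()) {
  n <- nrow(mesh@vertices)
  out <- matrix(NA_real_, n, 3)
  for (v in seq_len(n)) {
    if (attrs$degenerate[v]) next
    out[v, ] <- curvatureGradient(mesh, attrs, v, cfg)
  }
  out
}

#' Extremality from curvature gradient and principal direction
#'
#' \deqn{e_{max} = \nabla k_{max} \cdot t_{max}:}
#' the directional derivative of the maximal principal curvature along its
#' own principal direction. Crest points are the zero-crossings of this
#' scalar over the surface.
#'
#' @param attrs per-vertex attributes (columns \code{tmax.x..z}).
#' @param grad_kmax n-by-3 matrix (or numeric(3) for one vertex) of
#'   curvature-gradient estimates.
#' @return numeric extremality value(s); NA for degenerate vertices.
#' @export
extremality <- function(attrs, grad_kmax) {
  if (is.null(dim(grad_kmax))) grad_kmax <- matrix(grad_kmax, nrow = 1)
  rowSums(grad_kmax *
            as.matrix(attrs[, c("tmax.x", "tmax.y", "tmax.z")]))
}

#' Crest points and segments from per-triangle zero-crossings
#'
#' For every triangle whose three vertices are usable, the extremality signs
#' are examined (an exact zero counts as positive). If all three agree there
#' is no crest geometry in the triangle; otherwise the two edges joining the
#' odd-signed vertex to the others each carry a linearly interpolated
#' zero-crossing, and the pair is joined as one segment. Gaussian curvature
#' and curvedness at each crossing are interpolated with the same edge
#' parameter. Crossings are deduplicated by mesh edge, so segments in
#' adjacent triangles share crest points and can be chained into polylines.
#'
#' Because the principal direction \eqn{t_{max}} is only defined up to sign
#' and \eqn{e_{max}} is odd in it, with \code{oriented = TRUE} (default)
#' the directions of vertices 2 and 3 are flipped to have non-negative dot
#' product with vertex 1's direction before the sign test, flipping their
#' extremality values accordingly. Without this alignment, sign changes can
#' be artefacts of the representative chosen per vertex.
#'
#' @param mesh a [SurfaceMesh-class].
#' @param attrs per-vertex attributes with \code{emax}, \code{tmax.*},
#'   \code{K}, \code{C}, \code{degenerate}.
#' @param oriented align \eqn{t_{max}} signs within each triangle.
#' @return a [CrestSet-class] (polylines not yet linked; see
#'   [linkPolylines()]). \code{meta$skipped} counts triangles dropped for a
#'   degenerate vertex.
#' @export
triangleZeroCrossings <- function(mesh, attrs, oriented = TRUE) {
  tr <- mesh@triangles
  nt <- nrow(tr)
  usable <- !attrs$degenerate & is.finite(attrs$emax)
  triOk <- usable[tr[, 1]] & usable[tr[, 2]] & usable[tr[, 3]]
  skipped <- sum(!triOk)
  tru <- tr[triOk, , drop = FALSE]

  e1 <- attrs$emax[tru[, 1]]
  e2 <- attrs$emax[tru[, 2]]
  e3 <- attrs$emax[tru[, 3]]
  if (oriented && nrow(tru)) {
    tm <- as.matrix(attrs[, c("tmax.x", "tmax.y", "tmax.z")])
    d12 <- rowSums(tm[tru[, 1], , drop = FALSE] * tm[tru[, 2], , drop = FALSE])
    d13 <- rowSums(tm[tru[, 1], , drop = FALSE] * tm[tru[, 3], , drop = FALSE])
    e2 <- ifelse(d12 < 0, -e2, e2)   # emax is odd in tmax
    e3 <- ifelse(d13 < 0, -e3, e3)
  }
  s1 <- e1 >= 0; s2 <- e2 >= 0; s3 <- e3 >= 0
  allSame <- (s1 == s2) & (s2 == s3)
  cross <- which(!allSame)

  # odd vertex per crossing triangle (local index 1..3)
  odd <- integer(length(cross))
  odd[s2[cross] == s3[cross]] <- 1L
  odd[s1[cross] == s3[cross]] <- 2L
  odd[s1[cross] == s2[cross]] <- 3L

  em <- cbind(e1, e2, e3)[cross, , drop = FALSE]
  n <- length(cross)
  if (n == 0L)
    return(new("CrestSet", points = matrix(0, 0, 3),
               info = data.frame(edge1 = integer(), edge2 = integer(),
                                 t = numeric(), K = numeric(),
                                 C = numeric()),
               segments = matrix(0L, 0, 2), polylines = list(),
               meta = list(skipped = skipped, triangles = 0L)))

  others <- rbind(c(2L, 3L), c(1L, 3L), c(1L, 2L))
  va <- tru[cross, , drop = FALSE][cbind(seq_len(n), odd)]
  ea <- em[cbind(seq_len(n), odd)]
  mkCross <- function(which2) {
    oth <- others[odd, which2]
    vb <- tru[cross, , drop = FALSE][cbind(seq_len(n), oth)]
    eb <- em[cbind(seq_len(n), oth)]
    t <- ea / (ea - eb)
    pa <- mesh@vertices[va, , drop = FALSE]
    pb <- mesh@vertices[vb, , drop = FALSE]
    lowFirst <- va < vb
    list(pos = pa + t * (pb - pa),
         K = attrs$K[va] + t * (attrs$K[vb] - attrs$K[va]),
         C = attrs$C[va] + t * (attrs$C[vb] - attrs$C[va]),
         v1 = ifelse(lowFirst, va, vb), v2 = ifelse(lowFirst, vb, va),
         key = paste(pmin(va, vb), pmax(va, vb)),
         t = ifelse(lowFirst, t, 1 - t))
  }
  cA <- mkCross(1L); cB <- mkCross(2L)

  keys <- c(rbind(cA$key, cB$key))          # interleaved: triangle order
  pos <- matrix(NA_real_, 2L * n, 3L)
  pos[seq(1, 2 * n, 2), ] <- cA$pos; pos[seq(2, 2 * n, 2), ] <- cB$pos
  interleave <- function(a, b) c(rbind(a, b))
  info <- data.frame(edge1 = interleave(cA$v1, cB$v1),
                     edge2 = interleave(cA$v2, cB$v2),
                     t = interleave(cA$t, cB$t),
                     K = interleave(cA$K, cB$K),
                     C = interleave(cA$C, cB$C))
  first <- !duplicated(keys)
  pid <- match(keys, keys[first])
  points <- pos[first, , drop = FALSE]
  info <- info[first, , drop = FALSE]
  rownames(info) <- NULL
  segments <- matrix(pid, ncol = 2, byrow = TRUE)
  new("CrestSet", points = points, info = info, segments = segments,
      polylines = list(), meta = list(skipped = skipped, triangles = n))
}

#' Chain crest segments into polylines
#'
#' Segments sharing a crest point (i.e. lying on the same mesh edge) are
#' linked into ordered chains. Chains are built deterministically: the
#' unused segment with the smallest point id starts a chain, which is
#' extended greedily at both ends, always choosing the unused incident
#' segment leading to the smallest point id. Isolated segments become
#' length-2 chains.
#'
#' @param crest a [CrestSet-class] from [triangleZeroCrossings()].
#' @return the same CrestSet with \code{polylines} filled.
#' @export
linkPolylines <- function(crest) {
  seg <- crest@segments
  ns <- nrow(seg)
  if (!ns) { crest@polylines <- list(); return(crest) }
  # incidence: point id -> segment ids
  inc <- split(rep(seq_len(ns), 2), c(seg[, 1], seg[, 2]))
  used <- logical(ns)
  ord <- order(pmin(seg[, 1], seg[, 2]), pmax(seg[, 1], seg[, 2]))
  chains <- list()
  for (s0 in ord) {
    if (used[s0]) next
    used[s0] <- TRUE
    chain <- as.integer(seg[s0, ])
    if (chain[1] > chain[2]) chain <- rev(chain)
    repeat {   # extend at the tail
      tail <- chain[length(chain)]
      nxt <- inc[[as.character(tail)]]
      nxt <- nxt[!used[nxt]]
      if (!length(nxt)) break
      cand <- vapply(nxt, function(s) {
        o <- setdiff(as.integer(seg[s, ]), tail)
        if (length(o)) o[1] else tail
      }, 0L)
      pick <- which.min(cand)
      used[nxt[pick]] <- TRUE
      chain <- c(chain, cand[pick])
    }
    repeat {   # extend at the head
      head <- chain[1]
      nxt <- inc[[as.character(head)]]
      nxt <- nxt[!used[nxt]]
      if (!length(nxt)) break
      cand <- vapply(nxt, function(s) {
        o <- setdiff(as.integer(seg[s, ]), head)
        if (length(o)) o[1] else head
      }, 0L)
      pick <- which.min(cand)
      used[nxt[pick]] <- TRUE
      chain <- c(cand[pick], chain)
    }
    chains[[length(chains) + 1L]] <- chain
  }
  crest@polylines <- chains
  crest
}

#' Extract crest lines of a mesh
#'
#' Convenience wrapper for the whole second phase: per-vertex attributes
#' (if not supplied), triangle zero-crossings and polyline linking.
#'
#' @param mesh a [SurfaceMesh-class].
#' @param field the source [ScalarField-class] (used when \code{attrs} is
#'   missing).
#' @param attrs optional precomputed attributes from [attachAttributes()].
#' @param weights a [weightConfig()].
#' @param oriented see [triangleZeroCrossings()].
#' @param h finite-difference step for the curvature stage.
#' @return a [CrestSet-class] with polylines linked.
#' @export
extractCrestLines <- function(mesh, field = NULL, attrs = NULL,
                              weights = weightConfig(), oriented = TRUE,
                              h = NULL) {
  if (is.null(attrs)) {
    if (is.null(field))
      stop("either 'field' or precomputed 'attrs' is required")
    attrs <- attachAttributes(mesh, field, h = h, weights = weights)
  }
  linkPolylines(triangleZeroCrossings(mesh, attrs, oriented = oriented))
}
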