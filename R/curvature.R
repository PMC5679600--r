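#' Principal curvatures of the implicit surface at given points
#'
#' Curvatures are computed from the \emph{volume}, not from the mesh: the
#' gradient and Hessian of the implicit field (central differences, step
#' \code{h}) give the shape operator of the level set,
#' \deqn{S = -\frac{1}{|\nabla F|} P \, H_F \, P, \qquad
#'       P = I - \hat{n}\hat{n}^T,\ \hat{n} = \nabla F / |\nabla F|,}
#' whose two tangent-plane eigenvalues are the principal curvatures. Under
#' the inside-positive convention this makes convex surfaces positively
#' curved: a sphere of radius r has \eqn{k_{max} = k_{min} = +1/r}.
#'
#' Points where \eqn{|\nabla F|} falls below \code{grad_floor} are flagged
#' degenerate (the normal, hence the tangent plane, is undefined there) and
#' return NA curvatures; downstream stages skip them.
#'
#' The principal directions carry the usual sign ambiguity; they are
#' canonicalized so the largest-magnitude component is positive. At
#' near-umbilic points (\eqn{|k_{max} - k_{min}| < 10^{-6}}) any tangent
#' basis is valid; the eigenvector of the larger-magnitude eigenvalue is
#' kept, which makes the output deterministic.
#'
#' @param field a [ScalarField-class].
#' @param pts n-by-3 matrix of surface points (world coordinates).
#' @param h finite-difference step (scalar or per-axis), world units;
#'   default half a voxel.
#' @param grad_floor gradient magnitude below which a point is degenerate,
#'   relative to the mean gradient magnitude over \code{pts}.
#' @return data.frame with columns \code{kmax}, \code{kmin}, \code{tmax.x},
#'   \code{tmax.y}, \code{tmax.z}, \code{tmin.x..z}, \code{degenerate}.
#' @export
principalCurvatures <- function(field, pts, h = NULL, grad_floor = 1e-8) {
  pts <- .asPoints(pts)
  n <- nrow(pts)
  g <- fieldGradient(field, pts, h)
  hh <- fieldHessian(field, pts, h)
  gn <- .rowNorm(g)
  floorAbs <- grad_floor * max(mean(gn, na.rm = TRUE), .Machine$double.eps)
  kmax <- kmin <- rep(NA_real_, n)
  tmaxM <- tminM <- matrix(NA_real_, n, 3)
  degen <- logical(n)
  for (i in seq_len(n)) {
    if (!is.finite(gn[i]) || gn[i] <= floorAbs) {
      degen[i] <- TRUE
      next
    }
    nv <- g[i, ] / gn[i]
    P <- diag(3) - tcrossprod(nv)
    M <- -(P %*% hessianMatrix(hh[i, ]) %*% P) / gn[i]
    eg <- eigen((M + t(M)) / 2, symmetric = TRUE)
    # discard the eigenpair aligned with the normal (structurally zero)
    aln <- abs(colSums(eg$vectors * nv))
    keep <- order(aln)[1:2]
    ev <- eg$values[keep]
    vec <- eg$vectors[, keep, drop = FALSE]
    iMax <- if (abs(ev[1] - ev[2]) < 1e-6) which.max(abs(ev))
            else which.max(ev)
    iMin <- 3L - iMax
    tmax <- vec[, iMax]; tmin <- vec[, iMin]
    # exact tangency + unit length
    tmax <- tmax - sum(tmax * nv) * nv; tmax <- tmax / sqrt(sum(tmax^2))
    tmin <- tmin - sum(tmin * nv) * nv; tmin <- tmin / sqrt(sum(tmin^2))
    kmax[i] <- max(ev); kmin[i] <- min(ev)
    tmaxM[i, ] <- .canonicalSign(tmax)
    tminM[i, ] <- .canonicalSign(tmin)
  }
  data.frame(kmax = kmax, kmin = kmin,
             tmax.x = tmaxM[, 1], tmax.y = tmaxM[, 2], tmax.z = tmaxM[, 3],
             tmin.x = tminM[, 1], tmin.y = tminM[, 2], tmin.z = tminM[, 3],
             degenerate = degen)
}

# flip so the largest-magnitude component is positive (deterministic
# representative of the sign-ambiguous principal direction)
.canonicalSign <- function(v) {
  i <- which.max(abs(v))
  if (v[i] < 0) -v else v
}

#' Gaussian curvature from principal curvatures
#'
#' \eqn{K = k_{max} \cdot k_{min}}: large and positive at dome-like corners,
#' negative at saddles, near zero on flat or cylindrical regions.
#'
#' @param kmax,kmin principal curvatures (vectorized).
#' @return numeric Gaussian curvature.
#' @export
gaussianCurvature <- function(kmax, kmin) kmax * kmin

#' Curvedness from principal curvatures
#'
#' The root mean square of the two principal curvatures,
#' \deqn{C = \sqrt{(k_1^2 + k_2^2)/2} \in [0, \infty),}
#' zero exactly on flat surfaces and growing without bound as the surface
#' bends more tightly. Used to pick the single most feature-intensive point
#' of each landmark cluster.
#'
#' @param kmax,kmin principal curvatures (vectorized).
#' @return numeric curvedness, non-negative.
#' @export
curvedness <- function(kmax, kmin) sqrt((kmax^2 + kmin^2) / 2)

#' Per-vertex curvature attributes of a mesh
#'
#' Evaluates [principalCurvatures()] at every mesh vertex (from the field,
#' i.e. from volume information) and derives Gaussian curvature and
#' curvedness. Optionally (default) continues into the crest-line
#' quantities: the first-ring weighted estimate of \eqn{\nabla k_{max}}
#' and the extremality \eqn{e_{max} = \nabla k_{max} \cdot t_{max}}.
#'
#' Vertices with an undefined normal are flagged \code{degenerate}; a
#' warning summarises their count when they exceed 10% of the mesh.
#'
#' @param mesh a [SurfaceMesh-class].
#' @param field the [ScalarField-class] the mesh was extracted from.
#' @param h finite-difference step, as in [principalCurvatures()].
#' @param weights a [weightConfig()] for the gradient estimator.
#' @param extremal compute \code{gk.*} and \code{emax} columns (needs
#'   mesh adjacency).
#' @return data.frame, one row per vertex: \code{kmax}, \code{kmin},
#'   \code{tmax.*}, \code{tmin.*}, \code{K}, \code{C}, \code{degenerate},
#'   and (with \code{extremal}) \code{gk.x}, \code{gk.y}, \code{gk.z},
#'   \code{emax}.
#' @export
attachAttributes <- function(mesh, field, h = NULL,
                             weights = weightConfig(),
                             extremal = TRUE) {
  stopifnot(is(mesh, "SurfaceMesh"))
  attrs <- principalCurvatures(field, mesh@vertices, h = h)
  attrs$K <- gaussianCurvature(attrs$kmax, attrs$kmin)
  attrs$C <- curvedness(attrs$kmax, attrs$kmin)
  ndeg <- sum(attrs$degenerate)
  if (ndeg > 0.1 * nrow(attrs))
    warning(ndeg, " of ", nrow(attrs), " vertices are degenerate ",
            "(gradient below floor); consider a larger step h")
  if (extremal) {
    gk <- curvatureGradientAll(mesh, attrs, weights)
    attrs$gk.x <- gk[, 1]; attrs$gk.y <- gk[, 2]; attrs$gk.z <- gk[, 3]
    attrs$emax <- extremality(attrs, gk)
  }
  attrs
}
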