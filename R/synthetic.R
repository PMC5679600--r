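#' Construct an analytic test shape
#'
#' Shapes with a known implicit function and closed-form curvatures, used as
#' ground truth throughout the pipeline. All fields follow the
#' inside-positive convention: \eqn{F > 0} inside the object, \eqn{F = 0} on
#' its boundary.
#'
#' Implicit functions (centered forms, \eqn{u = q - center}):
#' \describe{
#'   \item{sphere}{\eqn{F = 1 - |u|^2 / r^2}; parameter \code{radius}.}
#'   \item{ellipsoid}{\eqn{F = 1 - \sum u_i^2 / a_i^2}; parameter
#'     \code{semiaxes} (length 3).}
#'   \item{superellipsoid}{\eqn{F = 1 - \sum |u_i / a_i|^p}; parameters
#'     \code{halfwidth} (scalar or length 3) and even \code{exponent}
#'     \eqn{p \ge 2}. With a large even exponent this is the "smooth cube":
#'     a cube with rounded edges and exactly 8 curvature-concentrated
#'     corners.}
#'   \item{torus}{\eqn{F = r^2 - (\sqrt{u_x^2 + u_y^2} - R)^2 - u_z^2}
#'     (ring radius \code{ring} = R in the xy-plane, tube radius
#'     \code{tube} = r).}
#' }
#'
#' @param kind shape kind.
#' @param center numeric(3) world-space center.
#' @param radius,semiaxes,halfwidth,exponent,ring,tube shape parameters, see
#'   Details.
#' @return an [AnalyticShape-class].
#' @examples
#' analyticShape("sphere", radius = 10)
#' analyticShape("superellipsoid", halfwidth = 20, exponent = 6,
#'               center = c(31.5, 31.5, 31.5))
#' @export
analyticShape <- function(kind = c("sphere", "ellipsoid", "superellipsoid",
                                   "torus"),
                          center = c(0, 0, 0), radius = 1,
                          semiaxes = c(1, 1, 1), halfwidth = 1, exponent = 6,
                          ring = 2, tube = 0.5) {
  kind <- match.arg(kind)
  params <- switch(kind,
    sphere = list(radius = radius),
    ellipsoid = list(semiaxes = rep(semiaxes, length.out = 3L)),
    superellipsoid = list(halfwidth = rep(halfwidth, length.out = 3L),
                          exponent = exponent),
    torus = list(ring = ring, tube = tube))
  new("AnalyticShape", kind = kind, center = as.double(center),
      parameters = params)
}

# raw implicit function of a shape (inside positive), vectorized
.shapeFun <- function(shape) {
  ctr <- shape@center
  p <- shape@parameters
  switch(shape@kind,
    sphere = function(q) {
      u <- sweep(.asPoints(q), 2, ctr)
      1 - rowSums(u * u) / p$radius^2
    },
    ellipsoid = function(q) {
      u <- sweep(sweep(.asPoints(q), 2, ctr), 2, p$semiaxes, "/")
      1 - rowSums(u * u)
    },
    superellipsoid = function(q) {
      u <- abs(sweep(sweep(.asPoints(q), 2, ctr), 2, p$halfwidth, "/"))
      1 - rowSums(u^p$exponent)
    },
    torus = function(q) {
      u <- sweep(.asPoints(q), 2, ctr)
      rho <- sqrt(u[, 1]^2 + u[, 2]^2)
      p$tube^2 - (rho - p$ring)^2 - u[, 3]^2
    })
}

# axis-aligned bounding half-extent of a shape
.shapeExtent <- function(shape) {
  p <- shape@parameters
  switch(shape@kind,
    sphere = rep(p$radius, 3),
    ellipsoid = p$semiaxes,
    superellipsoid = p$halfwidth,
    torus = c(p$ring + p$tube, p$ring + p$tube, p$tube))
}

#' Analytic implicit field of a shape
#'
#' Wraps the shape's implicit function as an [AnalyticField-class] with
#' isovalue 0, so the field's zero set is the shape boundary and the field
#' is positive inside.
#'
#' @param shape an [AnalyticShape-class].
#' @param margin domain margin beyond the shape's bounding box, as a
#'   fraction of its largest half-extent (default 0.5).
#' @return an [AnalyticField-class].
#' @export
analyticField <- function(shape, margin = 0.5) {
  ext <- .shapeExtent(shape) + margin * max(.shapeExtent(shape))
  scalarField(.shapeFun(shape), isovalue = 0,
              lower = shape@center - ext, upper = shape@center + ext)
}

#' Sample a shape onto a VolumeGrid
#'
#' Evaluates the analytic implicit function at every lattice node and adds
#' optional i.i.d. Gaussian noise. Deterministic for a fixed \code{seed}.
#' The shape should fit strictly inside the grid with at least a 2-voxel
#' margin so the extracted mesh is closed; a warning is raised otherwise
#' (the surface will be clipped at the open boundary).
#'
#' @param shape an [AnalyticShape-class].
#' @param dims integer(3) grid dimensions.
#' @param spacing numeric(3) voxel spacing (default 1,1,1).
#' @param origin numeric(3) world origin of the grid.
#' @param noise_sd standard deviation of additive Gaussian noise in field
#'   units (0 = noiseless).
#' @param seed integer RNG seed for the noise draw.
#' @return a [VolumeGrid-class].
#' @export
voxelize <- function(shape, dims, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                     noise_sd = 0, seed = 1L) {
  dims <- as.integer(dims)
  spacing <- rep(as.double(spacing), length.out = 3L)
  upper <- origin + (dims - 1) * spacing
  ext <- .shapeExtent(shape)
  if (any(shape@center - ext < origin + 2 * spacing) ||
      any(shape@center + ext > upper - 2 * spacing))
    warning("shape is within 2 voxels of the grid boundary; ",
            "the extracted surface will be clipped")
  nodes <- as.matrix(expand.grid(
    x = origin[1] + (seq_len(dims[1]) - 1) * spacing[1],
    y = origin[2] + (seq_len(dims[2]) - 1) * spacing[2],
    z = origin[3] + (seq_len(dims[3]) - 1) * spacing[3]))
  vals <- .shapeFun(shape)(nodes)   # expand.grid varies x fastest: file order
  if (noise_sd > 0)
    vals <- vals + withr::with_seed(as.integer(seed),
                                    stats::rnorm(length(vals), 0, noise_sd))
  volumeGrid(vals, dims = dims, spacing = spacing, origin = origin)
}

#' Closed-form surface curvatures of an analytic shape
#'
#' Test oracle: returns the exact principal curvatures, Gaussian curvature
#' and curvedness of the shape at a surface point, from the standard closed
#' forms (sphere: \eqn{k = 1/r}; ellipsoid: principal curvatures of
#' \eqn{\sum u_i^2/a_i^2 = 1}; torus: \eqn{1/tube} and
#' \eqn{\cos\phi/(ring + tube\cos\phi)}). Signs follow the convention that a
#' sphere is \eqn{+1/r} (convex surfaces have positive curvature).
#'
#' @param shape an [AnalyticShape-class] (superellipsoids are not supported:
#'   no simple closed form).
#' @param q numeric(3) point on the shape boundary.
#' @param tol how far (relative, in implicit-function value) \code{q} may be
#'   off-surface before an error is raised.
#' @return list with \code{k_max}, \code{k_min}, \code{K} (Gaussian) and
#'   \code{C} (curvedness).
#' @export
expectedGeometry <- function(shape, q, tol = 1e-6) {
  stopifnot(length(q) == 3L)
  if (shape@kind == "superellipsoid")
    stop("no closed-form curvature oracle for superellipsoids")
  f <- .shapeFun(shape)(matrix(q, 1))
  if (abs(f) > tol)
    stop("point is off the shape surface (|F| = ", format(abs(f)), ")")
  u <- q - shape@center
  p <- shape@parameters
  ks <- switch(shape@kind,
    sphere = rep(1 / p$radius, 2),
    ellipsoid = {
      a <- p$semiaxes
      # level set g = sum(u_i^2/a_i^2) - 1: shape operator of the ellipsoid
      grad <- 2 * u / a^2
      n <- grad / sqrt(sum(grad^2))
      H <- diag(2 / a^2)
      P <- diag(3) - tcrossprod(n)
      M <- (P %*% H %*% P) / sqrt(sum(grad^2))
      ev <- sort(eigen(M, symmetric = TRUE, only.values = TRUE)$values)
      ev[2:3]   # drop the structural zero along the normal
    },
    torus = {
      rho <- sqrt(u[1]^2 + u[2]^2)
      cosphi <- (rho - p$ring) / p$tube
      c(cosphi / (p$ring + p$tube * cosphi), 1 / p$tube)
    })
  k_max <- max(ks); k_min <- min(ks)
  list(k_max = k_max, k_min = k_min, K = k_max * k_min,
       C = sqrt((k_max^2 + k_min^2) / 2))
}
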