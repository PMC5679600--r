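# Shared fixtures, built once per test run. Everything is generated in code
# (no stored binary data); sizes are kept small so the whole suite stays
# fast while still exercising closed meshes of a few thousand triangles.

fix <- new.env()

# analytic sphere r = 10, meshed at cube size 1
fixSphere <- function() {
  if (is.null(fix$sphere)) {
    shape <- analyticShape("sphere", radius = 10)
    field <- analyticField(shape)
    mesh <- extractSurface(field, cube_size = 1, start = c(0, 0, 0),
                           rng_seed = 1)
    fix$sphere <- list(shape = shape, field = field, mesh = mesh)
  }
  fix$sphere
}

# analytic triaxial ellipsoid (semiaxes 16, 8, 6), meshed at cube size 1.
# triaxial rather than prolate: with two equal semiaxes the surface is
# axisymmetric, t_max is circumferential while grad(k_max) is meridional,
# and the extremality vanishes identically - no well-defined crest to test
fixEllipsoid <- function() {
  if (is.null(fix$ell)) {
    shape <- analyticShape("ellipsoid", semiaxes = c(16, 8, 6))
    field <- analyticField(shape)
    mesh <- extractSurface(field, cube_size = 1, start = c(0, 0, 0),
                           rng_seed = 1)
    attrs <- attachAttributes(mesh, field, h = 0.25)
    fix$ell <- list(shape = shape, field = field, mesh = mesh,
                    attrs = attrs)
  }
  fix$ell
}

# voxelized smooth cube at reduced resolution (48^3, halfwidth 15):
# same structure as the full study volume, cheaper to process in unit tests
fixSmoothCube <- function() {
  if (is.null(fix$cube)) {
    shape <- analyticShape("superellipsoid", halfwidth = 15, exponent = 6,
                           center = rep(23.5, 3))
    vol <- voxelize(shape, dims = c(48, 48, 48))
    field <- scalarField(vol, isovalue = 0)
    mesh <- extractSurface(field, cube_size = 1, start = rep(23.5, 3),
                           rng_seed = 1)
    attrs <- attachAttributes(mesh, field)
    crest <- linkPolylines(triangleZeroCrossings(mesh, attrs))
    fix$cube <- list(shape = shape, vol = vol, field = field, mesh = mesh,
                     attrs = attrs, crest = crest)
  }
  fix$cube
}

# the 8 corner positions of a voxelized smooth cube (surface points on the
# main diagonals: |u_i| = halfwidth * 3^(-1/exponent))
cubeCorners <- function(shape) {
  hw <- shape@parameters$halfwidth[1]
  p <- shape@parameters$exponent
  off <- hw * 3^(-1 / p)
  as.matrix(expand.grid(c(-off, off), c(-off, off), c(-off, off))) +
    matrix(shape@center, 8, 3, byrow = TRUE)
}

# a hand-built fan mesh: one center vertex + a planar ring of m neighbours,
# used to probe the first-ring gradient estimator on known curvature fields
ringMesh <- function(m = 6, radius = 1, jitter = 0) {
  th <- 2 * pi * (seq_len(m) - 1) / m + jitter
  verts <- rbind(c(0, 0, 0), cbind(radius * cos(th), radius * sin(th), 0))
  tris <- cbind(1L, 1L + seq_len(m), 1L + c(seq_len(m)[-1], 1L))
  new("SurfaceMesh", vertices = verts, triangles = tris,
      adjacency = .buildAdjacencyLocal(nrow(verts), tris))
}

.buildAdjacencyLocal <- function(nv, tris) {
  e <- rbind(tris[, c(1, 2)], tris[, c(2, 3)], tris[, c(1, 3)])
  e <- rbind(e, e[, 2:1])
  adj <- vector("list", nv)
  sp <- split(e[, 2], factor(e[, 1], levels = seq_len(nv)))
  for (v in seq_len(nv)) adj[[v]] <- sort(unique(sp[[v]]))
  adj
}

# minimal per-vertex attribute table for hand-built meshes
ringAttrs <- function(mesh, kmax, tmax = c(1, 0, 0)) {
  n <- nrow(vertices(mesh))
  tm <- matrix(tmax, n, 3, byrow = TRUE)
  data.frame(kmax = kmax, kmin = 0,
             tmax.x = tm[, 1], tmax.y = tm[, 2], tmax.z = tm[, 3],
             tmin.x = 0, tmin.y = 1, tmin.z = 0,
             degenerate = FALSE, K = 0, C = abs(kmax))
}

# independent brute-force evaluation of the first-ring weighted gradient
# (angle weight = cot of edge/axis angle, distance weight = normalized edge
# length, lambda mix); written as plain loops so it shares no code with the
# package implementation
bruteRingGradient <- function(p0, nbrs, k0, ki, lambda, cot_cap = 1e3) {
  n <- nrow(nbrs)
  dist <- numeric(n)
  for (i in seq_len(n))
    dist[i] <- sqrt(sum((nbrs[i, ] - p0)^2))
  wd <- dist / sum(dist)
  out <- numeric(3)
  for (ax in 1:3) {
    num <- 0; den <- 0
    for (i in seq_len(n)) {
      dlt <- nbrs[i, ] - p0
      perp <- sqrt(sum(dlt[-ax]^2))
      wa <- if (perp < 1e-12) sign(dlt[ax]) * cot_cap
            else min(cot_cap, max(-cot_cap, dlt[ax] / perp))
      w <- lambda * wa + (1 - lambda) * wd[i]
      num <- num + w * (ki[i] - k0)
      den <- den + abs(w)
    }
    out[ax] <- if (den < 1e-12) 0 else num / den
  }
  out
}
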