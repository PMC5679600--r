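test_that("first rings are symmetric, deduplicated and ordered", {
  s <- fixSphere()
  m <- s$mesh
  set.seed(4)
  for (v in sample(nrow(vertices(m)), 25)) {
    nb <- firstRing(m, v)
    expect_gte(length(nb), 3)           # interior vertex of a closed mesh
    expect_false(any(duplicated(nb)))
    expect_identical(nb, sort(nb))
    for (u in nb[1:2]) expect_true(v %in% firstRing(m, u))
  }
  # tetrahedron: every vertex has exactly the other 3 as neighbours
  tet <- new("SurfaceMesh",
             vertices = rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0),
                              c(0, 0, 1)),
             triangles = rbind(c(1L, 2L, 3L), c(1L, 2L, 4L), c(1L, 3L, 4L),
                               c(2L, 3L, 4L)),
             adjacency = list(2:4, c(1L, 3L, 4L), c(1L, 2L, 4L), 1:3))
  for (v in 1:4) expect_length(firstRing(tet, v), 3)
})

test_that("angle weights implement the signed clamped cotangent", {
  expect_equal(angleWeight(c(0, 0, 0), c(1, 1, 0), "x"), 1)
  expect_equal(angleWeight(c(0, 0, 0), c(-1, 1, 0), "x"), -1)
  # axis-aligned neighbour: clamped to the cap with the offset's sign
  expect_equal(angleWeight(c(0, 0, 0), c(1, 0, 0), "x"), 1e3)
  expect_equal(angleWeight(c(0, 0, 0), c(-1, 0, 0), "x", cot_cap = 50), -50)
  # cyclic permutation for the other axes
  expect_equal(angleWeight(c(0, 0, 0), c(3, 4, 0), "y"),
               4 / sqrt(9 + 0))
  expect_equal(angleWeight(c(0, 0, 0), c(0, 3, 4), "z"), 4 / 3)
  # magnitude clamp
  expect_equal(angleWeight(c(0, 0, 0), c(10, 1e-4, 0), "x", cot_cap = 100),
               100)
  expect_error(angleWeight(c(1, 2, 3), c(1, 2, 3), "x"), "coincides")
})

test_that("distance weights are normalized edge lengths", {
  tgt <- c(0, 0, 0)
  # n equidistant neighbours share the weight equally
  nb <- rbind(c(1, 0, 0), c(0, 1, 0), c(-1, 0, 0), c(0, -1, 0))
  expect_equal(distanceWeight(tgt, nb), rep(0.25, 4))
  # distances 1 and 3 -> weights 1/4 and 3/4 (proportional to distance)
  expect_equal(distanceWeight(tgt, rbind(c(1, 0, 0), c(3, 0, 0))),
               c(0.25, 0.75))
  set.seed(8)
  for (i in 1:5) {
    nb <- matrix(rnorm(15), ncol = 3)
    expect_equal(sum(distanceWeight(tgt, nb)), 1)
  }
  expect_error(distanceWeight(tgt, rbind(tgt, tgt)), "coincide")
})

test_that("the ring estimator agrees with brute-force weight evaluation everywhere", {
  # the implementation must equal an independently coded evaluation of the
  # weighted-sum estimator for arbitrary rings, mixes and fields
  for (m in c(5, 6, 8)) {
    mesh <- ringMesh(m = m, radius = 1, jitter = 0.3)
    p0 <- vertices(mesh)[1, ]
    nbrs <- vertices(mesh)[-1, , drop = FALSE]
    for (lam in c(0, 0.25, 0.5, 1)) {
      for (grad in list(c(1, 0, 0), c(0.5, -0.2, 0), c(-2, 1, 0))) {
        k <- as.vector(vertices(mesh) %*% grad) + 0.7
        est <- curvatureGradient(mesh, ringAttrs(mesh, k), 1L,
                                 weightConfig(lambda = lam))
        brute <- bruteRingGradient(p0, nbrs, k[1], k[-1], lambda = lam)
        expect_equal(as.vector(est), brute, tolerance = 1e-12)
        # no z-variation in a planar ring
        expect_lt(abs(est[3]), 1e-9)
      }
    }
  }
})

test_that("gradient recovery on a regular hex ring with a linear field", {
  # canonical fixture: regular hexagon, k = g*x + const; the angle-bearing
  # mixes recover the gradient with correct sign and bounded magnitude
  mesh <- ringMesh(m = 6, radius = 1)
  for (lam in c(0.5, 1)) {
    for (gx in c(1, -1, 2)) {
      k <- gx * vertices(mesh)[, 1] + 0.3
      est <- curvatureGradient(mesh, ringAttrs(mesh, k), 1L,
                               weightConfig(lambda = lam))
      expect_identical(sign(est[1]), sign(gx))
      expect_lt(abs(est[1] - gx), 0.25 * abs(gx))
      expect_lt(abs(est[2]), 1e-9)
    }
  }
  # the pure distance weight (lambda = 0) is direction-blind: on a
  # centered ring its numerator cancels exactly (a documented limit of
  # the estimator, not a bug)
  k <- vertices(mesh)[, 1] + 0.3
  est0 <- curvatureGradient(mesh, ringAttrs(mesh, k), 1L,
                            weightConfig(lambda = 0))
  expect_equal(as.vector(est0), c(0, 0, 0), tolerance = 1e-12)
})

test_that("estimator edge cases: constant field, lambda endpoints, degenerate rings", {
  mesh <- ringMesh(6)
  attrs <- ringAttrs(mesh, kmax = rep(2, 7))
  est <- curvatureGradient(mesh, attrs, 1L)
  expect_equal(as.vector(est), c(0, 0, 0))

  k <- vertices(mesh)[, 1] + 1
  a1 <- curvatureGradient(mesh, ringAttrs(mesh, k), 1L,
                          weightConfig(lambda = 1))
  a0 <- curvatureGradient(mesh, ringAttrs(mesh, k), 1L,
                          weightConfig(lambda = 0))
  expect_false(isTRUE(all.equal(as.vector(a1), as.vector(a0))))

  # all neighbours degenerate -> zero gradient, flagged
  attrs <- ringAttrs(mesh, kmax = k)
  attrs$degenerate[-1] <- TRUE
  est <- curvatureGradient(mesh, attrs, 1L)
  expect_equal(as.vector(est), c(0, 0, 0))
  expect_true(attr(est, "degenerate"))
})

test_that("extremality is the gradient / principal-direction dot product", {
  attrs <- data.frame(tmax.x = 1, tmax.y = 0, tmax.z = 0)
  expect_equal(extremality(attrs, c(0, 5, -2)), 0)   # orthogonal
  expect_equal(extremality(attrs, c(3, 1, 1)), 3)
  attrs2 <- data.frame(tmax.x = c(1, 0), tmax.y = c(0, 1),
                       tmax.z = c(0, 0))
  expect_equal(extremality(attrs2, rbind(c(1, 2, 3), c(4, 5, 6))),
               c(1, 5))
})

test_that("triangle zero-crossings implement the sign-pattern case table", {
  # single triangle, e = (+1, -1, -1): one segment, crossings at midpoints
  tri <- new("SurfaceMesh",
             vertices = rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
             triangles = matrix(c(1L, 2L, 3L), 1),
             adjacency = list(c(2L, 3L), c(1L, 3L), c(1L, 2L)))
  mkAttrs <- function(e) data.frame(
    kmax = 1, kmin = 0, tmax.x = 1, tmax.y = 0, tmax.z = 0,
    tmin.x = 0, tmin.y = 1, tmin.z = 0, degenerate = FALSE,
    K = c(10, 20, 30), C = c(1, 2, 3), emax = e)
  cr <- triangleZeroCrossings(tri, mkAttrs(c(1, -1, -1)))
  expect_equal(nrow(crestSegments(cr)), 1)
  expect_equal(nrow(crestPoints(cr)), 2)
  pts <- crestPoints(cr)[order(crestPoints(cr)[, 1]), ]
  expect_equal(pts, rbind(c(0, 0.5, 0), c(0.5, 0, 0)),
               ignore_attr = TRUE)
  # interpolated attributes at the midpoints
  expect_equal(sort(cr@info$K), c(15, 20))
  expect_equal(sort(cr@info$C), c(1.5, 2))

  # all same sign: nothing
  expect_equal(nrow(crestSegments(
    triangleZeroCrossings(tri, mkAttrs(c(1, 2, 3))))), 0)
  expect_equal(nrow(crestSegments(
    triangleZeroCrossings(tri, mkAttrs(c(-1, -2, -3))))), 0)

  # an exact zero counts as positive; with the others (+,-) the crossing on
  # the zero vertex's edge falls on the vertex itself
  cr0 <- triangleZeroCrossings(tri, mkAttrs(c(0, 1, -1)))
  expect_equal(nrow(crestSegments(cr0)), 1)
  expect_true(any(apply(crestPoints(cr0), 1, function(p)
    all(p == c(0, 0, 0)))))

  # a degenerate vertex suppresses the triangle and is counted
  at <- mkAttrs(c(1, -1, -1)); at$degenerate[2] <- TRUE
  crd <- triangleZeroCrossings(tri, at)
  expect_equal(nrow(crestSegments(crd)), 0)
  expect_equal(crd@meta$skipped, 1)
})

test_that("per-triangle sign alignment removes spurious crossings from t_max flips", {
  tri <- new("SurfaceMesh",
             vertices = rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
             triangles = matrix(c(1L, 2L, 3L), 1),
             adjacency = list(c(2L, 3L), c(1L, 3L), c(1L, 2L)))
  # same underlying extremality field, but vertex 2 stores -t_max and
  # therefore -e: oriented mode must flip it back and find no crossing
  attrs <- data.frame(kmax = 1, kmin = 0,
                      tmax.x = c(1, -1, 1), tmax.y = 0, tmax.z = 0,
                      tmin.x = 0, tmin.y = 1, tmin.z = 0,
                      degenerate = FALSE, K = 0, C = 0,
                      emax = c(1, -1, 1))
  expect_equal(nrow(crestSegments(triangleZeroCrossings(tri, attrs))), 0)
  expect_equal(nrow(crestSegments(
    triangleZeroCrossings(tri, attrs, oriented = FALSE))), 1)
})

test_that("zero-crossing conservation: every crossed triangle has exactly 2 crossings", {
  e <- fixEllipsoid()
  cr <- triangleZeroCrossings(e$mesh, e$attrs)
  # each segment is one triangle's pair of crossings
  expect_equal(nrow(crestSegments(cr)), cr@meta$triangles)
  # every crest point lies on a mesh edge: its two edge vertices are
  # adjacent in the mesh
  info <- cr@info
  adj <- adjacency(e$mesh)
  on_edge <- mapply(function(a, b) b %in% adj[[a]], info$edge1, info$edge2)
  expect_true(all(on_edge))
  expect_true(all(info$t >= 0 & info$t <= 1))
})

test_that("the triaxial ellipsoid crest follows the long principal section", {
  # for semiaxes a > b > c the k_max crest is the z = 0 principal section:
  # t_max points along z there, reflection symmetry forces the extremality
  # through zero across it, and the long-axis poles (the Gaussian-curvature
  # maxima) lie on it
  e <- fixEllipsoid()
  cr <- linkPolylines(triangleZeroCrossings(e$mesh, e$attrs))
  expect_gt(nrow(crestPoints(cr)), 0)
  lens <- lengths(polylines(cr))
  main <- polylines(cr)[[which.max(lens)]]
  pts <- crestPoints(cr)[main, , drop = FALSE]
  expect_gt(length(main), 20)
  expect_lt(stats::median(abs(pts[, 3])), 2)  # near the z = 0 plane
  # and on the boundary ellipse of that plane
  ell <- (pts[, 1] / 16)^2 + (pts[, 2] / 8)^2
  expect_lt(stats::median(abs(ell - 1)), 0.15)
})

test_that("polyline linking is deterministic and respects chain structure", {
  e <- fixEllipsoid()
  cr1 <- linkPolylines(triangleZeroCrossings(e$mesh, e$attrs))
  cr2 <- linkPolylines(triangleZeroCrossings(e$mesh, e$attrs))
  expect_identical(polylines(cr1), polylines(cr2))
  # two disjoint segments yield two polylines
  cs <- new("CrestSet",
            points = rbind(c(0, 0, 0), c(1, 0, 0), c(5, 0, 0), c(6, 0, 0)),
            info = data.frame(edge1 = 1:4, edge2 = 2:5, t = 0.5,
                              K = 0, C = 0),
            segments = rbind(c(1L, 2L), c(3L, 4L)),
            polylines = list(), meta = list())
  linked <- linkPolylines(cs)
  expect_length(polylines(linked), 2)
  # every crest point appears at most twice within a chain
  for (ch in polylines(linked)) expect_true(all(table(ch) <= 2))
})

test_that("crest topology is stable under rigid motion of the field", {
  ax <- c(0, 0, 1); th <- 0.5
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  efun <- function(q)
    1 - ((q[, 1] / 16)^2 + (q[, 2] / 8)^2 + (q[, 3] / 6)^2)
  f0 <- scalarField(efun, lower = rep(-24, 3), upper = rep(24, 3))
  fR <- scalarField(function(q) efun(q %*% R),
                    lower = rep(-24, 3), upper = rep(24, 3))
  m0 <- extractSurface(f0, cube_size = 1, start = c(0, 0, 0), rng_seed = 1)
  mR <- extractSurface(fR, cube_size = 1, start = c(0, 0, 0), rng_seed = 1)
  c0 <- linkPolylines(triangleZeroCrossings(m0,
                                            attachAttributes(m0, f0, h = 0.25)))
  cR <- linkPolylines(triangleZeroCrossings(mR,
                                            attachAttributes(mR, fR, h = 0.25)))
  # compare the structural crest (substantial chains); isolated crossings
  # are the near-zero extremality noise floor and grid-orientation bound
  chainPts <- function(cr) {
    l <- lengths(polylines(cr))
    sum(l[l >= 10])
  }
  n0 <- chainPts(c0); nR <- chainPts(cR)
  expect_lt(abs(n0 - nR) / max(n0, nR), 0.05)
})
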