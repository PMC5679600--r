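test_that("seed search lands on the surface and reports failure cleanly", {
  s <- fixSphere()
  seed <- findSeed(s$field, start = c(0, 0, 0), step = 1, rng_seed = 3)
  expect_lt(abs(sqrt(sum(seed^2)) - 10), 1e-3)
  expect_lt(abs(attr(seed, "value")), 1e-3)

  # random starts also converge, deterministically per seed
  s1 <- findSeed(s$field, start = "random", step = 1, rng_seed = 5)
  s2 <- findSeed(s$field, start = "random", step = 1, rng_seed = 5)
  expect_identical(as.vector(s1), as.vector(s2))

  cst <- scalarField(function(q) rep(1, nrow(q)), lower = rep(-2, 3),
                     upper = rep(2, 3))
  expect_error(findSeed(cst, start = c(0, 0, 0), max_steps = 50),
               "no surface found")
  expect_error(findSeed(s$field, start = c(100, 0, 0)), "outside")
})

test_that("bisection halves the bracket per step", {
  # linear field: after n bisections of [0, 1] the seed is within 2^-n
  lin <- scalarField(function(q) 0.3 - q[, 1], lower = rep(-2, 3),
                     upper = rep(2, 3))
  seed <- findSeed(lin, start = c(0, 0, 0), step = 1, rng_seed = 1,
                   tol = 1e-12)
  # 24 iterations cap: |x - 0.3| <= 1 / 2^24
  expect_lt(abs(seed[1] - 0.3), 1 / 2^24 + 1e-12)
})

test_that("continuation tracks exactly the mixed-polarity cubes covering the surface", {
  s <- fixSphere()
  seed <- findSeed(s$field, start = c(0, 0, 0), step = 1, rng_seed = 1)
  tr <- trackCubes(s$field, seed, cube_size = 1)
  expect_true(all(rowSums(tr$values >= 0) %in% 1:7))
  expect_false(any(duplicated(paste(tr$cubes[, 1], tr$cubes[, 2],
                                    tr$cubes[, 3]))))

  # coverage: densely sampled analytic surface points all lie in some cube
  set.seed(2)
  u <- matrix(rnorm(3000), ncol = 3)
  u <- 10 * u / sqrt(rowSums(u^2))
  cu <- floor(sweep(u, 2, tr$lower) / tr$cube_size)
  keys <- paste(cu[, 1], cu[, 2], cu[, 3])
  tracked <- paste(tr$cubes[, 1], tr$cubes[, 2], tr$cubes[, 3])
  expect_true(all(keys %in% tracked))

  # no cube may poke outside the domain
  up <- floor((s$field@upper - s$field@lower) / tr$cube_size)
  expect_true(all(tr$cubes >= 0))
  expect_true(all(sweep(tr$cubes + 1, 2, up, "<=")))

  expect_error(trackCubes(s$field, seed, cube_size = 1, max_cubes = 10),
               "runaway")
})

test_that("tracked-cube count scales like the inverse square of the cube size", {
  s <- fixSphere()
  sizes <- c(2, 1, 0.5)
  counts <- vapply(sizes, function(cs) {
    seed <- findSeed(s$field, start = c(0, 0, 0), step = cs, rng_seed = 1)
    nrow(trackCubes(s$field, seed, cube_size = cs)$cubes)
  }, 0)
  fit <- stats::lm(log(counts) ~ log(1 / sizes))
  expect_equal(unname(stats::coef(fit)[2]), 2, tolerance = 0.3)
})

test_that("the tetrahedral kernel emits the documented case table", {
  P <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  # one positive corner: one triangle, vertices at the linear zeros
  tri <- tetTriangles(c(1, -1, -1, -1), P)
  expect_length(tri, 1)
  expect_equal(sort(tri[[1]][, 1] + tri[[1]][, 2] + tri[[1]][, 3]),
               c(0.5, 0.5, 0.5))   # t = 1/(1+1) = 0.5 on each edge
  # 2-2 split: two triangles
  expect_length(tetTriangles(c(1, 1, -1, -1), P), 2)
  # uniform signs: nothing
  expect_length(tetTriangles(c(1, 2, 3, 4), P), 0)
  expect_length(tetTriangles(c(-1, -2, -3, -4), P), 0)
  # asymmetric values: crossing at v_a/(v_a - v_b)
  tri <- tetTriangles(c(3, -1, -1, -1), P)
  expect_equal(max(tri[[1]]), 0.75)  # 3/(3+1) along each unit edge
  # corner values (+2, -2): crossing at the edge midpoint
  tri <- tetTriangles(c(2, -2, -2, -2), P)
  expect_equal(sort(unique(round(as.vector(tri[[1]]), 9))), c(0, 0.5))
})

test_that("triangle orientation points outward for an inside-positive field", {
  s <- fixSphere()
  m <- s$mesh
  v <- vertices(m); tr <- triangles(m)
  a <- v[tr[, 1], ]; b <- v[tr[, 2], ]; c_ <- v[tr[, 3], ]
  n <- cbind((b[, 2] - a[, 2]) * (c_[, 3] - a[, 3]) -
             (b[, 3] - a[, 3]) * (c_[, 2] - a[, 2]),
             (b[, 3] - a[, 3]) * (c_[, 1] - a[, 1]) -
             (b[, 1] - a[, 1]) * (c_[, 3] - a[, 3]),
             (b[, 1] - a[, 1]) * (c_[, 2] - a[, 2]) -
             (b[, 2] - a[, 2]) * (c_[, 1] - a[, 1]))
  ctr <- (a + b + c_) / 3
  expect_true(all(rowSums(n * ctr) > 0))  # outward on a sphere at origin
})

test_that("the batch polygonizer agrees with the scalar cube kernel", {
  s <- fixSphere()
  seed <- findSeed(s$field, start = c(0, 0, 0), step = 2, rng_seed = 1)
  tr <- trackCubes(s$field, seed, cube_size = 2)
  # independent route: loop the reference kernel over every tracked cube
  ref <- list()
  for (i in seq_len(nrow(tr$cubes))) {
    ref <- c(ref, polygonizeCube(tr$values[i, ],
                                 origin = tr$lower + tr$cubes[i, ] * 2,
                                 size = 2))
  }
  mesh <- extractSurface(s$field, cube_size = 2, start = c(0, 0, 0),
                         rng_seed = 1)
  expect_equal(length(ref), nrow(triangles(mesh)))
  # same triangle geometry set (compare sorted centroid keys)
  ctrRef <- t(vapply(ref, colMeans, numeric(3)))
  v <- vertices(mesh); tri <- triangles(mesh)
  ctrMesh <- (v[tri[, 1], ] + v[tri[, 2], ] + v[tri[, 3], ]) / 3
  keyOf <- function(m) sort(apply(round(m, 9), 1, paste, collapse = ","))
  expect_identical(keyOf(ctrRef), keyOf(ctrMesh))
  expect_error(polygonizeCube(rep(1, 8)), "polarity")
})

test_that("emitted vertices lie on the piecewise-linear zero set", {
  s <- fixSphere()
  # |F| at a mesh vertex is bounded by the interpolation residual of one
  # cube cell, far below the field variation across a cell (~0.2 here)
  expect_lt(max(abs(fieldValue(s$field, vertices(s$mesh)))), 0.05)
})

test_that("extracted meshes are closed, deterministic and metrically accurate", {
  s <- fixSphere()
  st <- meshStats(s$mesh)
  expect_true(st$closed)
  expect_equal(st$euler, 2)
  # closed genus-0 identity: T = 2V - 4, ratio = 2 - 4/V
  expect_equal(st$n_triangles, 2 * st$n_vertices - 4)
  expect_equal(st$ratio, 2 - 4 / st$n_vertices, tolerance = 1e-12)

  m2 <- extractSurface(s$field, cube_size = 1, start = c(0, 0, 0),
                       rng_seed = 1)
  expect_identical(vertices(m2), vertices(s$mesh))
  expect_identical(triangles(m2), triangles(s$mesh))

  d <- sqrt(rowSums(vertices(s$mesh)^2))
  expect_lt(max(abs(d - 10)), 1)   # within one cube size of the sphere
})

test_that("halving the cube size keeps a well-resolved shape connected", {
  s <- fixSphere()
  for (cs in c(2, 1)) {
    m <- extractSurface(s$field, cube_size = cs, start = c(0, 0, 0),
                        rng_seed = 1)
    expect_equal(max(meshComponents(m)), 1)
  }
})

test_that("meshStats handles edge cases", {
  single <- new("SurfaceMesh",
                vertices = rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                triangles = matrix(c(1L, 2L, 3L), 1),
                adjacency = list(c(2L, 3L), c(1L, 3L), c(1L, 2L)))
  st <- meshStats(single)
  expect_equal(st$ratio, 1 / 3)
  expect_false(st$closed)
  empty <- new("SurfaceMesh", vertices = matrix(0, 0, 3),
               triangles = matrix(0L, 0, 3), adjacency = list())
  expect_error(meshStats(empty), "empty")
})
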