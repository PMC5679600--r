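# corner j = 1 + bx + 2*by + 4*bz, i.e. v000, v100, v010, v110, v001, ...
.CORNER_OFF <- cbind(bx = c(0L,1L,0L,1L,0L,1L,0L,1L),
                     by = c(0L,0L,1L,1L,0L,0L,1L,1L),
                     bz = c(0L,0L,0L,0L,1L,1L,1L,1L))

# cube faces: corner subsets and propagation direction
.FACES <- list(
  list(c = c(1L,3L,5L,7L), d = c(-1L, 0L, 0L)),
  list(c = c(2L,4L,6L,8L), d = c( 1L, 0L, 0L)),
  list(c = c(1L,2L,5L,6L), d = c( 0L,-1L, 0L)),
  list(c = c(3L,4L,7L,8L), d = c( 0L, 1L, 0L)),
  list(c = c(1L,2L,3L,4L), d = c( 0L, 0L,-1L)),
  list(c = c(5L,6L,7L,8L), d = c( 0L, 0L, 1L)))

# Kuhn decomposition: 6 tetrahedra sharing the main diagonal corner1-corner8
.TETS <- rbind(c(1L,2L,4L,8L), c(1L,2L,6L,8L), c(1L,3L,4L,8L),
               c(1L,3L,7L,8L), c(1L,5L,6L,8L), c(1L,5L,7L,8L))

#' Locate a seed point on the isosurface
#'
#' Marches from a starting point in straight lines until the field changes
#' sign between consecutive steps, then bisects the bracketing pair until
#' the interval is shorter than \code{tol} (or 24 bisections). Each restart
#' draws a fresh direction (and, with \code{start = "random"}, a fresh
#' uniform starting point) from an RNG seeded with \code{rng_seed}, so the
#' search is deterministic.
#'
#' @param field a [ScalarField-class].
#' @param start numeric(3) starting point, or \code{"random"}.
#' @param step march step length; default 1/64 of the smallest domain
#'   extent.
#' @param rng_seed integer seed for direction/start draws.
#' @param max_steps maximum march steps per restart.
#' @param restarts number of direction restarts before giving up.
#' @param tol bisection convergence interval; default \code{1e-4 * step}.
#' @return numeric(3) point with \eqn{|F|} at bisection tolerance, with the
#'   achieved \code{"value"} as an attribute.
#' @export
findSeed <- function(field, start = "random", step = NULL, rng_seed = 0L,
                     max_steps = 1000L, restarts = 10L, tol = NULL) {
  stopifnot(max_steps >= 1L)
  lo <- field@lower; up <- field@upper
  step <- step %||% (min(up - lo) / 64)
  tol <- tol %||% (1e-4 * step)
  randomStart <- identical(start, "random")
  if (!randomStart) {
    start <- as.double(start)
    if (!all(.inBounds(field, start)))
      stop("seed search start point is outside the field domain")
  }
  withr::with_seed(as.integer(rng_seed), {
    for (r in seq_len(max(1L, restarts))) {
      p0 <- if (randomStart) lo + stats::runif(3) * (up - lo) else start
      u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
      # march both ways along u so a supervised start is used efficiently
      for (sgn in c(1, -1)) {
        q <- matrix(p0, 1)
        f0 <- fieldValue(field, q)
        for (s in seq_len(max_steps)) {
          qn <- q + sgn * step * u
          if (!all(.inBounds(field, qn))) break
          f1 <- fieldValue(field, qn)
          if (is.finite(f0) && is.finite(f1) &&
              (sign(f1) != sign(f0) || f1 == 0)) {
            res <- .bisectSeed(field, q, qn, f0, f1, tol)
            return(res)
          }
          q <- qn; f0 <- f1
        }
      }
    }
    stop("no surface found: the field did not change sign within ",
         max_steps, " steps over ", restarts, " restarts; try a different ",
         "start point or isovalue")
  })
}

.bisectSeed <- function(field, a, b, fa, fb, tol, max_iter = 24L) {
  for (i in seq_len(max_iter)) {
    if (sqrt(sum((b - a)^2)) < tol) break
    m <- (a + b) / 2
    fm <- fieldValue(field, m)
    if (fm == 0) { a <- m; fa <- fm; break }
    if (sign(fm) == sign(fa)) { a <- m; fa <- fm } else { b <- m; fb <- fm }
  }
  out <- as.double(if (abs(fa) <= abs(fb)) a else b)
  attr(out, "value") <- fieldValue(field, matrix(out, 1))
  out
}

#' Track all surface-intersecting cubes by continuation
#'
#' Breadth-first continuation over a uniform cubic lattice anchored at the
#' field's lower domain corner: starting from the cube containing the seed,
#' a cube propagates across each face whose 4 corner signs are mixed. Every
#' returned cube has mixed corner polarity, no cube is visited twice, and no
#' cube with a corner outside the domain is tracked (open-boundary
#' clipping: no geometry is generated outside the volume dimensions).
#'
#' @param field a [ScalarField-class].
#' @param seed numeric(3) point on the surface (see [findSeed()]).
#' @param cube_size edge length of the continuation cubes, world units.
#' @param max_cubes abort if more cubes than this are tracked (runaway
#'   propagation guard).
#' @return list with \code{cubes} (n-by-3 integer lattice coordinates),
#'   \code{values} (n-by-8 corner field values in v000..v111 order),
#'   \code{cube_size} and \code{lower} (lattice anchor).
#' @export
trackCubes <- function(field, seed, cube_size, max_cubes = 2^20) {
  stopifnot(cube_size > 0)
  lo <- field@lower; up <- field@upper
  cs <- cube_size
  nmax <- floor((up - lo) / cs + 1e-9)   # cubes per axis
  if (any(nmax < 1))
    stop("cube_size exceeds the field domain")
  seedCube <- pmin(pmax(floor((as.double(seed) - lo) / cs), 0), nmax - 1)

  cornerVals <- function(cubes) {
    n <- nrow(cubes)
    out <- matrix(NA_real_, n, 8)
    for (j in 1:8) {
      pts <- sweep(cubes, 2, .CORNER_OFF[j, ], "+") * cs
      pts <- sweep(pts, 2, lo, "+")
      out[, j] <- fieldValue(field, pts, outside = "na")
    }
    out
  }
  inB <- function(cubes)
    cubes[, 1] >= 0 & cubes[, 2] >= 0 & cubes[, 3] >= 0 &
    cubes[, 1] < nmax[1] & cubes[, 2] < nmax[2] & cubes[, 3] < nmax[3]

  visited <- new.env(hash = TRUE, parent = emptyenv())
  keyOf <- function(cubes) paste(cubes[, 1], cubes[, 2], cubes[, 3])

  frontier <- matrix(as.integer(seedCube), 1)
  # a seed from bisection can sit a hair outside its mixed cube; widen once
  v <- cornerVals(frontier)
  s <- rowSums(v >= 0)
  if (s %in% c(0L, 8L)) {
    nb <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
    frontier <- sweep(nb, 2, as.integer(seedCube), "+")
    frontier <- frontier[inB(frontier), , drop = FALSE]
  }

  accCubes <- vector("list", 64); accVals <- vector("list", 64); nacc <- 0L
  total <- 0L
  while (nrow(frontier) > 0L) {
    keys <- keyOf(frontier)
    keep <- !duplicated(keys)
    frontier <- frontier[keep, , drop = FALSE]; keys <- keys[keep]
    new <- !vapply(keys, function(k)
      exists(k, envir = visited, inherits = FALSE), logical(1))
    frontier <- frontier[new, , drop = FALSE]; keys <- keys[new]
    if (!nrow(frontier)) break
    for (k in keys) assign(k, TRUE, envir = visited)
    vals <- cornerVals(frontier)
    signs <- vals >= 0
    mixed <- rowSums(signs) %in% 1:7 & !apply(is.na(vals), 1, any)
    if (any(mixed)) {
      nacc <- nacc + 1L
      accCubes[[nacc]] <- frontier[mixed, , drop = FALSE]
      accVals[[nacc]] <- vals[mixed, , drop = FALSE]
      total <- total + sum(mixed)
      if (total > max_cubes)
        stop("runaway propagation: more than ", max_cubes,
             " surface cubes tracked; check the isovalue or raise max_cubes")
      mc <- frontier[mixed, , drop = FALSE]
      ms <- signs[mixed, , drop = FALSE]
      nxt <- vector("list", 6)
      for (f in seq_along(.FACES)) {
        fc <- .FACES[[f]]
        fmix <- rowSums(ms[, fc$c, drop = FALSE]) %in% 1:3
        if (any(fmix))
          nxt[[f]] <- sweep(mc[fmix, , drop = FALSE], 2, fc$d, "+")
      }
      frontier <- do.call(rbind, nxt[!vapply(nxt, is.null, logical(1))])
      if (is.null(frontier) || !nrow(frontier)) break
      frontier <- frontier[inB(frontier), , drop = FALSE]
      # deterministic order
      if (nrow(frontier))
        frontier <- frontier[order(frontier[, 3], frontier[, 2],
                                   frontier[, 1]), , drop = FALSE]
    } else frontier <- frontier[0, , drop = FALSE]
  }
  if (total == 0L)
    stop("no surface cube found at the seed; is the seed on the surface?")
  list(cubes = do.call(rbind, accCubes[seq_len(nacc)]),
       values = do.call(rbind, accVals[seq_len(nacc)]),
       cube_size = cs, lower = lo)
}

#' Triangulate one tetrahedron of the sign field
#'
#' Reference kernel of the polygonizer: given the field values and positions
#' of a tetrahedron's 4 corners, emits the piecewise-linear zero set inside
#' it. One corner differing in sign from the other three gives 1 triangle;
#' a 2-2 split gives a quad cut into 2 triangles. Each triangle vertex lies
#' at the linear zero \eqn{t = v_a / (v_a - v_b)} of a sign-change edge, and
#' triangles are oriented with the normal pointing toward decreasing field
#' (outward under the inside-positive convention). Zero values count as
#' positive.
#'
#' @param values numeric(4) corner field values.
#' @param positions 4-by-3 matrix of corner positions.
#' @return list of 3-by-3 matrices (one row per triangle vertex); empty when
#'   all corners share a sign.
#' @export
tetTriangles <- function(values, positions) {
  stopifnot(length(values) == 4L, all(dim(positions) == c(4L, 3L)))
  pos <- values >= 0
  np <- sum(pos)
  if (np == 0L || np == 4L) return(list())
  cross3 <- function(a, b) c(a[2]*b[3] - a[3]*b[2], a[3]*b[1] - a[1]*b[3],
                             a[1]*b[2] - a[2]*b[1])
  zero <- function(a, b) {
    t <- values[a] / (values[a] - values[b])
    positions[a, ] + t * (positions[b, ] - positions[a, ])
  }
  orient <- function(tri, ref) {
    # flip so the normal points away from the positive side (ref point)
    n <- cross3(tri[2, ] - tri[1, ], tri[3, ] - tri[1, ])
    if (sum(n * (ref - colMeans(tri))) > 0) tri[c(1, 3, 2), ] else tri
  }
  if (np == 1L || np == 3L) {
    o <- if (np == 1L) which(pos) else which(!pos)
    rest <- setdiff(1:4, o)
    tri <- rbind(zero(o, rest[1]), zero(o, rest[2]), zero(o, rest[3]))
    ref <- if (np == 1L) positions[o, ] else colMeans(positions[rest, ])
    list(orient(tri, ref))
  } else {
    P <- which(pos); N <- which(!pos)
    q <- rbind(zero(P[1], N[1]), zero(P[1], N[2]),
               zero(P[2], N[2]), zero(P[2], N[1]))
    ref <- colMeans(positions[P, , drop = FALSE])
    list(orient(q[c(1, 2, 3), ], ref), orient(q[c(1, 3, 4), ], ref))
  }
}

#' Triangulate one tracked cube
#'
#' Decomposes the cube into 6 tetrahedra sharing the main diagonal (the
#' Kuhn split, which keeps face diagonals consistent between neighbouring
#' cubes) and applies [tetTriangles()] to each. The corner value order is
#' v000, v100, v010, v110, v001, v101, v011, v111.
#'
#' @param values numeric(8) corner field values; must be mixed-sign.
#' @param origin numeric(3) world position of corner v000.
#' @param size cube edge length.
#' @return list of 3-by-3 triangle matrices.
#' @export
polygonizeCube <- function(values, origin = c(0, 0, 0), size = 1) {
  stopifnot(length(values) == 8L)
  s <- sum(values >= 0)
  if (s == 0L || s == 8L)
    stop("cube has uniform corner polarity; only mixed cubes intersect the surface")
  P <- sweep(.CORNER_OFF * size, 2, origin, "+")
  out <- list()
  for (t in 1:6) {
    cid <- .TETS[t, ]
    out <- c(out, tetTriangles(values[cid], P[cid, , drop = FALSE]))
  }
  out
}

# vectorized polygonization of all tracked cubes with exact vertex welding
# by global lattice edge key; returns vertices + triangle index matrix
.polygonizeBatch <- function(tracked) {
  cubes <- tracked$cubes; vals <- tracked$values
  cs <- tracked$cube_size; lo <- tracked$lower
  keyParts <- function(g) paste(g[, 1], g[, 2], g[, 3], sep = ",")
  triKeys <- vector("list", 256); triPos <- vector("list", 256); nt <- 0L

  emit <- function(rows, eA, eB, cid, refCorner) {
    # rows: cube row indices; eA/eB: tet-local corner pairs (list of edges,
    # 3 per triangle); cid: the tet's 4 cube-corner ids; refCorner: function
    # giving the positive-side reference point for orientation
    n <- length(rows)
    csub <- cubes[rows, , drop = FALSE]
    vsub <- vals[rows, cid, drop = FALSE]
    cornerPos <- function(j)   # world position of cube corner j (global id)
      sweep(sweep(csub, 2, .CORNER_OFF[j, ], "+") * cs, 2, lo, "+")
    cornerKey <- function(j)
      keyParts(sweep(csub, 2, .CORNER_OFF[j, ], "+"))
    edgeData <- function(a, b) {   # a,b: tet-local indices 1..4
      ja <- cid[a]; jb <- cid[b]
      va <- vsub[, a]; vb <- vsub[, b]
      t <- va / (va - vb)
      Pa <- cornerPos(ja); Pb <- cornerPos(jb)
      ka <- cornerKey(ja); kb <- cornerKey(jb)
      lowFirst <- ka <= kb
      key <- ifelse(lowFirst, paste(ka, kb, sep = "|"),
                    paste(kb, ka, sep = "|"))
      # a crossing exactly on a lattice corner (field value 0 there) is
      # shared by several edges: weld it by the corner, not the edge
      key[t == 0] <- paste0("c:", ka[t == 0])
      key[t == 1] <- paste0("c:", kb[t == 1])
      list(pos = Pa + t * (Pb - Pa), key = key)
    }
    ref <- refCorner(cornerPos, vsub)
    for (i in seq_along(eA)) {     # one triangle per entry
      e1 <- edgeData(eA[[i]][1], eB[[i]][1])
      e2 <- edgeData(eA[[i]][2], eB[[i]][2])
      e3 <- edgeData(eA[[i]][3], eB[[i]][3])
      # orient: normal away from positive reference
      u <- e2$pos - e1$pos; v <- e3$pos - e1$pos
      nx <- u[, 2] * v[, 3] - u[, 3] * v[, 2]
      ny <- u[, 3] * v[, 1] - u[, 1] * v[, 3]
      nz <- u[, 1] * v[, 2] - u[, 2] * v[, 1]
      ctr <- (e1$pos + e2$pos + e3$pos) / 3
      flip <- (nx * (ref[, 1] - ctr[, 1]) + ny * (ref[, 2] - ctr[, 2]) +
               nz * (ref[, 3] - ctr[, 3])) > 0
      k2 <- ifelse(flip, e3$key, e2$key)
      k3 <- ifelse(flip, e2$key, e3$key)
      p2 <- e2$pos; p3 <- e3$pos
      p2[flip, ] <- e3$pos[flip, , drop = FALSE]
      p3[flip, ] <- e2$pos[flip, , drop = FALSE]
      nt <<- nt + 1L
      if (nt > length(triKeys)) {
        length(triKeys) <<- 2L * nt; length(triPos) <<- 2L * nt
      }
      triKeys[[nt]] <<- cbind(e1$key, k2, k3)
      triPos[[nt]] <<- cbind(e1$pos, p2, p3)   # 9 columns
    }
  }

  signs <- vals >= 0
  for (t in 1:6) {
    cid <- .TETS[t, ]
    S <- signs[, cid, drop = FALSE]
    code <- S[, 1] + 2L * S[, 2] + 4L * S[, 3] + 8L * S[, 4]
    for (cd in sort(unique(code))) {
      if (cd == 0L || cd == 15L) next
      rows <- which(code == cd)
      bits <- as.logical(bitwAnd(cd, c(1L, 2L, 4L, 8L)))
      np <- sum(bits)
      if (np == 1L || np == 3L) {
        o <- if (np == 1L) which(bits) else which(!bits)
        rest <- setdiff(1:4, o)
        refFn <- if (np == 1L) {
          function(cp, v) cp(cid[o])
        } else {
          function(cp, v)
            (cp(cid[rest[1]]) + cp(cid[rest[2]]) + cp(cid[rest[3]])) / 3
        }
        emit(rows, eA = list(rep(o, 3)), eB = list(rest), cid = cid,
             refCorner = refFn)
      } else {
        P <- which(bits); N <- which(!bits)
        refFn <- function(cp, v) (cp(cid[P[1]]) + cp(cid[P[2]])) / 2
        # quad (P1,N1) (P1,N2) (P2,N2) (P2,N1) -> triangles 123 and 134
        emit(rows,
             eA = list(c(P[1], P[1], P[2]), c(P[1], P[2], P[2])),
             eB = list(c(N[1], N[2], N[2]), c(N[1], N[2], N[1])),
             cid = cid, refCorner = refFn)
      }
    }
  }

  allKeys <- do.call(rbind, triKeys[seq_len(nt)])
  allPos <- do.call(rbind, triPos[seq_len(nt)])
  keyVec <- as.vector(t(allKeys))                    # v1,v2,v3 per triangle
  # interleave positions in the same order as keyVec
  n <- nrow(allKeys)
  posVec <- matrix(NA_real_, 3L * n, 3L)
  posVec[seq(1, 3 * n, 3), ] <- allPos[, 1:3, drop = FALSE]
  posVec[seq(2, 3 * n, 3), ] <- allPos[, 4:6, drop = FALSE]
  posVec[seq(3, 3 * n, 3), ] <- allPos[, 7:9, drop = FALSE]
  first <- !duplicated(keyVec)
  uk <- keyVec[first]
  vid <- match(keyVec, uk)
  verts <- posVec[first, , drop = FALSE]
  tris <- matrix(vid, ncol = 3, byrow = TRUE)
  ok <- tris[, 1] != tris[, 2] & tris[, 2] != tris[, 3] &
        tris[, 1] != tris[, 3]
  tris <- tris[ok, , drop = FALSE]
  # drop vertices orphaned by degenerate-triangle removal
  used <- sort(unique(as.vector(tris)))
  if (length(used) < nrow(verts)) {
    remap <- integer(nrow(verts)); remap[used] <- seq_along(used)
    verts <- verts[used, , drop = FALSE]
    tris <- matrix(remap[tris], ncol = 3)
  }
  list(vertices = verts, triangles = tris)
}

.buildAdjacency <- function(nv, tris) {
  e <- rbind(tris[, c(1, 2)], tris[, c(2, 3)], tris[, c(1, 3)])
  e <- rbind(e, e[, 2:1])
  adj <- vector("list", nv)
  sp <- split(e[, 2], factor(e[, 1], levels = seq_len(nv)))
  for (v in seq_len(nv)) adj[[v]] <- sort(unique(sp[[v]]))
  adj
}

#' Extract the isosurface mesh of a field
#'
#' Runs the full first phase: seed search ([findSeed()]), cube continuation
#' ([trackCubes()]), per-cube tetrahedral triangulation and exact vertex
#' welding by lattice edge key (vertices on shared cube edges are merged
#' bit-exactly, never by distance tolerance). Deterministic for a fixed
#' \code{rng_seed}.
#'
#' @param field a [ScalarField-class].
#' @param cube_size continuation cube edge length (world units). Default:
#'   the smallest voxel spacing for grid fields, 1/64 of the smallest
#'   domain extent otherwise.
#' @param cube_frac alternative to \code{cube_size}: fraction of the largest
#'   domain extent (the "cube size proportional to data size" convenience).
#' @param start seed-search start point, or \code{"random"}.
#' @param rng_seed integer seed for the seed search.
#' @param max_cubes runaway-propagation cap.
#' @param ... further arguments passed to [findSeed()].
#' @return a [SurfaceMesh-class] with first-ring adjacency built. The
#'   tracked-cube count is attached as attribute \code{"n_cubes"}.
#' @examples
#' sph <- analyticShape("sphere", radius = 10)
#' m <- extractSurface(analyticField(sph), cube_size = 2, start = c(0, 0, 0))
#' meshStats(m)
#' @export
extractSurface <- function(field, cube_size = NULL, cube_frac = NULL,
                           start = "random", rng_seed = 0L,
                           max_cubes = 2^20, ...) {
  if (is.null(cube_size)) {
    cube_size <- if (!is.null(cube_frac))
      cube_frac * max(field@upper - field@lower)
    else if (is(field, "GridField")) min(field@grid@spacing)
    else min(field@upper - field@lower) / 64
  }
  seed <- findSeed(field, start = start, step = cube_size,
                   rng_seed = rng_seed, ...)
  tracked <- trackCubes(field, seed, cube_size, max_cubes = max_cubes)
  geo <- .polygonizeBatch(tracked)
  mesh <- new("SurfaceMesh", vertices = geo$vertices,
              triangles = geo$triangles,
              adjacency = .buildAdjacency(nrow(geo$vertices),
                                          geo$triangles))
  attr(mesh, "n_cubes") <- nrow(tracked$cubes)
  mesh
}

#' Mesh summary statistics
#'
#' Counts and the triangles-per-vertex ratio. For a closed genus-0 mesh
#' Euler's identity gives \eqn{T = 2V - 4}, so the ratio approaches 2 from
#' below as the mesh is refined.
#'
#' @param mesh a [SurfaceMesh-class].
#' @return list with \code{n_triangles}, \code{n_vertices}, \code{n_edges},
#'   \code{ratio} (= triangles/vertices), \code{euler}
#'   (\eqn{V - E + F}) and \code{closed} (every edge shared by exactly 2
#'   triangles).
#' @export
meshStats <- function(mesh) {
  stopifnot(is(mesh, "SurfaceMesh"))
  nv <- nrow(mesh@vertices); nt <- nrow(mesh@triangles)
  if (nt == 0L) stop("empty mesh")
  e <- rbind(mesh@triangles[, c(1, 2)], mesh@triangles[, c(2, 3)],
             mesh@triangles[, c(1, 3)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  ekey <- paste(e[, 1], e[, 2])
  tab <- table(ekey)
  ne <- length(tab)
  list(n_triangles = nt, n_vertices = nv, n_edges = ne,
       ratio = nt / nv, euler = nv - ne + nt,
       closed = all(tab == 2L))
}

#' Connected components of a mesh
#'
#' Labels vertices by connected component of the edge graph (used to detect
#' the polygonizer's cube-size failure mode, where an undersized cube grid
#' splits a thin feature).
#'
#' @param mesh a [SurfaceMesh-class].
#' @return integer vector of component labels (1-based), one per vertex.
#' @export
meshComponents <- function(mesh) {
  adj <- mesh@adjacency
  nv <- length(adj)
  comp <- integer(nv)
  cur <- 0L
  for (v in seq_len(nv)) {
    if (comp[v] != 0L) next
    cur <- cur + 1L
    queue <- v
    comp[v] <- cur
    while (length(queue)) {
      u <- queue[[1]]; queue <- queue[-1]
      nb <- adj[[u]]
      nb <- nb[comp[nb] == 0L]
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}
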