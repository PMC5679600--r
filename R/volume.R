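#' Construct a VolumeGrid
#'
#' @param data 3D numeric array of intensities (dimensions nx, ny, nz, all
#'   >= 2), or a numeric vector of length nx*ny*nz together with \code{dims}.
#'   Vector input is filled with x varying fastest, then y, then z.
#' @param dims integer(3), required when \code{data} is a vector.
#' @param spacing numeric(3) positive voxel spacing (default 1,1,1).
#' @param origin numeric(3) world position of node (0,0,0) (default 0,0,0).
#' @return a [VolumeGrid-class].
#' @examples
#' volumeGrid(0:7, dims = c(2, 2, 2))
#' @export
volumeGrid <- function(data, dims = NULL, spacing = c(1, 1, 1),
                       origin = c(0, 0, 0)) {
  if (is.null(dim(data))) {
    if (is.null(dims))
      stop("'dims' is required when 'data' is a vector")
    dims <- as.integer(dims)
    if (length(data) != prod(dims))
      stop(sprintf("volume size mismatch: expected %d values for %s, found %d",
                   prod(dims), paste(dims, collapse = "x"), length(data)))
    data <- array(as.double(data), dim = dims)
  }
  new("VolumeGrid", data = data, spacing = as.double(spacing),
      origin = as.double(origin))
}

#' Read an ASCII volume file
#'
#' The on-disk format is whitespace-separated numbers, optionally preceded by
#' a one-line header \code{"nx ny nz sx sy sz"}. When the header is absent,
#' \code{dims} (and optionally \code{spacing}) must be supplied. Values are
#' stored with \strong{x varying fastest, then y, then z}: the value at file
#' position \code{i + nx*(j + ny*k)} (0-based) becomes lattice node
#' \code{(i, j, k)}.
#'
#' @param path file to read.
#' @param dims integer(3) grid dimensions; overrides nothing when a header is
#'   present.
#' @param spacing numeric(3) voxel spacing; default from header or 1,1,1.
#' @param origin numeric(3) world origin (not stored in the file).
#' @return a [VolumeGrid-class].
#' @seealso [writeAsciiVolume()]
#' @export
readAsciiVolume <- function(path, dims = NULL, spacing = NULL,
                            origin = c(0, 0, 0)) {
  if (!file.exists(path))
    stop("volume file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines))
    stop("empty volume file: ", path)
  first <- strsplit(trimws(lines[1]), "[[:space:]]+")[[1]]
  haveHeader <- FALSE
  if (length(first) == 6L) {
    hv <- suppressWarnings(as.numeric(first))
    if (!anyNA(hv) && all(hv[1:3] == round(hv[1:3])) && all(hv[1:3] >= 2) &&
        all(hv[4:6] > 0)) {
      haveHeader <- TRUE
      dims <- as.integer(hv[1:3])
      if (is.null(spacing)) spacing <- hv[4:6]
    }
  }
  if (is.null(dims))
    stop("no header line found and 'dims' not supplied for: ", path)
  if (is.null(spacing)) spacing <- c(1, 1, 1)
  body <- if (haveHeader) lines[-1] else lines
  toks <- strsplit(trimws(body), "[[:space:]]+")
  vals <- suppressWarnings(as.numeric(unlist(toks)))
  if (anyNA(vals)) {
    nPerLine <- lengths(toks)
    bad <- which(vapply(toks, function(t)
      anyNA(suppressWarnings(as.numeric(t))), logical(1)))[1]
    stop(sprintf("non-numeric token on data line %d of %s",
                 bad + haveHeader, path))
  }
  need <- prod(dims)
  if (length(vals) < need)
    stop(sprintf("volume format error in %s: expected %d values for %s, found %d",
                 path, need, paste(dims, collapse = "x"), length(vals)))
  volumeGrid(vals[seq_len(need)], dims = dims, spacing = spacing,
             origin = origin)
}

#' Write an ASCII volume file
#'
#' Writes the header line \code{"nx ny nz sx sy sz"} (unless
#' \code{header = FALSE}) followed by the intensities with x varying fastest,
#' then y, then z, one z-slice row group per line batch. Round-trips through
#' [readAsciiVolume()] bit-identically for values representable at 17
#' significant digits.
#'
#' @param grid a [VolumeGrid-class].
#' @param path output file.
#' @param header write the dimension/spacing header line.
#' @return \code{path}, invisibly.
#' @export
writeAsciiVolume <- function(grid, path, header = TRUE) {
  stopifnot(is(grid, "VolumeGrid"))
  d <- dim(grid@data)
  con <- file(path, "w")
  on.exit(close(con))
  if (header)
    writeLines(paste(c(d, sprintf("%.17g", grid@spacing)), collapse = " "),
               con)
  # x fastest, then y, then z == R array storage order
  vals <- sprintf("%.17g", as.vector(grid@data))
  writeLines(vapply(split(vals, (seq_along(vals) - 1L) %/% d[1]),
                    paste, "", collapse = " "), con)
  invisible(path)
}

#' Wrap a volume or function as a ScalarField
#'
#' Builds the continuous implicit field \eqn{F(q) = value(q) - p_c} whose
#' zero set is the isosurface at intensity \code{isovalue}. Grid sources are
#' evaluated by tri-linear interpolation in world coordinates (index
#' coordinates scaled by spacing, shifted by origin). Function sources must
#' accept an n-by-3 matrix and return n values; their isovalue defaults to 0
#' so the function's own zero set is the surface.
#'
#' @param source a [VolumeGrid-class] or a vectorized function.
#' @param isovalue the constant \eqn{p_c}.
#' @param lower,upper numeric(3) domain bounds; required for function
#'   sources, derived from the grid otherwise.
#' @return a [GridField-class] or [AnalyticField-class].
#' @export
scalarField <- function(source, isovalue = 0, lower = NULL, upper = NULL) {
  if (is(source, "VolumeGrid")) {
    d <- dim(source@data)
    lo <- source@origin
    up <- source@origin + (d - 1) * source@spacing
    new("GridField", grid = source, isovalue = as.double(isovalue),
        lower = lo, upper = up)
  } else if (is.function(source)) {
    if (is.null(lower) || is.null(upper))
      stop("'lower' and 'upper' bounds are required for a function source")
    new("AnalyticField", fun = source, isovalue = as.double(isovalue),
        lower = as.double(lower), upper = as.double(upper))
  } else stop("'source' must be a VolumeGrid or a function")
}

# tri-linear interpolation, vectorized over points given in index coordinates
.trilinearIdx <- function(arr, idx) {
  d <- dim(arr)
  # half-open cells; a point exactly on the top face belongs to the last cell
  i0 <- pmin(floor(idx[, 1]), d[1] - 2); fx <- idx[, 1] - i0
  j0 <- pmin(floor(idx[, 2]), d[2] - 2); fy <- idx[, 2] - j0
  k0 <- pmin(floor(idx[, 3]), d[3] - 2); fz <- idx[, 3] - k0
  at <- function(di, dj, dk)
    arr[cbind(i0 + di + 1, j0 + dj + 1, k0 + dk + 1)]
  # full 8-corner form
  at(0,0,0) * (1-fx)*(1-fy)*(1-fz) + at(1,0,0) * fx*(1-fy)*(1-fz) +
  at(0,1,0) * (1-fx)*fy*(1-fz)     + at(0,0,1) * (1-fx)*(1-fy)*fz +
  at(1,1,0) * fx*fy*(1-fz)         + at(1,0,1) * fx*(1-fy)*fz +
  at(0,1,1) * (1-fx)*fy*fz         + at(1,1,1) * fx*fy*fz
}

#' @rdname fieldValue
#' @export
setMethod("fieldValue", "GridField", function(field, pts,
                                              outside = c("error", "na")) {
  outside <- match.arg(outside)
  pts <- .asPoints(pts)
  ok <- .inBounds(field, pts)
  if (!all(ok) && outside == "error")
    stop("point outside field domain: row ", which(!ok)[1])
  g <- field@grid
  idx <- sweep(sweep(pts, 2, g@origin, "-"), 2, g@spacing, "/")
  out <- rep(NA_real_, nrow(pts))
  if (any(ok))
    out[ok] <- .trilinearIdx(g@data, idx[ok, , drop = FALSE]) - field@isovalue
  out
})

#' @rdname fieldValue
#' @export
setMethod("fieldValue", "AnalyticField", function(field, pts,
                                                  outside = c("error", "na")) {
  outside <- match.arg(outside)
  pts <- .asPoints(pts)
  ok <- .inBounds(field, pts)
  if (!all(ok) && outside == "error")
    stop("point outside field domain: row ", which(!ok)[1])
  out <- rep(NA_real_, nrow(pts))
  if (any(ok))
    out[ok] <- field@fun(pts[ok, , drop = FALSE]) - field@isovalue
  out
})

# default finite-difference step: half a voxel per axis (world units)
.defaultStep <- function(field) {
  if (is(field, "GridField")) 0.5 * field@grid@spacing
  else 0.5 * (field@upper - field@lower) / 64
}

#' Central-difference gradient of a field
#'
#' Component i is \eqn{(F(q + h e_i) - F(q - h e_i)) / (2h)}. Exact for
#' fields linear in each coordinate and second-order accurate otherwise.
#' Where the stencil would leave the domain the component falls back to a
#' one-sided two-point difference; affected rows are flagged in the
#' \code{"onesided"} attribute (an n-by-3 logical matrix).
#'
#' @param field a [ScalarField-class].
#' @param pts n-by-3 matrix of world-space query points (or numeric(3)).
#' @param h step size: scalar or per-axis numeric(3), world units. Default
#'   half a voxel in each axis's own spacing.
#' @return n-by-3 matrix of gradient components with attribute
#'   \code{"onesided"}.
#' @export
fieldGradient <- function(field, pts, h = NULL) {
  pts <- .asPoints(pts)
  h <- rep(h %||% .defaultStep(field), length.out = 3L)
  n <- nrow(pts)
  out <- matrix(0, n, 3)
  flag <- matrix(FALSE, n, 3)
  lo <- field@lower; up <- field@upper
  f0 <- NULL
  for (ax in 1:3) {
    hp <- pts; hp[, ax] <- hp[, ax] + h[ax]
    hm <- pts; hm[, ax] <- hm[, ax] - h[ax]
    okp <- hp[, ax] <= up[ax]
    okm <- hm[, ax] >= lo[ax]
    if (any(!okp & !okm))
      stop("finite-difference step too large for the domain on axis ", ax)
    central <- okp & okm
    vp <- fieldValue(field, hp, outside = "na")
    vm <- fieldValue(field, hm, outside = "na")
    d <- (vp - vm) / (2 * h[ax])
    if (any(!central)) {
      if (is.null(f0)) f0 <- fieldValue(field, pts)
      i <- which(!okp)   # backward difference
      d[i] <- (f0[i] - vm[i]) / h[ax]
      i <- which(!okm)   # forward difference
      d[i] <- (vp[i] - f0[i]) / h[ax]
      flag[!central, ax] <- TRUE
    }
    out[, ax] <- d
  }
  attr(out, "onesided") <- flag
  out
}

#' Central-difference Hessian of a field
#'
#' Standard central second differences on the diagonal and four-point cross
#' stencils off the diagonal; the result is symmetric by construction and
#' exact (to round-off) for quadratic fields. Near the domain boundary the
#' affected terms switch to one-sided 3-point second differences (diagonal)
#' or one-sided-in-one-axis cross stencils, and the rows are flagged in the
#' \code{"onesided"} attribute.
#'
#' @inheritParams fieldGradient
#' @return n-by-6 matrix with columns \code{xx, yy, zz, xy, xz, yz} and
#'   attribute \code{"onesided"} (logical(n)). Use [hessianMatrix()] to
#'   expand row i to a symmetric 3-by-3 matrix.
#' @export
fieldHessian <- function(field, pts, h = NULL) {
  pts <- .asPoints(pts)
  h <- rep(h %||% .defaultStep(field), length.out = 3L)
  n <- nrow(pts)
  lo <- field@lower; up <- field@upper
  out <- matrix(0, n, 6)
  colnames(out) <- c("xx", "yy", "zz", "xy", "xz", "yz")
  flag <- logical(n)

  # per-axis admissible offsets: central (-h, 0, +h) or shifted one-sided
  offs <- vector("list", 3L)
  for (ax in 1:3) {
    okp <- pts[, ax] + h[ax] <= up[ax]
    okm <- pts[, ax] - h[ax] >= lo[ax]
    if (any(!okp & !okm))
      stop("finite-difference stencil does not fit the domain on axis ", ax)
    sh <- numeric(n)                  # stencil center shift
    sh[!okp] <- -h[ax]                # backward: points -2h, -h, 0
    sh[!okm] <- +h[ax]                # forward:  points 0, +h, +2h
    flag <- flag | (sh != 0)
    offs[[ax]] <- sh
  }

  sh <- do.call(cbind, offs)
  for (ax in 1:3) {
    s <- sh[, ax]
    # three stencil points at center + s + {-h, 0, +h} on axis ax
    step <- function(m) {
      q <- pts
      q[, ax] <- q[, ax] + s + m * h[ax]
      fieldValue(field, q)
    }
    out[, ax] <- (step(-1) - 2 * step(0) + step(1)) / h[ax]^2
  }
  pair <- rbind(c(1, 2), c(1, 3), c(2, 3))
  for (pidx in 1:3) {
    a <- pair[pidx, 1]; b <- pair[pidx, 2]
    sa <- sh[, a]; sb <- sh[, b]
    step2 <- function(ma, mb) {
      q <- pts
      q[, a] <- q[, a] + sa + ma * h[a]
      q[, b] <- q[, b] + sb + mb * h[b]
      fieldValue(field, q)
    }
    out[, 3 + pidx] <- (step2(1, 1) - step2(1, -1) - step2(-1, 1) +
                        step2(-1, -1)) / (4 * h[a] * h[b])
  }
  attr(out, "onesided") <- flag
  out
}

#' Expand one Hessian row to a symmetric 3-by-3 matrix
#'
#' @param hrow numeric(6) in the column order of [fieldHessian()].
#' @return symmetric 3-by-3 matrix.
#' @export
hessianMatrix <- function(hrow) {
  matrix(c(hrow[1], hrow[4], hrow[5],
           hrow[4], hrow[2], hrow[6],
           hrow[5], hrow[6], hrow[3]), 3, 3)
}
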