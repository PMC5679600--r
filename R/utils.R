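# internal helpers shared across modules

.asPoints <- function(pts) {
  if (is.null(dim(pts))) {
    stopifnot(length(pts) == 3L)
    pts <- matrix(pts, nrow = 1L)
  }
  if (ncol(pts) != 3L)
    stop("points must be given as an n-by-3 matrix")
  storage.mode(pts) <- "double"
  pts
}

# pinned float formatting: 9 significant digits, plain notation where possible
.fmtNum <- function(x) sprintf("%.9g", x)

.rowNorm <- function(m) sqrt(rowSums(m * m))

`%||%` <- function(a, b) if (is.null(a)) b else a

# world bounds of a field
.fieldLower <- function(field) field@lower
.fieldUpper <- function(field) field@upper

.inBounds <- function(field, pts) {
  pts <- .asPoints(pts)
  lo <- field@lower; up <- field@upper
  pts[, 1] >= lo[1] & pts[, 1] <= up[1] &
  pts[, 2] >= lo[2] & pts[, 2] <= up[2] &
  pts[, 3] >= lo[3] & pts[, 3] <= up[3]
}
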