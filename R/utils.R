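# Small vectorized 3D geometry helpers shared across the package.
# All coordinates are in millimetres.

#' Row-wise cross product of two n x 3 matrices
#' @param a,b numeric matrices with 3 columns (or length-3 vectors)
#' @return n x 3 matrix of cross products
#' @keywords internal
row_cross <- function(a, b) {
  a <- rbind3(a); b <- rbind3(b)
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

#' Row-wise Euclidean norm
#' @keywords internal
row_norm <- function(a) {
  a <- rbind3(a)
  sqrt(rowSums(a * a))
}

#' Row-wise dot product
#' @keywords internal
row_dot <- function(a, b) rowSums(rbind3(a) * rbind3(b))

# coerce a length-3 vector to a 1 x 3 matrix, pass matrices through
rbind3 <- function(x) {
  if (is.matrix(x)) x else matrix(x, ncol = 3L)
}

#' Normalize rows to unit length
#' @keywords internal
row_unit <- function(a, tol = 1e-300) {
  a <- rbind3(a)
  n <- row_norm(a)
  a / pmax(n, tol)
}

# stable %||%
`%||%` <- function(x, y) if (is.null(x)) y else x

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
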