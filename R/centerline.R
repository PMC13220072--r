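#' Vessel centerline
#'
#' Ordered polyline of 3D points (mm) with cumulative arc length and unit
#' tangents (central differences in the interior, one-sided at the ends).
#'
#' @param points numeric matrix, k x 3, ordered centerline points in mm
#' @return object of class `centerline` with `points`, `s` (arc length, mm)
#'   and `tangent` (k x 3 unit vectors)
#' @examples
#' cl <- centerline(cbind(0, 0, seq(0, 30, length.out = 61)))
#' max(cl$s)  # 30
#' @export
centerline <- function(points) {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  if (ncol(points) != 3L) stopf("centerline points must have 3 columns")
  k <- nrow(points)
  if (k < 2L) stopf("centerline needs at least 2 points, got %d", k)
  seg <- row_norm(points[-1L, , drop = FALSE] - points[-k, , drop = FALSE])
  if (any(seg < 1e-12)) stopf("duplicated consecutive centerline points")
  s <- c(0, cumsum(seg))
  tng <- matrix(0, k, 3L)
  tng[1L, ] <- points[2L, ] - points[1L, ]
  tng[k, ] <- points[k, ] - points[k - 1L, ]
  if (k > 2L) tng[2:(k - 1L), ] <- points[3:k, , drop = FALSE] - points[1:(k - 2L), , drop = FALSE]
  structure(list(points = points, s = s, tangent = row_unit(tng)),
            class = "centerline")
}

#' @export
print.centerline <- function(x, ...) {
  cat(sprintf("<centerline> %d points, arc length %.3f mm\n",
              nrow(x$points), max(x$s)))
  invisible(x)
}

#' Read a centerline from CSV
#'
#' Expects columns `x`, `y`, `z` (mm); headerless 3-column files are accepted.
#'
#' @param path CSV file path
#' @return a [centerline]
#' @export
read_centerline <- function(path) {
  if (!file.exists(path)) stopf("centerline file not found: %s", path)
  first <- readLines(path, n = 1L)
  has_header <- grepl("[A-Za-z]", first)
  df <- utils::read.csv(path, header = has_header)
  if (has_header) {
    cols <- tolower(names(df))
    idx <- match(c("x", "y", "z"), cols)
    if (anyNA(idx)) stopf("centerline CSV must have x,y,z columns")
    df <- df[, idx]
  } else if (ncol(df) < 3L) {
    stopf("centerline CSV must have 3 coordinate columns")
  } else df <- df[, 1:3]
  centerline(as.matrix(df))
}

#' Write a centerline to CSV (x,y,z in mm)
#' @param cl a [centerline]
#' @param path output file
#' @export
write_centerline <- function(cl, path) {
  df <- data.frame(x = cl$points[, 1L], y = cl$points[, 2L], z = cl$points[, 3L])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Radial decomposition of points about a centerline
#'
#' For each query point: the nearest centerline sample, the arc-length station,
#' and the radial offset orthogonalized against the local tangent. The radial
#' direction is the outward unit vector from the axis through the point; `r`
#' is the radial distance (mm) so the local lumen diameter is `2 * r`.
#'
#' @param P numeric matrix, n x 3 query points (mm)
#' @param cl a [centerline]
#' @return list with `idx` (nearest sample), `s` (station, mm), `r` (radial
#'   distance, mm), `dir` (n x 3 outward unit radial vectors)
#' @export
radial_decomp <- function(P, cl) {
  P <- rbind3(P)
  C <- cl$points
  # nearest centerline sample via squared-distance matrix (BLAS-friendly)
  d2 <- outer(rowSums(P * P), rowSums(C * C), "+") - 2 * tcrossprod(P, C)
  idx <- max.col(-d2, ties.method = "first")
  near <- C[idx, , drop = FALSE]
  tng <- cl$tangent[idx, , drop = FALSE]
  v <- P - near
  v <- v - tng * row_dot(v, tng)           # remove axial component
  r <- row_norm(v)
  if (any(r < 1e-12))
    stopf("point lies on the centerline axis: radial direction undefined (vertex %d)",
          which(r < 1e-12)[1L])
  list(idx = idx, s = cl$s[idx], r = r, dir = v / r)
}
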