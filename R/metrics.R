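#' Interpolate a centerline at arc-length stations
#'
#' @param cl a [centerline]
#' @param s arc-length positions (mm) within `[0, max(cl$s)]`
#' @return list with `points` (k x 3) and `tangent` (k x 3, unit)
#' @export
centerline_at <- function(cl, s) {
  if (any(s < -1e-9 | s > max(cl$s) + 1e-9))
    stopf("station outside centerline extent [0, %.3f] mm", max(cl$s))
  s <- pmin(pmax(s, 0), max(cl$s))
  px <- stats::approx(cl$s, cl$points[, 1L], xout = s)$y
  py <- stats::approx(cl$s, cl$points[, 2L], xout = s)$y
  pz <- stats::approx(cl$s, cl$points[, 3L], xout = s)$y
  tx <- stats::approx(cl$s, cl$tangent[, 1L], xout = s)$y
  ty <- stats::approx(cl$s, cl$tangent[, 2L], xout = s)$y
  tz <- stats::approx(cl$s, cl$tangent[, 3L], xout = s)$y
  list(points = cbind(px, py, pz), tangent = row_unit(cbind(tx, ty, tz)))
}

# Intersect a triangulation with the plane through p0 with normal tng.
# Returns a list of closed loops, each an ordered matrix of 3D points.
slice_loops <- function(mesh, p0, tng) {
  v <- mesh$vertices; f <- mesh$faces
  d <- as.vector((v - matrix(p0, nrow(v), 3L, byrow = TRUE)) %*% tng)
  eps <- 1e-9 * max(1, max(abs(d)))
  d[d == 0] <- eps                                  # nudge exact hits off the plane
  s1 <- d[f[, 1L]]; s2 <- d[f[, 2L]]; s3 <- d[f[, 3L]]
  cross12 <- s1 * s2 < 0; cross23 <- s2 * s3 < 0; cross31 <- s3 * s1 < 0
  hit <- which(cross12 + cross23 + cross31 == 2L)
  if (!length(hit)) return(list())

  nv <- nrow(v)
  ekey <- function(i, j) pmin(i, j) * (nv + 1) + pmax(i, j)
  ipoint <- function(i, j) {
    t <- d[i] / (d[i] - d[j])
    v[i, , drop = FALSE] + t * (v[j, , drop = FALSE] - v[i, , drop = FALSE])
  }
  seg_a <- seg_b <- numeric(length(hit))
  pt_a <- pt_b <- matrix(0, length(hit), 3L)
  for (q in seq_along(hit)) {
    fc <- f[hit[q], ]
    ends <- list()
    if (cross12[hit[q]]) ends[[length(ends) + 1L]] <- c(fc[1L], fc[2L])
    if (cross23[hit[q]]) ends[[length(ends) + 1L]] <- c(fc[2L], fc[3L])
    if (cross31[hit[q]]) ends[[length(ends) + 1L]] <- c(fc[3L], fc[1L])
    seg_a[q] <- ekey(ends[[1L]][1L], ends[[1L]][2L])
    seg_b[q] <- ekey(ends[[2L]][1L], ends[[2L]][2L])
    pt_a[q, ] <- ipoint(ends[[1L]][1L], ends[[1L]][2L])
    pt_b[q, ] <- ipoint(ends[[2L]][1L], ends[[2L]][2L])
  }
  # chain segments into loops: nodes are cut edges, segments join two nodes
  keys <- unique(c(seg_a, seg_b))
  node_pt <- rbind(pt_a, pt_b)[match(keys, c(seg_a, seg_b)), , drop = FALSE]
  ia <- match(seg_a, keys); ib <- match(seg_b, keys)
  adj <- vector("list", length(keys))
  for (q in seq_along(ia)) {
    adj[[ia[q]]] <- c(adj[[ia[q]]], ib[q])
    adj[[ib[q]]] <- c(adj[[ib[q]]], ia[q])
  }
  visited <- rep(FALSE, length(keys))
  loops <- list()
  for (start in seq_along(keys)) {
    if (visited[start] || length(adj[[start]]) != 2L) next
    path <- integer(0)
    cur <- start; prev <- 0L
    closed <- FALSE
    repeat {
      visited[cur] <- TRUE
      path <- c(path, cur)
      nxt <- setdiff(adj[[cur]], prev)[1L]
      if (is.na(nxt) || length(adj[[cur]]) < 2L) break
      if (nxt == start) { closed <- TRUE; break }
      prev <- cur; cur <- nxt
    }
    if (closed && length(path) >= 3L)
      loops[[length(loops) + 1L]] <- node_pt[path, , drop = FALSE]
  }
  loops
}

# planar polygon area of an ordered 3D loop lying in the plane with normal tng
loop_area <- function(loop, tng) {
  u <- c(1, 0, 0)
  if (abs(sum(u * tng)) > 0.9) u <- c(0, 1, 0)
  u <- u - tng * sum(u * tng); u <- u / sqrt(sum(u^2))
  w <- c(tng[2] * u[3] - tng[3] * u[2],
         tng[3] * u[1] - tng[1] * u[3],
         tng[1] * u[2] - tng[2] * u[1])
  x <- loop %*% u; y <- loop %*% w
  n <- length(x)
  j <- c(2:n, 1L)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

#' Frame-wise mean lumen diameter profile
#'
#' At each arc-length station the surface is sliced by the plane normal to
#' the local centerline tangent; the mean lumen diameter (MLD) is the
#' area-equivalent diameter `2 * sqrt(A / pi)` of the enclosed lumen polygon.
#' When a slice produces several closed loops (e.g. side branches) the loop
#' whose centroid is nearest the centerline point is used. Stations whose
#' slice yields no closed loop are skipped with a warning. Stations are
#' placed at `spacing/2, 3*spacing/2, ...` so end planes of open tubes are
#' never sliced exactly on the boundary.
#'
#' @param mesh a [trimesh] (triangulate simplex meshes with
#'   [simplex_to_tri()] first)
#' @param cl a [centerline]
#' @param spacing frame spacing (mm), default 0.5
#' @param stations optional explicit arc-length stations (mm), overriding
#'   `spacing`
#' @return data.frame of class `mld_profile` with columns `s` (mm) and
#'   `mld` (mm)
#' @export
mld_profile <- function(mesh, cl, spacing = 0.5, stations = NULL) {
  if (is.null(stations)) {
    if (spacing <= 0) stopf("mld_profile: spacing must be > 0")
    stations <- seq(spacing / 2, max(cl$s) - spacing / 4, by = spacing)
  }
  at <- centerline_at(cl, stations)
  mld <- rep(NA_real_, length(stations))
  for (k in seq_along(stations)) {
    loops <- slice_loops(mesh, at$points[k, ], at$tangent[k, ])
    if (!length(loops)) next
    if (length(loops) > 1L) {
      cen <- t(vapply(loops, colMeans, numeric(3)))
      d2 <- rowSums((cen - matrix(at$points[k, ], nrow(cen), 3L, byrow = TRUE))^2)
      loops <- loops[which.min(d2)]
    }
    mld[k] <- 2 * sqrt(loop_area(loops[[1L]], at$tangent[k, ]) / pi)
  }
  if (anyNA(mld)) {
    warnf("mld_profile: %d station(s) produced no closed lumen polygon; skipped", sum(is.na(mld)))
    stations <- stations[!is.na(mld)]
    mld <- mld[!is.na(mld)]
  }
  structure(data.frame(s = stations, mld = mld),
            class = c("mld_profile", "data.frame"))
}

#' Lumen diameters at explicit cross-section stations
#'
#' @param mesh a [trimesh]
#' @param cl a [centerline]
#' @param stations arc-length positions (mm); must lie within the centerline
#'   extent
#' @return numeric vector of area-equivalent diameters (mm), one per station
#' @export
cross_section_diameters <- function(mesh, cl, stations) {
  if (!length(stations)) return(numeric(0))
  prof <- mld_profile(mesh, cl, stations = stations)
  prof$mld[match(stations, prof$s)]
}

#' Bland-Altman agreement between two paired series
#'
#' @param s,r numeric vectors of equal length >= 2 (e.g. predicted and
#'   reference MLD series, mm)
#' @param loa_mult limits-of-agreement multiplier (1.96 for 95% LoA)
#' @return list with `bias` = mean(s - r), `loa_low`, `loa_high`
#'   (bias -/+ loa_mult * sample SD of the differences)
#' @export
bland_altman <- function(s, r, loa_mult = 1.96) {
  if (length(s) != length(r)) stopf("bland_altman: length mismatch (%d vs %d)", length(s), length(r))
  if (length(s) < 2L) stopf("bland_altman: need at least 2 pairs")
  d <- s - r
  bias <- mean(d)
  sd_d <- stats::sd(d)
  list(bias = bias, loa_low = bias - loa_mult * sd_d, loa_high = bias + loa_mult * sd_d)
}

#' Error statistics between two paired series
#'
#' `max|e| = max_i |s_i - r_i|`, `RMSE = sqrt(mean((s_i - r_i)^2))`,
#' `MARE = 100 * mean(|s_i - r_i| / |r_i|)` (percent).
#'
#' @param s,r numeric vectors of equal length; `r` must be nonzero everywhere
#'   for MARE
#' @return list with `max_abs`, `rmse` (same units as inputs), `mare` (%)
#' @export
error_stats <- function(s, r) {
  if (length(s) != length(r)) stopf("error_stats: length mismatch (%d vs %d)", length(s), length(r))
  if (any(r == 0)) stopf("error_stats: reference contains zeros; MARE undefined")
  e <- s - r
  list(max_abs = max(abs(e)),
       rmse = sqrt(mean(e^2)),
       mare = 100 * mean(abs(e / r)))
}

#' Combined lumen-agreement report
#'
#' Bland-Altman bias and limits of agreement plus the error statistics for
#' two paired MLD series.
#'
#' @param s predicted series (mm); `r` reference series (mm)
#' @param r reference series (mm)
#' @return list of class `agreement_report`: `bias`, `loa_low`, `loa_high`,
#'   `max_abs_error`, `rmse` (mm), `mare` (%)
#' @export
agreement_report <- function(s, r) {
  ba <- bland_altman(s, r)
  es <- error_stats(s, r)
  structure(list(bias = ba$bias, loa_low = ba$loa_low, loa_high = ba$loa_high,
                 max_abs_error = es$max_abs, rmse = es$rmse, mare = es$mare),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf(paste0("<agreement_report>\n  bias %.4f mm, 95%% LoA [%.4f, %.4f] mm\n",
                     "  max|e| %.4f mm, RMSE %.4f mm, MARE %.2f%%\n"),
              x$bias, x$loa_low, x$loa_high, x$max_abs_error, x$rmse, x$mare))
  invisible(x)
}
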