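#' Synthetic vessel tube specification
#'
#' Parameterizes the synthetic fixtures that stand in for patient geometries:
#' straight, curved and stenotic open-ended tubes with exact centerlines and
#' analytic ground-truth diameter profiles.
#'
#' @param length tube length along the centerline (mm)
#' @param diameter base lumen diameter (mm)
#' @param n_axial,n_circ discretization counts (>= 2 axial, >= 3 circumferential)
#' @param stenosis_severity fractional diameter reduction in [0, 1)
#' @param stenosis_center arc-length position of the stenosis (mm; default mid-tube)
#' @param stenosis_width Gaussian width of the stenosis (mm)
#' @param curvature_radius sweep radius (mm); `Inf` for a straight tube
#' @param jitter vertex jitter amplitude (mm), 0 by default (robustness testing only)
#' @param seed integer seed controlling the optional jitter
#' @return object of class `tube_spec`
#' @export
tube_spec <- function(length = 30, diameter = 3, n_axial = 40, n_circ = 32,
                      stenosis_severity = 0, stenosis_center = length / 2,
                      stenosis_width = 3, curvature_radius = Inf,
                      jitter = 0, seed = 1L) {
  if (n_circ < 3L || n_axial < 2L)
    stopf("tube_spec: need n_circ >= 3 and n_axial >= 2")
  if (stenosis_severity < 0 || stenosis_severity >= 1)
    stopf("tube_spec: stenosis_severity must lie in [0, 1)")
  if (length <= 0 || diameter <= 0) stopf("tube_spec: length and diameter must be > 0")
  structure(list(length = length, diameter = diameter,
                 n_axial = as.integer(n_axial), n_circ = as.integer(n_circ),
                 stenosis_severity = stenosis_severity,
                 stenosis_center = stenosis_center,
                 stenosis_width = stenosis_width,
                 curvature_radius = curvature_radius,
                 jitter = jitter, seed = as.integer(seed)),
            class = "tube_spec")
}

# grid faces of an open tube: axial rows x circumferential columns,
# wrapped circumferentially, outward-oriented for CCW theta and +axis rows
tube_faces <- function(n_axial, n_circ) {
  idx <- function(i, j) (i - 1L) * n_circ + ((j - 1L) %% n_circ) + 1L
  faces <- matrix(0L, 2L * (n_axial - 1L) * n_circ, 3L)
  k <- 0L
  for (i in seq_len(n_axial - 1L)) for (j in seq_len(n_circ)) {
    a <- idx(i, j); b <- idx(i, j + 1L); cc <- idx(i + 1L, j + 1L); d <- idx(i + 1L, j)
    faces[k + 1L, ] <- c(a, b, cc)
    faces[k + 2L, ] <- c(a, cc, d)
    k <- k + 2L
  }
  faces
}

# analytic radius profile (mm) at arc-length s
tube_radius_at <- function(spec, s) {
  r <- rep(spec$diameter / 2, length(s))
  if (spec$stenosis_severity > 0)
    r <- r * (1 - spec$stenosis_severity *
                exp(-(s - spec$stenosis_center)^2 / (2 * spec$stenosis_width^2)))
  r
}

make_tube_impl <- function(spec) {
  na <- spec$n_axial; nc <- spec$n_circ
  s_ax <- seq(0, spec$length, length.out = na)
  theta <- seq(0, 2 * pi, length.out = nc + 1L)[-(nc + 1L)]
  rad <- tube_radius_at(spec, s_ax)

  verts <- matrix(0, na * nc, 3L)
  for (i in seq_len(na)) {
    rows <- ((i - 1L) * nc + 1L):(i * nc)
    verts[rows, ] <- cbind(rad[i] * cos(theta), rad[i] * sin(theta), s_ax[i])
  }

  if (spec$jitter > 0) {
    set.seed(spec$seed)
    verts <- verts + matrix(stats::runif(length(verts), -spec$jitter, spec$jitter),
                            ncol = 3L)
  }
  n_cl <- max(2L, ceiling(spec$length / 0.25) + 1L)
  cl_s <- seq(0, spec$length, length.out = n_cl)
  cl <- centerline(cbind(0, 0, cl_s))
  truth <- data.frame(s = cl_s, diameter = 2 * tube_radius_at(spec, cl_s))
  list(mesh = trimesh(verts, tube_faces(na, nc)), centerline = cl, truth = truth)
}

#' Straight open-ended tube fixture
#'
#' @param spec a [tube_spec] (stenosis and curvature fields ignored/zero)
#' @return list with `mesh` (a [trimesh]), `centerline`, and `truth`
#'   (data.frame `s`, `diameter`: the exact analytic diameter profile)
#' @examples
#' fx <- make_tube(tube_spec(length = 30, diameter = 3))
#' range(fx$truth$diameter)  # 3 3
#' @export
make_tube <- function(spec) {
  spec$stenosis_severity <- 0
  spec$curvature_radius <- Inf
  make_tube_impl(spec)
}

#' Stenotic tube fixture (Gaussian diameter dip)
#'
#' Radius modulated as
#' `r(s) = (D/2) * (1 - severity * exp(-(s - s0)^2 / (2 w^2)))`, giving a
#' smooth parameterized lesion with analytic ground truth.
#'
#' @param spec a [tube_spec] with `stenosis_severity > 0`
#' @return as [make_tube()]
#' @export
make_stenotic_tube <- function(spec) {
  spec$curvature_radius <- Inf
  make_tube_impl(spec)
}

#' Curved tube fixture (circular-arc sweep)
#'
#' The tube is swept along a circular arc of radius `curvature_radius` in the
#' x-z plane; cross-sections remain exact circles in the plane normal to the
#' arc. The centerline follows the arc with the requested arc length.
#'
#' @param spec a [tube_spec] with finite `curvature_radius`
#' @return as [make_tube()]
#' @export
make_curved_tube <- function(spec) {
  if (!is.finite(spec$curvature_radius))
    return(make_tube(spec))
  Rc <- spec$curvature_radius
  if (Rc <= spec$diameter / 2)
    stopf("make_curved_tube: curvature radius %.2f mm would self-intersect the tube", Rc)
  if (Rc <= spec$diameter)
    stopf("make_curved_tube: curvature radius must exceed the tube diameter")
  na <- spec$n_axial; nc <- spec$n_circ
  s_ax <- seq(0, spec$length, length.out = na)
  theta <- seq(0, 2 * pi, length.out = nc + 1L)[-(nc + 1L)]
  rad <- tube_radius_at(spec, s_ax)
  ang <- s_ax / Rc
  # arc center at (0,0,Rc); centerline point at angle a: Rc*(sin a, 0, 1 - cos a)
  # in-plane outward frame vector e1(a) = (sin a, 0, -cos a); e2 = (0,1,0)
  verts <- matrix(0, na * nc, 3L)
  for (i in seq_len(na)) {
    cpt <- c(Rc * sin(ang[i]), 0, Rc * (1 - cos(ang[i])))
    e1 <- c(sin(ang[i]), 0, -cos(ang[i]))
    rows <- ((i - 1L) * nc + 1L):(i * nc)
    verts[rows, ] <- matrix(cpt, nc, 3L, byrow = TRUE) +
      rad[i] * (outer(cos(theta), e1) + outer(sin(theta), c(0, 1, 0)))
  }
  if (spec$jitter > 0) {
    set.seed(spec$seed)
    verts <- verts + matrix(stats::runif(length(verts), -spec$jitter, spec$jitter),
                            ncol = 3L)
  }
  n_cl <- max(2L, ceiling(spec$length / 0.25) + 1L)
  a_cl <- seq(0, spec$length, length.out = n_cl) / Rc
  cl <- centerline(cbind(Rc * sin(a_cl), 0, Rc * (1 - cos(a_cl))))
  truth <- data.frame(s = a_cl * Rc, diameter = 2 * tube_radius_at(spec, a_cl * Rc))
  list(mesh = trimesh(verts, tube_faces(na, nc)), centerline = cl, truth = truth)
}

#' Closed icosahedron triangulation (exact dual-count fixture)
#'
#' Built from the golden-ratio coordinates; faces are recovered by
#' brute-force support-plane enumeration and oriented outward, so the counts
#' (12 vertices, 20 faces, 30 edges) are exact by construction.
#'
#' @param radius circumscribed sphere radius (mm)
#' @return a [trimesh]
#' @export
icosahedron <- function(radius = 1) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(cbind(0, c(1, 1, -1, -1), c(phi, -phi, phi, -phi)),
             cbind(c(1, 1, -1, -1), c(phi, -phi, phi, -phi), 0),
             cbind(c(phi, -phi, phi, -phi), 0, c(1, 1, -1, -1)))
  v <- v / sqrt(1 + phi^2) * radius
  faces <- list()
  combs <- utils::combn(12L, 3L)
  for (k in seq_len(ncol(combs))) {
    tri <- combs[, k]
    nrm <- row_cross(v[tri[2L], ] - v[tri[1L], ], v[tri[3L], ] - v[tri[1L], ])[1L, ]
    d <- as.vector((v[-tri, , drop = FALSE] -
                      matrix(v[tri[1L], ], 9L, 3L, byrow = TRUE)) %*% nrm)
    if (all(d < -1e-9)) {
      faces[[length(faces) + 1L]] <- tri          # outward as listed
    } else if (all(d > 1e-9)) {
      faces[[length(faces) + 1L]] <- tri[c(1L, 3L, 2L)]
    }
  }
  trimesh(v, do.call(rbind, faces))
}

#' Closed torus triangulation (random closed-surface fixture)
#'
#' @param n_u,n_v major/minor discretization counts (>= 3)
#' @param R_major,r_minor torus radii (mm)
#' @return a [trimesh] (closed: no boundary edges)
#' @export
torus_mesh <- function(n_u = 12L, n_v = 8L, R_major = 10, r_minor = 3) {
  if (n_u < 3L || n_v < 3L) stopf("torus_mesh: need n_u, n_v >= 3")
  if (r_minor >= R_major) stopf("torus_mesh: r_minor must be < R_major")
  u <- seq(0, 2 * pi, length.out = n_u + 1L)[-(n_u + 1L)]
  v <- seq(0, 2 * pi, length.out = n_v + 1L)[-(n_v + 1L)]
  verts <- matrix(0, n_u * n_v, 3L)
  for (i in seq_len(n_u)) {
    rows <- ((i - 1L) * n_v + 1L):(i * n_v)
    verts[rows, ] <- cbind((R_major + r_minor * cos(v)) * cos(u[i]),
                           (R_major + r_minor * cos(v)) * sin(u[i]),
                           r_minor * sin(v))
  }
  idx <- function(i, j) ((i - 1L) %% n_u) * n_v + ((j - 1L) %% n_v) + 1L
  faces <- matrix(0L, 2L * n_u * n_v, 3L)
  k <- 0L
  for (i in seq_len(n_u)) for (j in seq_len(n_v)) {
    a <- idx(i, j); b <- idx(i + 1L, j); cc <- idx(i + 1L, j + 1L); d <- idx(i, j + 1L)
    faces[k + 1L, ] <- c(a, b, cc)
    faces[k + 2L, ] <- c(a, cc, d)
    k <- k + 2L
  }
  trimesh(verts, faces)
}
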