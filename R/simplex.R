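#' 2-simplex mesh: the dual of a triangulation
#'
#' A 2-simplex mesh is a polygonal surface in which every free vertex has
#' exactly three neighbors. It is constructed as the dual of a triangulated
#' surface: one simplex vertex per input triangle (placed at the triangle
#' centroid), with two simplex vertices adjacent iff their source triangles
#' share an edge. Vertices whose source triangle touches a boundary edge are
#' flagged `constrained`: they are never displaced and receive no forces,
#' mirroring the fixed-end conditions used for open vessel segments. They
#' keep degree < 3 without padding.
#'
#' Neighbors are stored in the cyclic order of the source triangle's edges
#' (opposite edges (v1,v2), (v2,v3), (v3,v1)), so that the simplex normal of
#' a vertex agrees with its source-triangle orientation.
#'
#' @param tri a [trimesh], an orientable manifold surface, possibly with
#'   boundary (open tube ends). Non-manifold edges are rejected.
#' @return object of class `simplexmesh`: `vertices` (m x 3, mm),
#'   `neighbors` (m x 3 integer, NA where clipped), `constrained` (logical),
#'   `source_face` (integer map back to the originating triangle),
#'   `faces` (list of polygonal faces as dual-vertex cycles, one per
#'   interior vertex of the triangulation)
#' @examples
#' sm <- triangulation_to_simplex(icosahedron())
#' nrow(sm$vertices)      # 20, one per triangle
#' all(rowSums(!is.na(sm$neighbors)) == 3)
#' @export
triangulation_to_simplex <- function(tri) {
  validate_trimesh(tri)
  v <- tri$vertices; f <- tri$faces
  m <- nrow(f); nv <- nrow(v)
  centroids <- (v[f[, 1L], , drop = FALSE] +
                v[f[, 2L], , drop = FALSE] +
                v[f[, 3L], , drop = FALSE]) / 3

  # undirected edge -> owning faces
  und <- edge_table(f)
  key <- edge_key(und, nv)
  fid <- rep.int(seq_len(m), 3L)
  ord <- order(key, fid)
  key_s <- key[ord]; fid_s <- fid[ord]
  first <- !duplicated(key_s)
  # for each edge occurrence, the partner face (NA on boundary)
  partner <- rep(NA_integer_, length(key_s))
  runs <- rle(key_s)$lengths
  stopifnot(all(runs <= 2L))  # guaranteed by validate_trimesh
  two <- which(runs == 2L)
  pos <- cumsum(runs)
  p2 <- pos[two]; p1 <- p2 - 1L
  partner[p1] <- fid_s[p2]; partner[p2] <- fid_s[p1]
  partner_of <- partner[order(ord)]       # back to original (face, edge-slot) order

  neighbors <- matrix(partner_of, nrow = m, ncol = 3L)  # slot k = edge k of face
  boundary_touch <- rowSums(is.na(neighbors)) > 0L

  faces_poly <- dual_faces(f, neighbors, nv)

  structure(list(vertices = centroids,
                 neighbors = neighbors,
                 constrained = boundary_touch,
                 source_face = seq_len(m),
                 faces = faces_poly),
            class = "simplexmesh")
}

#' @export
print.simplexmesh <- function(x, ...) {
  cat(sprintf("<simplexmesh> %d vertices (%d constrained), %d edges, %d faces\n",
              nrow(x$vertices), sum(x$constrained),
              nrow(simplex_edges(x)), length(x$faces)))
  invisible(x)
}

# polygonal faces of the dual mesh: the cycle of triangles around each
# interior vertex of the triangulation, walked through shared edges
dual_faces <- function(f, neighbors, nv) {
  m <- nrow(f)
  inc <- split(rep.int(seq_len(m), 3L), as.vector(f))  # vertex -> incident faces
  out <- vector("list", 0L)
  for (vtx_chr in names(inc)) {
    vtx <- as.integer(vtx_chr)
    fs <- inc[[vtx_chr]]
    if (length(fs) < 3L) next
    # walk: within face cur, the two edges at vtx are the edge slots whose
    # endpoints include vtx; step across the slot not used to arrive
    start <- fs[1L]
    cycle <- integer(0)
    cur <- start; prev <- NA_integer_
    ok <- TRUE
    repeat {
      cycle <- c(cycle, cur)
      tri_v <- f[cur, ]
      slots <- which(tri_v[c(1L, 2L, 3L)] == vtx | tri_v[c(2L, 3L, 1L)] == vtx)
      nbrs <- neighbors[cur, slots]
      nxt <- nbrs[!(nbrs %in% prev)][1L]
      if (is.na(nxt)) { ok <- FALSE; break }   # boundary vertex: open fan
      if (nxt == start) break
      if (length(cycle) > length(fs)) { ok <- FALSE; break }
      prev <- cur; cur <- nxt
    }
    if (ok && length(cycle) == length(fs)) out[[length(out) + 1L]] <- cycle
  }
  out
}

#' Edges of a simplex mesh
#' @param sm a `simplexmesh`
#' @return integer matrix, e x 2, each dual edge once
#' @export
simplex_edges <- function(sm) {
  m <- nrow(sm$vertices)
  i <- rep.int(seq_len(m), 3L)
  j <- as.vector(sm$neighbors)
  keep <- !is.na(j) & i < j
  cbind(i[keep], j[keep])
}

#' Simplex vertex normal (three-neighbor wedge formula)
#'
#' The unit normal at a simplex vertex is the normalized sum of pairwise
#' wedge (cross) products of its three neighbor positions,
#' `N1 x N2 + N2 x N3 + N3 x N1`, which is algebraically identical to the
#' normalized area vector `(N2 - N1) x (N3 - N1)` of the neighbor triangle.
#'
#' @param N1,N2,N3 neighbor positions; length-3 vectors or n x 3 matrices
#' @param tol degeneracy tolerance on the unnormalized norm (mm^2)
#' @return unit normal(s), same shape as input
#' @export
vertex_normal <- function(N1, N2, N3, tol = 1e-12) {
  w <- row_cross(N1, N2) + row_cross(N2, N3) + row_cross(N3, N1)
  n <- row_norm(w)
  if (any(n < tol))
    stopf("degenerate geometry: collinear neighbors at vertex %d (wedge norm %.3e)",
          which(n < tol)[1L], min(n))
  res <- w / n
  if (!is.matrix(N1)) res <- drop(res)
  res
}

#' Circumscribed circle and sphere of a simplex vertex configuration
#'
#' The three neighbors define a circumscribed circle (radius `r`, center `C`
#' in their plane); the vertex plus neighbors define a circumscribed sphere
#' (radius `R`, center `O`). If the four points are (numerically) coplanar
#' the sphere is undefined and `degenerate` is set.
#'
#' @param P vertex position(s), length-3 vector or n x 3 matrix
#' @param N1,N2,N3 neighbor positions, same shape
#' @return list with `r`, `C`, `R`, `O`, `degenerate` (logical)
#' @export
circumscribed_elements <- function(P, N1, N2, N3) {
  P <- rbind3(P); N1 <- rbind3(N1); N2 <- rbind3(N2); N3 <- rbind3(N3)
  a <- N2 - N1; b <- N3 - N1
  u <- row_cross(a, b)
  u2 <- row_dot(u, u)
  if (any(u2 < 1e-24))
    stopf("collinear neighbors: circumcircle undefined (vertex %d)", which(u2 < 1e-24)[1L])
  Cc <- N1 + (row_cross(u, a) * row_dot(b, b) + row_cross(b, u) * row_dot(a, a)) / (2 * u2)
  r <- row_norm(Cc - N1)

  # sphere: 2 (Xj - P) . O = |Xj|^2 - |P|^2 for Xj in {N1, N2, N3}, via Cramer
  m1 <- 2 * (N1 - P); m2 <- 2 * (N2 - P); m3 <- 2 * (N3 - P)
  r1 <- row_dot(N1, N1) - row_dot(P, P)
  r2 <- row_dot(N2, N2) - row_dot(P, P)
  r3 <- row_dot(N3, N3) - row_dot(P, P)
  det <- row_dot(m1, row_cross(m2, m3))
  scale <- row_norm(m1) * row_norm(m2) * row_norm(m3)
  degen <- abs(det) < 1e-12 * pmax(scale, 1e-300)
  det_safe <- ifelse(degen, 1, det)
  O <- (row_cross(m2, m3) * r1 + row_cross(m3, m1) * r2 + row_cross(m1, m2) * r3) / det_safe
  R <- row_norm(O - P)
  O[degen, ] <- NA_real_
  R[degen] <- NA_real_
  list(r = r, C = Cc, R = R, O = O, degenerate = degen)
}

#' Simplex angle of a vertex over its three neighbors
#'
#' A discrete curvature measure: the angle `phi` in `[-pi, pi]` defined by
#' `sin(phi) = (r/R) * sign((N1 - P) . n)` and
#' `cos(phi) = (||C - O||/R) * sign((C - O) . n)`, recovered with the
#' two-argument arctangent. `phi` is 0 for a locally flat configuration,
#' has magnitude pi/2 when the vertex sits at the pole of the circumsphere
#' over the neighbor circle, and negates under mirror reflection.
#'
#' For exactly coplanar-concyclic configurations the circumsphere is
#' undefined; `phi = 0` is returned with attribute `degenerate = TRUE`.
#'
#' @param P vertex position(s); `N1,N2,N3` neighbors (vectors or matrices)
#' @param N1,N2,N3 neighbor positions
#' @param n optional precomputed unit normal(s); computed via
#'   [vertex_normal()] if omitted
#' @return numeric vector of angles (radians) with attribute `degenerate`
#' @export
simplex_angle <- function(P, N1, N2, N3, n = NULL) {
  P <- rbind3(P); N1 <- rbind3(N1); N2 <- rbind3(N2); N3 <- rbind3(N3)
  if (is.null(n)) n <- rbind3(vertex_normal(N1, N2, N3)) else n <- rbind3(n)
  ce <- circumscribed_elements(P, N1, N2, N3)
  degen <- ce$degenerate
  R <- ifelse(degen, 1, ce$R)
  if (any(!degen & R < 1e-12)) stopf("degenerate circumsphere (R ~ 0)")
  sin_phi <- ce$r / R * sign(row_dot(N1 - P, n))
  O <- ce$O
  O[degen, ] <- ce$C[degen, ]   # forces ||C - O|| = 0 on the degenerate branch
  dCO <- ce$C - O
  cos_phi <- row_norm(dCO) / R * sign(row_dot(dCO, n))
  phi <- atan2(sin_phi, cos_phi)
  phi[degen] <- 0
  attr(phi, "degenerate") <- degen
  phi
}

#' Per-vertex simplex geometry
#'
#' Vectorized normals, circumscribed elements and simplex angles for every
#' full-degree vertex of a simplex mesh. Vertices with clipped neighborhoods
#' (degree < 3) get NA rows.
#'
#' @param sm a `simplexmesh`
#' @return list with `normal` (m x 3), `r`, `R`, `phi` (length m)
#' @export
simplex_geometry <- function(sm) {
  m <- nrow(sm$vertices)
  full <- rowSums(!is.na(sm$neighbors)) == 3L
  normal <- matrix(NA_real_, m, 3L)
  r <- R <- phi <- rep(NA_real_, m)
  if (any(full)) {
    P <- sm$vertices[full, , drop = FALSE]
    N1 <- sm$vertices[sm$neighbors[full, 1L], , drop = FALSE]
    N2 <- sm$vertices[sm$neighbors[full, 2L], , drop = FALSE]
    N3 <- sm$vertices[sm$neighbors[full, 3L], , drop = FALSE]
    n <- rbind3(vertex_normal(N1, N2, N3))
    normal[full, ] <- n
    ce <- circumscribed_elements(P, N1, N2, N3)
    r[full] <- ce$r; R[full] <- ce$R
    phi[full] <- simplex_angle(P, N1, N2, N3, n = n)
  }
  list(normal = normal, r = r, R = R, phi = phi)
}

#' Triangulate a simplex (polygonal) mesh
#'
#' Fan-triangulates every closed polygonal face around its centroid,
#' producing a `trimesh` of the same surface (used for slicing, export and
#' lumen metrics of deformed simplex meshes). Open boundary fans are dropped,
#' so tubes keep open ends.
#'
#' @param sm a `simplexmesh`
#' @return a [trimesh]
#' @export
simplex_to_tri <- function(sm) {
  nvert <- nrow(sm$vertices)
  nf <- length(sm$faces)
  if (nf == 0L) stopf("simplex mesh has no closed polygonal faces")
  cents <- t(vapply(sm$faces, function(cyc)
    colMeans(sm$vertices[cyc, , drop = FALSE]), numeric(3)))
  tris <- vector("list", nf)
  for (k in seq_len(nf)) {
    cyc <- sm$faces[[k]]
    nn <- length(cyc)
    tris[[k]] <- cbind(nvert + k, cyc, cyc[c(2:nn, 1L)])
  }
  trimesh(rbind(sm$vertices, cents), do.call(rbind, tris), validate = FALSE)
}
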