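#' Triangulated surface mesh
#'
#' Lightweight container for a triangulated surface: an `n x 3` matrix of
#' vertex coordinates (mm) and an `m x 3` integer matrix of 1-based vertex
#' indices per face. Validation checks index ranges, degenerate faces,
#' manifoldness (no edge used by more than two faces) and orientation
#' consistency (each interior edge traversed once per direction).
#'
#' @param vertices numeric matrix, n x 3, coordinates in mm
#' @param faces integer matrix, m x 3, 1-based vertex indices
#' @param validate logical; run full validation (default TRUE)
#' @return object of class `trimesh` with elements `vertices`, `faces`
#' @examples
#' ico <- icosahedron()
#' nrow(ico$faces)  # 20
#' @export
trimesh <- function(vertices, faces, validate = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stopf("vertices must have 3 columns, got %d", ncol(vertices))
  if (ncol(faces) != 3L) stopf("faces must have 3 columns, got %d", ncol(faces))
  mesh <- structure(list(vertices = vertices, faces = faces), class = "trimesh")
  if (validate) validate_trimesh(mesh)
  mesh
}

#' @export
print.trimesh <- function(x, ...) {
  be <- boundary_edges(x)
  cat(sprintf("<trimesh> %d vertices, %d faces, %d boundary edges\n",
              nrow(x$vertices), nrow(x$faces), nrow(be)))
  invisible(x)
}

# canonical undirected edge key matrix (m*3 x 2, sorted per row)
edge_table <- function(faces) {
  e <- rbind(faces[, c(1L, 2L)], faces[, c(2L, 3L)], faces[, c(3L, 1L)])
  cbind(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
}

edge_key <- function(e, nv) (e[, 1L] - 1) * as.double(nv) + e[, 2L]

#' Validate a triangulated mesh
#'
#' @param mesh a `trimesh`
#' @param area_tol faces with area below this (mm^2) are rejected as degenerate
#' @return the mesh, invisibly; errors describe the offending simplex
#' @export
validate_trimesh <- function(mesh, area_tol = 1e-12) {
  v <- mesh$vertices; f <- mesh$faces
  nv <- nrow(v)
  if (any(f < 1L) || any(f > nv)) stopf("face indices out of range 1..%d", nv)
  if (any(f[, 1L] == f[, 2L] | f[, 2L] == f[, 3L] | f[, 1L] == f[, 3L]))
    stopf("faces with repeated vertex indices present")
  # degenerate faces
  a <- row_cross(v[f[, 2L], , drop = FALSE] - v[f[, 1L], , drop = FALSE],
                 v[f[, 3L], , drop = FALSE] - v[f[, 1L], , drop = FALSE])
  bad <- which(row_norm(a) / 2 < area_tol)
  if (length(bad)) stopf("degenerate (zero-area) face(s): %s", paste(utils::head(bad, 5L), collapse = ", "))
  # manifoldness: each undirected edge in at most 2 faces
  und <- edge_table(f)
  key <- edge_key(und, nv)
  cnt <- table(key)
  over <- names(cnt)[cnt > 2]
  if (length(over)) {
    k <- as.double(over[1L])
    stopf("non-manifold edge (%d, %d) used by %d faces",
          k %/% nv + 1, ((k - 1) %% nv) + 1, max(cnt))
  }
  # orientation: directed interior edges must appear once per direction,
  # i.e. no directed edge repeated
  dir_e <- rbind(f[, c(1L, 2L)], f[, c(2L, 3L)], f[, c(3L, 1L)])
  dkey <- (dir_e[, 1L] - 1) * as.double(nv) + dir_e[, 2L]
  if (anyDuplicated(dkey))
    stopf("inconsistent orientation: a directed edge is traversed twice")
  invisible(mesh)
}

#' Boundary edges of a triangulation
#'
#' Edges used by exactly one face, as a k x 2 matrix of vertex indices.
#' A closed surface returns a 0-row matrix.
#'
#' @param mesh a `trimesh`
#' @return integer matrix, k x 2
#' @export
boundary_edges <- function(mesh) {
  und <- edge_table(mesh$faces)
  key <- edge_key(und, nrow(mesh$vertices))
  tab <- table(key)
  single <- as.double(names(tab)[tab == 1])
  nv <- nrow(mesh$vertices)
  cbind(as.integer(single %/% nv + ifelse(single %% nv == 0, 0, 1)),
        as.integer(ifelse(single %% nv == 0, nv, single %% nv)))
}

#' Faces incident to the boundary
#'
#' Indices of faces that own at least one boundary edge.
#' @param mesh a `trimesh`
#' @return integer vector of face indices
#' @export
boundary_faces <- function(mesh) {
  nv <- nrow(mesh$vertices)
  und <- edge_table(mesh$faces)
  key <- edge_key(und, nv)
  tab <- table(key)
  bkey <- as.double(names(tab)[tab == 1])
  m <- nrow(mesh$faces)
  fid <- rep.int(seq_len(m), 3L)
  sort(unique(fid[key %in% bkey]))
}

#' Re-orient a triangulation so face normals point away from a centerline
#'
#' Orientation is first made globally consistent by flood fill over face
#' adjacency; the whole mesh is then flipped if the majority of face normals
#' point towards the centerline rather than away from it (luminal surface
#' convention: outward = away from the axis).
#'
#' @param mesh a `trimesh`
#' @param centerline a [centerline] object
#' @return a `trimesh` with consistent, outward orientation
#' @export
orient_outward <- function(mesh, centerline) {
  f <- mesh$faces; v <- mesh$vertices
  m <- nrow(f); nv <- nrow(v)
  # face adjacency via shared undirected edges
  und <- edge_table(f)
  key <- edge_key(und, nv)
  fid <- rep.int(seq_len(m), 3L)
  ord <- order(key)
  key_s <- key[ord]; fid_s <- fid[ord]
  same <- which(key_s[-1] == key_s[-length(key_s)])
  adj_a <- fid_s[same]; adj_b <- fid_s[same + 1L]
  nbr <- split(c(adj_b, adj_a), c(adj_a, adj_b))
  flip <- rep(NA, m)
  # directed-edge sets for consistency checks
  dkeys <- function(tri) {
    e <- rbind(tri[c(1L, 2L)], tri[c(2L, 3L)], tri[c(3L, 1L)])
    (e[, 1L] - 1) * as.double(nv) + e[, 2L]
  }
  for (seed in seq_len(m)) {
    if (!is.na(flip[seed])) next
    flip[seed] <- FALSE
    queue <- seed
    while (length(queue)) {
      cur <- queue[[1L]]; queue <- queue[-1L]
      tri_c <- f[cur, ]
      if (flip[cur]) tri_c <- tri_c[c(1L, 3L, 2L)]
      dk_c <- dkeys(tri_c)
      for (nb in nbr[[as.character(cur)]] %||% integer()) {
        tri_n <- f[nb, ]
        consistent_if_unflipped <- !any(dkeys(tri_n) %in% dk_c)
        want <- !consistent_if_unflipped
        if (is.na(flip[nb])) {
          flip[nb] <- want
          queue <- c(queue, nb)
        } else if (flip[nb] != want) {
          stopf("surface is non-orientable near face %d", nb)
        }
      }
    }
  }
  f[flip, ] <- f[flip, c(1L, 3L, 2L), drop = FALSE]
  # outward test: face normal vs radial direction from the centerline
  cen <- (v[f[, 1L], ] + v[f[, 2L], ] + v[f[, 3L], ]) / 3
  nrm <- row_cross(v[f[, 2L], ] - v[f[, 1L], ], v[f[, 3L], ] - v[f[, 1L], ])
  rad <- radial_decomp(cen, centerline)
  if (mean(row_dot(nrm, rad$dir) > 0) < 0.5) f <- f[, c(1L, 3L, 2L)]
  trimesh(v, f, validate = FALSE)
}
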