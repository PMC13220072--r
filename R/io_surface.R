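#' Read a triangulated surface (STL, PLY or OBJ)
#'
#' ASCII variants of the three formats are supported; binary files are
#' rejected with a format error. Units are assumed to be millimetres
#' throughout — no auto-detection.
#'
#' @param path file path; format chosen by extension (.stl, .ply, .obj)
#' @param validate run [validate_trimesh()] on the result (default TRUE)
#' @return a [trimesh]
#' @export
read_surface <- function(path, validate = TRUE) {
  if (!file.exists(path)) stopf("surface file not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  mesh <- switch(ext,
                 stl = read_stl(path),
                 ply = read_ply(path),
                 obj = read_obj(path),
                 stopf("unsupported surface format '.%s' (use STL, PLY or OBJ)", ext))
  if (validate) validate_trimesh(mesh)
  mesh
}

#' Write a triangulated surface (ASCII STL, PLY or OBJ)
#'
#' @param mesh a [trimesh]
#' @param path output path; format chosen by extension
#' @return the path, invisibly
#' @export
write_surface <- function(mesh, path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         stl = write_stl(mesh, path),
         ply = write_ply(mesh, path),
         obj = write_obj(mesh, path),
         stopf("unsupported surface format '.%s' (use STL, PLY or OBJ)", ext))
  invisible(path)
}

read_stl <- function(path) {
  head_raw <- readBin(path, "raw", n = 5L)
  if (!identical(rawToChar(head_raw), "solid"))
    stopf("binary STL is not supported; export ASCII STL: %s", path)
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (length(vl) %% 3L != 0L) stopf("malformed STL: vertex count not a multiple of 3")
  nums <- t(vapply(strsplit(trimws(vl), "\\s+"),
                   function(p) as.numeric(p[2:4]), numeric(3)))
  # merge duplicate coordinates into shared vertices
  key <- apply(format(nums, digits = 15, scientific = TRUE), 1L, paste, collapse = ",")
  uid <- match(key, unique(key))
  verts <- nums[!duplicated(key), , drop = FALSE]
  faces <- matrix(uid, ncol = 3L, byrow = TRUE)
  trimesh(verts, faces, validate = FALSE)
}

write_stl <- function(mesh, path) {
  v <- mesh$vertices; f <- mesh$faces
  nrm <- row_unit(row_cross(v[f[, 2L], ] - v[f[, 1L], ], v[f[, 3L], ] - v[f[, 1L], ]))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("solid surface units=mm", con)
  fmt3 <- function(x) paste(format(x, digits = 9, scientific = TRUE, trim = TRUE), collapse = " ")
  for (k in seq_len(nrow(f))) {
    writeLines(c(paste("facet normal", fmt3(nrm[k, ])),
                 "  outer loop",
                 paste("    vertex", fmt3(v[f[k, 1L], ])),
                 paste("    vertex", fmt3(v[f[k, 2L], ])),
                 paste("    vertex", fmt3(v[f[k, 3L], ])),
                 "  endloop",
                 "endfacet"), con)
  }
  writeLines("endsolid surface", con)
}

read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^v\\s", lines, value = TRUE)
  fl <- grep("^f\\s", lines, value = TRUE)
  if (!length(vl) || !length(fl)) stopf("malformed OBJ: no vertices or faces")
  verts <- t(vapply(strsplit(trimws(vl), "\\s+"),
                    function(p) as.numeric(p[2:4]), numeric(3)))
  fidx <- lapply(strsplit(trimws(fl), "\\s+"), function(p) {
    as.integer(vapply(strsplit(p[-1L], "/"), `[[`, "", 1L))
  })
  if (any(lengths(fidx) != 3L)) stopf("non-triangular OBJ faces are not supported")
  trimesh(verts, do.call(rbind, fidx), validate = FALSE)
}

write_obj <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# triangulated surface, units mm", con)
  writeLines(sprintf("v %.9g %.9g %.9g",
                     mesh$vertices[, 1L], mesh$vertices[, 2L], mesh$vertices[, 3L]), con)
  writeLines(sprintf("f %d %d %d",
                     mesh$faces[, 1L], mesh$faces[, 2L], mesh$faces[, 3L]), con)
}

read_ply <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!identical(trimws(lines[1L]), "ply")) stopf("not a PLY file: %s", path)
  if (!any(grepl("format ascii", lines))) stopf("binary PLY is not supported: %s", path)
  endh <- which(trimws(lines) == "end_header")[1L]
  nv <- as.integer(sub(".*element vertex\\s+", "", grep("element vertex", lines[1:endh], value = TRUE)[1L]))
  nf <- as.integer(sub(".*element face\\s+", "", grep("element face", lines[1:endh], value = TRUE)[1L]))
  body <- lines[(endh + 1L):length(lines)]
  verts <- t(vapply(strsplit(trimws(body[1:nv]), "\\s+"),
                    function(p) as.numeric(p[1:3]), numeric(3)))
  frows <- strsplit(trimws(body[(nv + 1L):(nv + nf)]), "\\s+")
  fidx <- lapply(frows, function(p) as.integer(p[2:(1L + as.integer(p[1L]))]) + 1L)
  if (any(lengths(fidx) != 3L)) stopf("non-triangular PLY faces: triangulate first")
  trimesh(verts, do.call(rbind, fidx), validate = FALSE)
}

write_ply <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0", "comment units mm",
               sprintf("element vertex %d", nrow(mesh$vertices)),
               "property double x", "property double y", "property double z",
               sprintf("element face %d", nrow(mesh$faces)),
               "property list uchar int vertex_indices", "end_header"), con)
  writeLines(sprintf("%.9g %.9g %.9g",
                     mesh$vertices[, 1L], mesh$vertices[, 2L], mesh$vertices[, 3L]), con)
  writeLines(sprintf("3 %d %d %d",
                     mesh$faces[, 1L] - 1L, mesh$faces[, 2L] - 1L, mesh$faces[, 3L] - 1L), con)
}

#' Export a simplex mesh as a polygonal PLY plus JSON adjacency sidecar
#'
#' Writes the polygonal (dual) surface to ASCII PLY and a sidecar JSON file
#' (`<path>.adjacency.json`) with the neighbor triples, constrained flags and
#' source-face map, from which the simplex structure can be rebuilt exactly.
#'
#' @param sm a `simplexmesh`
#' @param path output PLY path
#' @return the path, invisibly
#' @export
write_simplex <- function(sm, path) {
  con <- file(path, "w")
  writeLines(c("ply", "format ascii 1.0", "comment 2-simplex polygonal mesh, units mm",
               sprintf("element vertex %d", nrow(sm$vertices)),
               "property double x", "property double y", "property double z",
               sprintf("element face %d", length(sm$faces)),
               "property list uchar int vertex_indices", "end_header"), con)
  writeLines(sprintf("%.9g %.9g %.9g",
                     sm$vertices[, 1L], sm$vertices[, 2L], sm$vertices[, 3L]), con)
  for (cyc in sm$faces)
    writeLines(paste(c(length(cyc), cyc - 1L), collapse = " "), con)
  close(con)
  nb <- sm$neighbors
  nb[is.na(nb)] <- 0L                      # 0 marks a clipped (boundary) slot
  jsonlite::write_json(
    list(neighbors = unname(as.data.frame(nb)),
         constrained = sm$constrained,
         source_face = sm$source_face),
    paste0(path, ".adjacency.json"), auto_unbox = FALSE, digits = NA)
  invisible(path)
}
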