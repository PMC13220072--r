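# Independent oracles, deliberately written with plain loops / direct algebra
# so they share no code path with the package implementation.

# normalized triangle area vector (N2-N1) x (N3-N1)
oracle_normal <- function(N1, N2, N3) {
  a <- N2 - N1; b <- N3 - N1
  w <- c(a[2] * b[3] - a[3] * b[2],
         a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  w / sqrt(sum(w^2))
}

# undirected edge count of a triangulation by brute-force enumeration
oracle_edge_count <- function(faces) {
  es <- character(0)
  for (k in seq_len(nrow(faces))) {
    f <- faces[k, ]
    for (pr in list(c(1, 2), c(2, 3), c(3, 1))) {
      i <- f[pr[1]]; j <- f[pr[2]]
      es <- c(es, paste(min(i, j), max(i, j)))
    }
  }
  length(unique(es))
}

# triangles incident to a boundary edge, by brute-force edge enumeration
oracle_boundary_faces <- function(faces) {
  keys <- list()
  for (k in seq_len(nrow(faces))) {
    f <- faces[k, ]
    for (pr in list(c(1, 2), c(2, 3), c(3, 1))) {
      key <- paste(min(f[pr[1]], f[pr[2]]), max(f[pr[1]], f[pr[2]]))
      keys[[key]] <- c(keys[[key]], k)
    }
  }
  single <- Filter(function(v) length(v) == 1L, keys)
  sort(unique(unlist(single)))
}

# uniaxial incompressible reduced-polynomial Cauchy stress, explicit sum
oracle_stress <- function(lambda, C) {
  I1 <- lambda^2 + 2 / lambda
  s <- 0
  for (i in 1:6) s <- s + i * C[i] * (I1 - 3)^(i - 1)
  2 * (lambda^2 - 1 / lambda) * s
}

# agreement statistics via plain loops
oracle_bland_altman <- function(s, r) {
  d <- numeric(length(s))
  for (i in seq_along(s)) d[i] <- s[i] - r[i]
  m <- sum(d) / length(d)
  sdd <- sqrt(sum((d - m)^2) / (length(d) - 1))
  list(bias = m, loa_low = m - 1.96 * sdd, loa_high = m + 1.96 * sdd)
}

oracle_error_stats <- function(s, r) {
  mx <- 0; ss <- 0; mare <- 0
  for (i in seq_along(s)) {
    e <- s[i] - r[i]
    mx <- max(mx, abs(e))
    ss <- ss + e^2
    mare <- mare + abs(e / r[i])
  }
  list(max_abs = mx, rmse = sqrt(ss / length(s)), mare = 100 * mare / length(s))
}

# shoelace polygon area from ordered 2D coordinates
oracle_shoelace <- function(x, y) {
  n <- length(x); a <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    a <- a + x[i] * y[j] - x[j] * y[i]
  }
  abs(a) / 2
}

# small shared fixtures ------------------------------------------------------

fixture_tube <- function(...) make_tube(tube_spec(...))

# an elliptical open tube (semi-axes a, b) along z, used as an MLD oracle case
elliptic_tube <- function(a = 2, b = 1, length = 10, n_axial = 12, n_circ = 48) {
  theta <- seq(0, 2 * pi, length.out = n_circ + 1L)[-(n_circ + 1L)]
  z <- seq(0, length, length.out = n_axial)
  verts <- do.call(rbind, lapply(z, function(zz)
    cbind(a * cos(theta), b * sin(theta), zz)))
  idx <- function(i, j) (i - 1L) * n_circ + ((j - 1L) %% n_circ) + 1L
  faces <- do.call(rbind, lapply(seq_len(n_axial - 1L), function(i)
    do.call(rbind, lapply(seq_len(n_circ), function(j)
      rbind(c(idx(i, j), idx(i, j + 1L), idx(i + 1L, j + 1L)),
            c(idx(i, j), idx(i + 1L, j + 1L), idx(i + 1L, j)))))))
  list(mesh = trimesh(verts, faces),
       centerline = centerline(cbind(0, 0, seq(0, length, length.out = 41))))
}
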