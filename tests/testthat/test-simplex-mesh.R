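test_that("dual construction gives the dual-polyhedron counts on the icosahedron", {
  sm <- triangulation_to_simplex(icosahedron())
  expect_identical(nrow(sm$vertices), 20L)
  expect_true(all(rowSums(!is.na(sm$neighbors)) == 3L))
  expect_identical(nrow(simplex_edges(sm)), 30L)
  expect_identical(length(sm$faces), 12L)
  expect_false(any(sm$constrained))
  # round trip: source_face is the identity on the originating triangles
  expect_identical(sm$source_face, seq_len(20L))
})

test_that("every vertex of a closed-surface dual has exactly three distinct neighbors", {
  set.seed(11)
  for (k in 1:5) {
    tm <- torus_mesh(sample(4:12, 1), sample(4:9, 1), 10, 3)
    sm <- triangulation_to_simplex(tm)
    expect_true(all(rowSums(!is.na(sm$neighbors)) == 3L))
    expect_true(all(apply(sm$neighbors, 1, function(r) length(unique(r)) == 3L)))
    # adjacency is symmetric: i in neighbors of each of its neighbors
    for (i in sample(nrow(sm$vertices), 5)) {
      for (j in sm$neighbors[i, ]) expect_true(i %in% sm$neighbors[j, ])
    }
  }
})

test_that("boundary-adjacent dual vertices are constrained, per enumeration oracle", {
  fx <- fixture_tube(length = 20, diameter = 3, n_axial = 10, n_circ = 16)
  sm <- triangulation_to_simplex(fx$mesh)
  expect_identical(which(sm$constrained), oracle_boundary_faces(fx$mesh$faces))
  # constrained vertices keep degree < 3 without padding
  expect_true(all(rowSums(is.na(sm$neighbors[sm$constrained, ])) > 0L))
  expect_true(all(rowSums(is.na(sm$neighbors[!sm$constrained, ])) == 0L))
})

test_that("non-manifold input is rejected with the offending edge reported", {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(0, -1, 0))
  f <- rbind(c(1, 2, 3), c(1, 2, 4), c(2, 1, 5))  # edge (1,2) in three faces
  expect_error(triangulation_to_simplex(trimesh(v, f, validate = FALSE)),
               "non-manifold edge \\(1, 2\\)")
})

test_that("wedge-sum normal equals the normalized area vector (algebraic identity)", {
  expect_equal(vertex_normal(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
               c(1, 1, 1) / sqrt(3), tolerance = 1e-15)
  set.seed(21)
  for (k in 1:1000) {
    N <- matrix(rnorm(9), 3)
    expect_equal(vertex_normal(N[1, ], N[2, ], N[3, ]),
                 oracle_normal(N[1, ], N[2, ], N[3, ]), tolerance = 1e-12)
  }
})

test_that("collinear neighbors raise a degeneracy error naming the vertex", {
  expect_error(vertex_normal(c(0, 0, 0), c(1, 1, 1), c(2, 2, 2)),
               "collinear neighbors at vertex 1")
})

test_that("circumscribed elements solve the circle and sphere", {
  # neighbors on the unit circle in z = 0, vertex at the pole
  th <- c(0, 2 * pi / 3, 4 * pi / 3)
  ce <- circumscribed_elements(c(0, 0, 1),
                               c(cos(th[1]), sin(th[1]), 0),
                               c(cos(th[2]), sin(th[2]), 0),
                               c(cos(th[3]), sin(th[3]), 0))
  expect_equal(ce$r, 1, tolerance = 1e-12)
  expect_equal(drop(ce$C), c(0, 0, 0), tolerance = 1e-12)
  expect_equal(ce$R, 1, tolerance = 1e-12)
  expect_equal(drop(ce$O), c(0, 0, 0), tolerance = 1e-12)

  # equilateral neighbors with side s: circumradius s/sqrt(3)
  s <- 2.7
  pts <- s / sqrt(3) * cbind(cos(th), sin(th), 0)
  ce2 <- circumscribed_elements(c(0.3, -0.2, 1.1), pts[1, ], pts[2, ], pts[3, ])
  expect_equal(ce2$r, s / sqrt(3), tolerance = 1e-12)

  # random quadruples: |O - X| constant over all four points
  set.seed(31)
  for (k in 1:200) {
    P <- rnorm(3); N1 <- rnorm(3); N2 <- rnorm(3); N3 <- rnorm(3)
    ce3 <- circumscribed_elements(P, N1, N2, N3)
    if (ce3$degenerate) next
    for (X in list(P, N1, N2, N3))
      expect_equal(sqrt(sum((drop(ce3$O) - X)^2)), ce3$R, tolerance = 1e-9)
  }
})

test_that("simplex angle satisfies its trigonometric identity and sign conventions", {
  th <- c(0, 2 * pi / 3, 4 * pi / 3)
  Ns <- lapply(th, function(t) c(cos(t), sin(t), 0))
  phi_pole <- simplex_angle(c(0, 0, 1), Ns[[1]], Ns[[2]], Ns[[3]])
  expect_equal(abs(as.numeric(phi_pole)), pi / 2, tolerance = 1e-12)

  set.seed(41)
  P <- matrix(rnorm(3000), ncol = 3); N1 <- matrix(rnorm(3000), ncol = 3)
  N2 <- matrix(rnorm(3000), ncol = 3); N3 <- matrix(rnorm(3000), ncol = 3)
  phi <- simplex_angle(P, N1, N2, N3)
  expect_true(all(abs(phi) <= pi + 1e-12))
  expect_equal(max(abs(sin(phi)^2 + cos(phi)^2 - 1)), 0, tolerance = 1e-10)

  # mirror reflection: the recomputed wedge normal flips under reflection, so
  # the printed sign rules send (sin, cos) -> (-sin, -cos); the pole case
  # (cos = 0) therefore negates exactly
  refl <- function(X) X * matrix(c(1, 1, -1), nrow(X), 3, byrow = TRUE)
  phi_m <- simplex_angle(refl(P), refl(N1), refl(N2), refl(N3))
  expect_equal(as.numeric(phi_m), as.numeric(atan2(-sin(phi), -cos(phi))), tolerance = 1e-9)
  pole_m <- simplex_angle(c(0, 0, -1), Ns[[1]], Ns[[2]], Ns[[3]])
  expect_equal(as.numeric(pole_m), -as.numeric(phi_pole), tolerance = 1e-12)
  ang <- 0.83
  Rz <- rbind(c(cos(ang), -sin(ang), 0), c(sin(ang), cos(ang), 0), c(0, 0, 1))
  shift <- matrix(c(2, -1, 5), nrow(P), 3, byrow = TRUE)
  phi_r <- simplex_angle(P %*% t(Rz) + shift, N1 %*% t(Rz) + shift,
                         N2 %*% t(Rz) + shift, N3 %*% t(Rz) + shift)
  expect_equal(as.numeric(phi_r), as.numeric(phi), tolerance = 1e-9)
})

test_that("coplanar-concyclic configurations report phi = 0 with a degeneracy flag", {
  # vertex on the same circle as its neighbors: infinite circumsphere
  th <- c(0, 0.8, 1.9, 4.0)
  pts <- cbind(cos(th), sin(th), 0)
  phi <- simplex_angle(pts[4, ], pts[1, ], pts[2, ], pts[3, ])
  expect_identical(as.numeric(phi), 0)
  expect_true(attr(phi, "degenerate"))
})

test_that("per-vertex simplex geometry is consistent and r <= R", {
  fx <- fixture_tube(length = 20, diameter = 3, n_axial = 12, n_circ = 16)
  sm <- triangulation_to_simplex(orient_outward(fx$mesh, fx$centerline))
  g <- simplex_geometry(sm)
  full <- rowSums(!is.na(sm$neighbors)) == 3L
  expect_true(all(abs(rowSums(g$normal[full, ]^2) - 1) < 1e-10))
  expect_true(all(g$r[full] <= g$R[full] + 1e-9))
  # an outward-oriented tube has outward dual normals
  rd <- radial_decomp(sm$vertices[full, ], fx$centerline)
  expect_true(all(rowSums(g$normal[full, ] * rd$dir) > 0))
})
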