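test_that("MLD of analytic tubes matches the truth profile", {
  fx <- fixture_tube(length = 30, diameter = 3, n_axial = 30, n_circ = 32)
  prof <- mld_profile(fx$mesh, fx$centerline, 1)
  expect_true(all(abs(prof$mld - 3) < 0.01 * 3))  # polygonal discretization
  # 50% stenosis: minimum MLD 1.5 mm at the throat
  fs <- make_stenotic_tube(tube_spec(length = 30, diameter = 3, n_axial = 60,
                                     n_circ = 32, stenosis_severity = 0.5))
  ps <- mld_profile(fs$mesh, fs$centerline, 0.5)
  expect_equal(min(ps$mld), 1.5, tolerance = 0.02)
  expect_equal(ps$s[which.min(ps$mld)], 15, tolerance = 0.5)
})

test_that("elliptical lumen gives the area-equivalent diameter 2*sqrt(ab)", {
  et <- elliptic_tube(a = 2, b = 1)
  prof <- mld_profile(et$mesh, et$centerline, 2)
  expect_true(all(abs(prof$mld - 2 * sqrt(2)) < 0.01 * 2 * sqrt(2)))
  # against the shoelace-area oracle on the analytic inscribed polygon
  th <- seq(0, 2 * pi, length.out = 49)[-49]
  a_poly <- oracle_shoelace(2 * cos(th), sin(th))
  expect_equal(mean(prof$mld), 2 * sqrt(a_poly / pi), tolerance = 1e-3)
})

test_that("MLD is invariant under rigid transformation of mesh + centerline", {
  fx <- fixture_tube(length = 20, diameter = 3, n_axial = 16, n_circ = 24)
  p0 <- mld_profile(fx$mesh, fx$centerline, 2)
  ang <- 0.62
  R <- rbind(c(cos(ang), 0, sin(ang)), c(0, 1, 0), c(-sin(ang), 0, cos(ang)))
  shift <- c(5, -3, 2)
  mesh2 <- trimesh(fx$mesh$vertices %*% t(R) +
                     matrix(shift, nrow(fx$mesh$vertices), 3, byrow = TRUE),
                   fx$mesh$faces, validate = FALSE)
  cl2 <- centerline(fx$centerline$points %*% t(R) +
                      matrix(shift, nrow(fx$centerline$points), 3, byrow = TRUE))
  p1 <- mld_profile(mesh2, cl2, 2)
  expect_equal(p1$mld, p0$mld, tolerance = 1e-9)
})

test_that("cross-section diameters work at explicit stations", {
  fx <- fixture_tube(length = 30, diameter = 3, n_axial = 30, n_circ = 32)
  d5 <- cross_section_diameters(fx$mesh, fx$centerline, c(5, 10, 15, 20, 25))
  expect_length(d5, 5L)
  expect_true(all(abs(d5 - 3) < 0.03))
  expect_identical(cross_section_diameters(fx$mesh, fx$centerline, numeric(0)),
                   numeric(0))
  expect_error(cross_section_diameters(fx$mesh, fx$centerline, 45), "outside")
  # stenosis center < shoulder
  fs <- make_stenotic_tube(tube_spec(length = 30, diameter = 3, n_axial = 60,
                                     n_circ = 32, stenosis_severity = 0.5))
  dd <- cross_section_diameters(fs$mesh, fs$centerline, c(15, 8))
  expect_lt(dd[1], dd[2])
})

test_that("bland_altman matches its brute-force oracle and conventions", {
  expect_error(bland_altman(1:3, 1:4), "length mismatch")
  same <- bland_altman(c(1, 2, 3), c(1, 2, 3))
  expect_identical(same$bias, 0)
  expect_identical(same$loa_low, 0); expect_identical(same$loa_high, 0)
  shifted <- bland_altman(c(1, 2, 3) + 0.4, c(1, 2, 3))
  expect_equal(shifted$bias, 0.4, tolerance = 1e-12)
  expect_equal(shifted$loa_high - shifted$loa_low, 0, tolerance = 1e-12)
  set.seed(5)
  s <- rnorm(100, 3, 0.2); r <- rnorm(100, 3, 0.2)
  got <- bland_altman(s, r)
  want <- oracle_bland_altman(s, r)
  expect_equal(got$bias, want$bias, tolerance = 1e-12)
  expect_equal(got$loa_low, want$loa_low, tolerance = 1e-12)
  expect_equal(got$loa_high, want$loa_high, tolerance = 1e-12)
  # antisymmetry of the bias
  expect_equal(bland_altman(r, s)$bias, -got$bias, tolerance = 1e-12)
})

test_that("error_stats matches hand computation and its loop oracle", {
  z <- error_stats(c(1, 2), c(1, 2))
  expect_identical(unlist(z), c(max_abs = 0, rmse = 0, mare = 0))
  h <- error_stats(c(2, 2), c(1, 2))
  expect_equal(h$max_abs, 1)
  expect_equal(h$rmse, 1 / sqrt(2), tolerance = 1e-12)
  expect_equal(h$mare, 50, tolerance = 1e-12)
  set.seed(6)
  s <- rnorm(200, 3, 0.3); r <- rnorm(200, 3, 0.3)
  got <- error_stats(s, r); want <- oracle_error_stats(s, r)
  expect_equal(got$max_abs, want$max_abs, tolerance = 1e-12)
  expect_equal(got$rmse, want$rmse, tolerance = 1e-12)
  expect_equal(got$mare, want$mare, tolerance = 1e-12)
  # max|e| and RMSE symmetric under swap; MARE is not
  rev <- error_stats(r, s)
  expect_equal(rev$max_abs, got$max_abs, tolerance = 1e-15)
  expect_equal(rev$rmse, got$rmse, tolerance = 1e-15)
  expect_false(isTRUE(all.equal(rev$mare, got$mare)))
  expect_error(error_stats(c(1, 2), c(0, 2)), "MARE undefined")
})

test_that("agreement_report combines both statistic families coherently", {
  set.seed(7)
  s <- rnorm(50, 3, 0.1); r <- rnorm(50, 3, 0.1)
  rep <- agreement_report(s, r)
  expect_true(rep$loa_low <= rep$bias && rep$bias <= rep$loa_high)
  expect_lte(rep$rmse, rep$max_abs_error)
  expect_true(all(is.finite(unlist(rep))))
})
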