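# reference device: cobalt alloy, E = 233 GPa, nu = 0.35, crimped radius
# 0.5 mm, 9 atm nominal pressure, L = 34 mm, target diameter 2.15 mm
ref_spec <- function(...) stent_spec(34, 2.15, 0.5, 233, 0.35, 9, ...)

test_that("derived device quantities match independent hand evaluation", {
  sp <- ref_spec()
  E <- 233e3                                  # MPa
  I <- pi * 2.15^4 / 64
  k <- 3 * E * I / 34^3
  expect_equal(sp$k_stn, k, tolerance = 1e-12)
  expect_equal(sp$k_stn, 18.65, tolerance = 1e-3)   # ~18.65 N/mm
  P <- 9 * 0.101325
  expect_equal(sp$F_unit, P * 2.15, tolerance = 1e-12)
  expect_equal(sp$F_rf, P * 2.15 * 34, tolerance = 1e-12)
  expect_equal(sp$F_unit, 1.9606, tolerance = 1e-4)
  expect_equal(sp$F_rf, 66.66, tolerance = 1e-4)
  expect_equal(sp$delta, 34 / (2 * pi * 0.08 * k * 0.5), tolerance = 1e-12)
  expect_equal(sp$delta, 7.25, tolerance = 1e-3)
  expect_equal(sp$chi, sp$threshold_T * sp$delta, tolerance = 1e-15)
})

test_that("rigidity and force scalings follow their closed forms", {
  sp <- ref_spec()
  # doubled length: delta grows 16-fold, so chi must be disabled to construct
  sp2 <- stent_spec(68, 2.15, 0.5, 233, 0.35, 9, threshold_T = 0)
  expect_equal(radial_rigidity(sp2), radial_rigidity(sp) / 8, tolerance = 1e-12)
  expect_equal(radial_force(sp2)$F_rf, 2 * radial_force(sp)$F_rf, tolerance = 1e-12)
  sp3 <- stent_spec(34, 2.15, 0.5, 233, 0.35, 9, strut_thickness_mm = 0.16)
  expect_equal(inflection_chi(sp3)$delta, sp$delta / 2, tolerance = 1e-12)
  # T = 0: chi = 0 and the equilibrium diameter is exactly D_stn
  sp4 <- ref_spec(threshold_T = 0)
  expect_identical(sp4$chi, 0)
  expect_identical(sp4$d_equilibrium, 2.15)
  # k_stn -> 0 as D_stn -> 0
  expect_lt(stent_spec(34, 1e-4, 0.5, 233, threshold_T = 0)$k_stn, 1e-15)
  expect_error(stent_spec(-1, 2.15, 0.5, 233), "positive")
  expect_error(ref_spec(threshold_T = 1), "lower threshold_T")
})

test_that("internal force is the linear radial law with the right fixed point", {
  sp <- ref_spec()
  n <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  # equilibrium: zero force
  F0 <- internal_force(rep((1 - sp$chi) * sp$D_stn, 3), n, sp)
  expect_equal(max(abs(F0)), 0, tolerance = 1e-15)
  # fully crimped with chi = 0: magnitude k/F_rf along +n
  sp0 <- ref_spec(threshold_T = 0)
  F1 <- internal_force(rep(0, 3), n, sp0)
  expect_equal(F1, n * (sp0$k_stn / sp0$F_rf), tolerance = 1e-12)
  # linearity: halving the deficit halves the magnitude
  d_eq <- (1 - sp$chi) * sp$D_stn
  Fa <- internal_force(d_eq - 0.8, n[1, , drop = FALSE], sp)
  Fb <- internal_force(d_eq - 0.4, n[1, , drop = FALSE], sp)
  expect_equal(2 * sqrt(sum(Fb^2)), sqrt(sum(Fa^2)), tolerance = 1e-12)
  # constrained vertices receive zero
  Fc <- internal_force(rep(1, 3), n, sp, constrained = c(TRUE, FALSE, FALSE))
  expect_identical(Fc[1, ], c(0, 0, 0))
  expect_gt(sum(abs(Fc[2, ])), 0)
})

test_that("device substitution acts only through the derived quantities", {
  sp <- ref_spec()
  # a different device with identical k_stn, F_rf, chi produces identical forces
  sp_alt <- sp
  sp_alt$E_stn <- 1; sp_alt$L <- 99       # corrupt raw fields, keep derived
  n <- matrix(c(0, 0, 1), 1)
  expect_equal(internal_force(1.3, n, sp_alt), internal_force(1.3, n, sp))
})

test_that("stent mesh generation projects inward to the crimped radius", {
  fx <- fixture_tube(length = 40, diameter = 4, n_axial = 30, n_circ = 16)
  sm <- triangulation_to_simplex(orient_outward(fx$mesh, fx$centerline))
  sp <- stent_spec(34, 2.15, 0.5, 233, 0.35, 9)
  sb <- build_stent_mesh(sm, fx$centerline, sp)
  rd <- radial_decomp(sb$stent$vertices, fx$centerline)
  expect_true(all(abs(rd$r - 0.5) < 1e-9))
  # axial extent inside [s0, s0 + L], L = 34 mm
  expect_true(all(rd$s >= sb$s0 - 1e-9 & rd$s <= sb$s0 + 34 + 1e-9))
  # pairing is injective and nearest-vertex consistent (brute force)
  expect_identical(anyDuplicated(sb$pairing), 0L)
  av <- sm$vertices
  for (k in sample(length(sb$pairing), 10)) {
    d2 <- rowSums((av - matrix(sb$stent$vertices[k, ], nrow(av), 3, byrow = TRUE))^2)
    # the paired artery vertex is the nearest one radially outward of the
    # stent vertex (same dual position, larger radius)
    expect_equal(which.min(d2), sb$pairing[k])
  }
  # connectivity copied: neighbor relations map through the pairing
  nb <- sb$stent$neighbors
  for (k in sample(nrow(nb), 10)) {
    for (j in nb[k, ]) {
      if (is.na(j)) next
      expect_true(sb$pairing[j] %in% sm$neighbors[sb$pairing[k], ])
    }
  }
})

test_that("stent generation errors and warnings fire on bad segments", {
  fx <- fixture_tube(length = 20, diameter = 4, n_axial = 15, n_circ = 12)
  sm <- triangulation_to_simplex(orient_outward(fx$mesh, fx$centerline))
  sp <- stent_spec(34, 2.15, 0.5, 233, 0.35, 9)
  expect_error(build_stent_mesh(sm, fx$centerline, sp), "exceeds centerline")
  # pre-loaded contact warning: crimped radius >= lumen radius
  sp2 <- stent_spec(10, 2.15, 2.5, 233, 0.35, 9)
  expect_warning(build_stent_mesh(sm, fx$centerline, sp2), "pre-loaded")
})
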