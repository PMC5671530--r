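test_that("equivalent pressure stress follows the compression-positive convention", {
  sig <- rbind(c(-2, -2, -2, 0),    # hydrostatic compression a = 2
               c(3, 3, 3, 0),
               c(1, -1, 0, 0.5))
  expect_identical(pressure_stress(sig), c(2, -3, 0))
  pr <- principal_stresses(sig)
  expect_true(all(pr[, 1] >= pr[, 2] & pr[, 2] >= pr[, 3]))
  expect_equal(principal_stresses(rbind(c(1, -1, 0, 0)))[1, ], c(1, 0, -1))
})

test_that("hydrostatic patch test: uniform pressure gives uniform stress state", {
  m <- fix_cylinder()
  P <- 0.016
  sol <- solve_hyperelastic(m, list(body = npwt_materials()$muscle),
                            list(list(edges = cyl_edges(m, c("right", "top")),
                                      p = P)),
                            cyl_fixed(m), nsteps = 4)
  p <- pressure_stress(sol$stress)
  expect_lt(max(abs(p - P)) / P, 0.01)
  dev <- cbind(sol$stress[, 1] + p, sol$stress[, 2] + p,
               sol$stress[, 3] + p, sol$stress[, 4])
  expect_lt(max(abs(dev)) / P, 0.01)
})

test_that("zero load gives zero displacement", {
  m <- fix_cylinder(nr = 4, nz = 5)
  sol <- solve_hyperelastic(m, list(body = npwt_materials()$muscle),
                            list(list(edges = cyl_edges(m, "top"), p = 0)),
                            cyl_fixed(m), nsteps = 1)
  expect_equal(max(abs(sol$u)), 0)
})

test_that("FE uniaxial response matches the incompressible closed form", {
  m <- fix_cylinder(nr = 5, nz = 9)
  mats <- npwt_materials()
  P <- 0.016
  sol <- solve_hyperelastic(m, list(body = mats$muscle),
                            list(list(edges = cyl_edges(m, "top"), p = P)),
                            cyl_fixed(m))
  top <- which(abs(m$nodes[, 2] - 0.02) < 1e-12)
  lam_fe <- 1 + mean(sol$u[top, 2]) / 0.02
  lam_cf <- uniroot(function(l) mr_uniaxial_stress(l, mats$muscle) + P,
                    c(0.5, 1), tol = 1e-12)$root
  expect_equal(lam_fe, lam_cf, tolerance = 1e-4)
  expect_equal(mean(sol$stress[, 2]), -P, tolerance = 1e-6)
})

test_that("small-load response is linear (doubling the suction doubles u)", {
  m <- fix_cylinder(nr = 4, nz = 7)
  mats <- list(body = npwt_materials()$muscle)
  lo <- list(list(edges = cyl_edges(m, "top"), p = mmhg_to_mpa(1)))
  hi <- list(list(edges = cyl_edges(m, "top"), p = mmhg_to_mpa(2)))
  s1 <- solve_hyperelastic(m, mats, lo, cyl_fixed(m), nsteps = 2)
  s2 <- solve_hyperelastic(m, mats, hi, cyl_fixed(m), nsteps = 2)
  expect_equal(max(abs(s2$u)) / max(abs(s1$u)), 2, tolerance = 1e-3)
})

test_that("macro solve converges tightly and deforms most at the wound edge", {
  sol <- fix_macro(125)
  expect_lt(sol$residual, 1e-8)
  mesh <- sol$mesh
  mag <- sqrt(rowSums(sol$u^2))
  musc <- unique(as.vector(mesh$elems[mesh$region == "muscle", ]))
  imax <- musc[which.max(mag[musc])]
  rim <- mesh$geom$wound_rim_node
  d <- sqrt(sum((mesh$nodes[imax, ] - mesh$nodes[rim, ])^2))
  expect_lt(d, 0.015)   # within 1.5 cm of the wound rim
})

test_that("suction sweep gives monotone deformation and contraction", {
  defs <- vapply(c(70, 125, 150), function(s) max_deformation(fix_macro(s)), 0)
  acs <- vapply(c(70, 125, 150), function(s) wound_area_change(fix_macro(s)), 0)
  expect_true(all(diff(defs) > 0))
  expect_true(all(diff(acs) > 0))
})

test_that("max deformation is mesh-converged (< 3% across a refinement level)", {
  d1 <- max_deformation(fix_macro(125))
  fine <- build_limb_geometry(limb_geometry_params(),
                              h_fine = 0.0014, h_coarse = 0.0056)
  d2 <- max_deformation(solve_macro(fine, load = npwt_load_case(125)))
  expect_lt(abs(d2 - d1) / d2, 0.03)
})

test_that("load-case construction and unit conversion are exact", {
  lc <- npwt_load_case(125)
  expect_equal(lc$suction_mpa, 125 * 133.322e-6)
  expect_equal(lc$filler_top_mpa, lc$suction_mpa)
  lc2 <- npwt_load_case(0.016, units = "MPa")
  expect_equal(lc2$suction_mpa, 0.016)
  expect_error(npwt_load_case(-70), "positive")
})
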