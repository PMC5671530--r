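test_that("oxygenated area follows the indicator arithmetic", {
  base <- fix_baseline()
  u <- base
  u$C[] <- 40.32
  expect_equal(oxygenated_area(u), 1)
  u$C[] <- 5
  expect_equal(oxygenated_area(u), 0)
  # radial step profile: oxygenated inside 20 um only
  r <- sqrt(rowSums(u$mesh$nodes^2))
  u$C <- ifelse(r < 20e-6, 40, 0)
  # within one radial ring of the annulus arithmetic
  expect_lt(abs(oxygenated_area(u) - (20^2 - 5.5^2) / (40^2 - 5.5^2)), 0.03)
})

test_that("area_change is the signed relative difference", {
  expect_equal(area_change(0.5, 0.5), 0)
  expect_equal(area_change(0.25, 0.5), -50)
  expect_equal(area_change(0.675, 0.5), 35)
  expect_error(area_change(0.5, 0), "zero")
})

test_that("baseline diffusion obeys the maximum principle and is radially monotone", {
  base <- fix_baseline()
  expect_true(all(base$C >= -1e-12))
  expect_true(all(base$C <= 40.32 + 1e-9))
  rc <- ring_means(base)
  expect_true(all(diff(rc) < 1e-9))
  expect_equal(rc[1], 40.32)
})

test_that("mass change equals the boundary influx at every step", {
  base <- fix_baseline()
  dm <- diff(base$mass)
  expect_lt(max(abs(dm - base$influx * base$dt)) / max(abs(dm)), 1e-3)
})

test_that("baseline agrees with an independent 1D radial finite-volume oracle", {
  base <- fix_baseline()
  orc <- radial_fd_oracle()
  rc <- ring_means(base)
  Cref <- approx(orc$r, orc$C, xout = base$mesh$geom$radii, rule = 2)$y
  expect_lt(sqrt(sum((rc - Cref)^2) / sum(Cref^2)), 0.005)
})

test_that("zero coupling reproduces the baseline bit-for-bit", {
  mesh <- fix_cap_mesh()
  base <- fix_baseline()
  p_any <- seq_len(nrow(mesh$elems)) * 1e-3
  again <- solve_diffusion(mesh, diffusion_params(), p_any)
  expect_identical(base$C, again$C)
  expect_error(solve_diffusion(mesh, diffusion_params(K_P = 1)), "K_P")
})

test_that("steady state with radial p satisfies C = const - (s K_P / D) p", {
  mesh <- fix_cap_mesh()
  dp <- diffusion_params(D_tissue = 2e-5, D_wall = 2e-5, K_P = -0.5,
                         tau_end = 6, dtau = 0.01)
  ctr <- element_centroids(mesh)
  rc <- sqrt(rowSums(ctr^2))
  beta <- 0.05 / 40e-6
  pel <- beta * (rc - 5e-6)
  st <- solve_diffusion(mesh, dp, pel)
  rn <- st$mesh$geom$radii
  Cex <- 40.32 - (dp$solubility * dp$K_P / dp$D_tissue) * beta * (rn - 5e-6)
  got <- ring_means(st)
  # interior rings: exclude the wall band and the outermost ring, where
  # the element-to-node projection of the piecewise-constant p is one-sided
  int <- 4:(length(rn) - 1)
  expect_lt(max(abs(got[int] - Cex[int])) / diff(range(Cex)), 0.01)
})

test_that("coupling direction: at steady state K_P > 0 depletes high-p tissue", {
  # radial p increasing outward; run to (near) steady state
  mesh <- fix_cap_mesh()
  ctr <- element_centroids(mesh)
  rc <- sqrt(rowSums(ctr^2))
  pel <- 0.02 / 40e-6 * (rc - 5e-6)
  stdy <- function(K) solve_diffusion(
    mesh, diffusion_params(K_P = K, tau_end = 6, dtau = 0.01), pel)
  up <- stdy(0.5)
  dn <- stdy(-0.5)
  rup <- ring_means(up); rdn <- ring_means(dn)
  int <- 4:(length(rup) - 1)
  # C decreases outward for K_P > 0, increases for K_P < 0 (sign reversal)
  expect_true(all(diff(rup[int]) < 0))
  expect_true(all(diff(rdn[int]) > 0))
  # the uncoupled steady state is uniform at the wall value (area 1);
  # positive coupling pushes tissue below threshold and shrinks it
  expect_lt(oxygenated_area(up), 1)
  expect_lt(min(up$C), fix_baseline()$params$threshold)
  expect_equal(oxygenated_area(dn), 1)
})

test_that("binary masks agree with the area fractions and are symmetric", {
  base <- fix_baseline()
  u <- base
  u$C[] <- 40
  m <- export_binary_mask(u, n = 256)
  # all-white inside the annulus
  xs <- seq(-40e-6, 40e-6, length.out = 256)
  rr <- sqrt(outer(xs^2, rep(1, 256), "+") * 0 + outer(xs^2, xs^2, "+"))
  inside <- rr >= 5.5e-6 & rr <= 40e-6
  expect_gt(sum(m[inside]) / sum(inside), 0.98)
  # baseline mask: rotationally symmetric, pixel area matches quadrature
  mb <- export_binary_mask(base, n = 1024)
  expect_lt(abs(sum(mb) / sum({
    xs2 <- seq(-40e-6, 40e-6, length.out = 1024)
    rr2 <- sqrt(outer(xs2^2, xs2^2, "+"))
    rr2 >= 5.5e-6 & rr2 <= 40e-6
  }) - oxygenated_area(base)), 0.01)
  expect_lt(mean(mb != t(mb)), 0.01)        # 90-degree rotation symmetry
  expect_lt(mean(mb != mb[nrow(mb):1, ]), 0.01)  # mirror symmetry
  f <- tempfile(fileext = ".png")
  export_binary_mask(base, n = 128, file = f)
  expect_true(file.exists(f))
  unlink(f)
})
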