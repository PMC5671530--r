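test_that("capillary geometry and mesh areas match annulus arithmetic", {
  g <- capillary_geometry()
  expect_error(capillary_geometry(lumen_radius = 45), "below")
  mesh <- fix_cap_mesh()
  ann <- mesh$region %in% c("wall", "tissue")
  a <- element_areas(mesh)
  expect_equal(sum(a[ann]), pi * ((40e-6)^2 - (5e-6)^2), tolerance = 0.01)
  expect_equal(sum(a[mesh$region == "wall"]) / sum(a[ann]),
               (5.5^2 - 5^2) / (40^2 - 5^2), tolerance = 1e-3)
  # wall_thickness -> 0 gives a single-material annulus
  m0 <- build_capillary_mesh(capillary_geometry(wall_thickness = 0))
  expect_false(any(m0$region == "wall"))
})

test_that("zero load gives (numerically) zero pressure stress", {
  sol <- solve_capillary(fix_cap_mesh(), fix_cap_materials(),
                         capillary_load_case(0, 0, 0), nsteps = 1)
  expect_lt(max(abs(sol$p)), 1e-10)
})

test_that("equibiaxial far-field compression recovers the hydrostatic limit", {
  a <- 1e-3  # 1 kPa
  sol <- solve_capillary(fix_cap_mesh(), fix_cap_materials(),
                         capillary_load_case(-a, -a, 0), nsteps = 2)
  ctr <- element_centroids(sol$mesh)
  rc <- sqrt(rowSums(ctr^2))
  far <- sol$mesh$region == "tissue" & rc > 25e-6
  expect_equal(mean(sol$p[far]), a, tolerance = 0.05)
})

test_that("luminal-only loading matches the Lame thick-wall solution", {
  m <- npwt_materials()
  uni <- list(wall = m$tissue, tissue = m$tissue, frame = m$tissue)
  P <- 0.05e-3  # 0.05 kPa
  sol <- solve_capillary(fix_cap_mesh(), uni,
                         capillary_load_case(0, 0, 0.05), nsteps = 2)
  ctr <- element_centroids(sol$mesh)
  rc <- sqrt(rowSums(ctr^2))
  th <- atan2(ctr[, 2], ctr[, 1])
  c2 <- cos(th)^2; s2 <- sin(th)^2; cs <- cos(th) * sin(th)
  srr <- sol$stress[, 1] * c2 + sol$stress[, 2] * s2 + 2 * sol$stress[, 4] * cs
  stt <- sol$stress[, 1] * s2 + sol$stress[, 2] * c2 - 2 * sol$stress[, 4] * cs
  aL <- 5e-6
  sel <- rc > 7e-6 & rc < 20e-6   # clear of hole discretisation and frame
  expect_lt(max(abs(srr[sel] + P * aL^2 / rc[sel]^2)) / P, 0.05)
  expect_lt(max(abs(stt[sel] - P * aL^2 / rc[sel]^2)) / P, 0.05)
})

test_that("solution is invariant under 90-degree rotation with swapped loads", {
  mesh <- fix_cap_mesh()
  cm <- fix_cap_materials()
  s1 <- solve_capillary(mesh, cm, capillary_load_case(-0.005, -0.018, 0.5),
                        nsteps = 4)
  s2 <- solve_capillary(mesh, cm, capillary_load_case(-0.018, -0.005, 0.5),
                        nsteps = 4)
  nt <- mesh$geom$n_theta
  ne <- nrow(mesh$elems)
  jj <- rep(seq_len(nt), times = ne / nt)
  kk <- rep(seq_len(ne / nt), each = nt)
  perm <- (kk - 1) * nt + ((jj - 1 + nt / 4) %% nt) + 1
  expect_lt(max(abs(s1$p - s2$p[perm])) / max(abs(s1$p)), 1e-6)
})

test_that("stress concentrates at the lumen and compression gives positive p", {
  mesh <- fix_cap_mesh()
  sol <- solve_capillary(mesh, fix_cap_materials(),
                         capillary_load_case(-0.005, -0.018, 0.5), nsteps = 4)
  ctr <- element_centroids(mesh)
  rc <- sqrt(rowSums(ctr^2))
  vm <- sqrt(((sol$stress[, 1] - sol$stress[, 2])^2 +
                (sol$stress[, 2] - sol$stress[, 3])^2 +
                (sol$stress[, 3] - sol$stress[, 1])^2) / 2 +
               3 * sol$stress[, 4]^2)
  far <- mesh$region == "tissue" & rc > 25e-6
  expect_gt(max(vm[rc < 6.5e-6]), 2 * mean(vm[far]))
  expect_gt(mean(sol$p[mesh$region == "tissue"]), 0)
  # mixed tension/compression: spatially sign-varying p
  sm <- solve_capillary(mesh, fix_cap_materials(),
                        capillary_load_case(0.01, -0.01, 0.5), nsteps = 4)
  tis <- mesh$region == "tissue"
  expect_gt(max(sm$p[tis]), 0.001)
  expect_lt(min(sm$p[tis]), -0.001)
})
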