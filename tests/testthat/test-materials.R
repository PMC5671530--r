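test_that("Mooney-Rivlin energy and derived constants match hand arithmetic", {
  mats <- npwt_materials()
  expect_equal(mr_energy(3, 3, mats$muscle), 0)
  expect_equal(mr_energy(3.1, 3.05, mats$muscle), 0.00504, tolerance = 1e-12)
  # C2 = 0 reduces to neo-Hookean
  nh <- mooney_rivlin(0.01, 0)
  expect_equal(mr_energy(3.4, 9.99, nh), 0.01 * 0.4, tolerance = 1e-12)
  expect_equal(mats$muscle$mu0, 0.1828, tolerance = 1e-12)
  # volumetric penalty with D > 0
  expect_equal(mr_energy(3, 3, mats$wall, J = 1.1),
               (1 / 1e-6) * 0.1^2, tolerance = 1e-9)
})

test_that("uniaxial closed form agrees with the energy derivative", {
  mats <- npwt_materials()
  expect_equal(mr_uniaxial_stress(1, mats$muscle), 0)
  expect_equal(mr_uniaxial_stress(1.1, mats$muscle),
               2 * (1.21 - 1 / 1.1) * (0.0094 + 0.082 / 1.1),
               tolerance = 1e-10)
  # sigma = lambda dW/dlambda for the incompressible uniaxial path,
  # written independently through the invariant derivatives
  lam <- c(0.7, 0.9, 1.3, 2)
  sig <- 2 * mats$muscle$C1 * (lam^2 - 1 / lam) +
    2 * mats$muscle$C2 * (lam - 1 / lam^2)
  expect_equal(mr_uniaxial_stress(lam, mats$muscle), sig, tolerance = 1e-10)
  expect_error(mr_uniaxial_stress(-1, mats$muscle), "positive")
})

test_that("stress kernels are exact derivatives of their energies", {
  set.seed(1)
  n <- 120
  e <- matrix(stats::rnorm(n * 4, 0, 0.15), n, 4)
  C <- cbind(1 + e[, 1], 1 + e[, 2], 1 + abs(e[, 3]), 0.5 * e[, 4])
  mats <- npwt_materials()
  fd_stress <- function(efun, C) {
    S <- matrix(0, n, 4)
    for (b in 1:4) {
      h <- 1e-6
      Cp <- C; Cm <- C
      Cp[, b] <- Cp[, b] + h; Cm[, b] <- Cm[, b] - h
      g <- (efun(Cp) - efun(Cm)) / (2 * h)
      S[, b] <- if (b == 4) g else 2 * g
    }
    S
  }
  for (mat in list(mats$muscle, mats$wall)) {
    S <- npwtox:::.mr_stress(C, mat)
    Sfd <- fd_stress(function(Cx) npwtox:::.mr_energy_C(Cx, mat), C)
    expect_lt(max(abs(S - Sfd)) / max(abs(S)), 1e-6)
    D <- npwtox:::.mr_tangent(C, mat)
    Dfd <- npwtox:::.num_tangent(function(Cx) npwtox:::.mr_stress(Cx, mat), C)
    expect_lt(max(abs(D - Dfd)) / max(abs(D)), 1e-5)
  }
  mf <- mats$filler
  S <- npwtox:::.foam_stress(C, mf)
  Sfd <- fd_stress(function(Cx) npwtox:::.foam_energy_C(Cx, mf), C)
  expect_lt(max(abs(S - Sfd)) / max(abs(S)), 1e-5)
})

test_that("material constructors validate their inputs", {
  expect_error(mooney_rivlin(-1, 0.1))
  expect_error(mooney_rivlin(0, 0))
  expect_error(hyperfoam(0, 1, 1), "mu")
  expect_error(hyperfoam(1, 0, 1), "alpha")
  m <- mooney_rivlin(0.0094, 0.082, D = 0, bulk_ratio = 1000)
  expect_equal(m$kappa, 1000 * 0.1828)
  w <- mooney_rivlin(0.257, 0.00257, D = 1e-6)
  expect_equal(w$kappa, 2e6)
})
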