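test_that("axial profile is linear with the closed-form slope", {
  ap0 <- axial_transport_params()     # M = 0
  expect_equal(axial_profile(ap0, c(0, 0.3, 1)), rep(120, 3))
  ap <- axial_transport_params(consumption_M = 0.5)
  expect_equal(axial_profile(ap, 0), 120)
  # independent mass balance: oxygen removed per unit length equals
  # M * pi * (Rt^2 - Rc^2); blood flow Q = vbar * pi * Rc^2
  Rc <- 5e-6; Rt <- 40e-6; vbar <- 0.0005 / 2
  drop1mm <- 0.5 * pi * (Rt^2 - Rc^2) * 1e-3 / (vbar * pi * Rc^2)
  expect_equal(axial_profile(ap, 1), 120 - drop1mm, tolerance = 1e-12)
  expect_true(all(diff(axial_profile(ap, seq(0, 1, 0.1))) < 0))
  expect_error(axial_profile(ap, 1.2), "range")
})

test_that("doubling V_max halves the concentration drop", {
  a1 <- axial_transport_params(consumption_M = 0.5)
  a2 <- axial_transport_params(consumption_M = 0.5, V_max = 0.001)
  d1 <- 120 - axial_profile(a1, 0.8)
  d2 <- 120 - axial_profile(a2, 0.8)
  expect_equal(d1 / d2, 2, tolerance = 1e-12)
})

test_that("consumption calibration reproduces the 40.32 uM wall value", {
  ap <- axial_transport_params()
  M <- calibrate_consumption(ap, 40.32)
  # brute-force check of the arithmetic: solve the linear balance directly
  Rc <- 5e-6; Rt <- 40e-6; vbar <- 0.0005 / 2
  M_direct <- (120 - 40.32) * Rc^2 * vbar / ((Rt^2 - Rc^2) * 0.5e-3)
  expect_equal(M, M_direct, tolerance = 1e-12)
  expect_equal(M, 0.632, tolerance = 1e-3)
  apc <- axial_transport_params(consumption_M = M)
  expect_equal(axial_profile(apc, 0.5), 40.32, tolerance = 1e-10)
  expect_equal(calibrate_consumption(ap, 120 - 1e-9), 0, tolerance = 1e-6)
  expect_error(calibrate_consumption(ap, 130), "below")
})
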