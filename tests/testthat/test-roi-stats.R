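test_that("ROI samples are one per element and order-invariant", {
  stress <- rbind(c(1, 0, 0, 0), c(3, 0, 0, 0), c(2, -1, 0.5, 0))
  s <- collect_roi_stresses(stress, c(1, 2))
  expect_equal(sort(s$sigma_max), c(1, 3))
  expect_equal(sort(s$sigma_min), c(0, 0))
  s2 <- collect_roi_stresses(stress, c(2, 1))
  expect_equal(sort(s2$sigma_max), sort(s$sigma_max))
  # uniform field: all samples identical
  su <- collect_roi_stresses(stress[c(1, 1, 1), ], 1:3)
  expect_true(all(su$sigma_max == 1))
  expect_error(collect_roi_stresses(stress, integer()), "empty")
})

test_that("modal stress follows the histogram definition", {
  expect_equal(modal_stress(rep(0.25, 10)), 0.25)
  expect_equal(modal_stress(0.7), 0.7)
  set.seed(3)
  bi <- c(rnorm(700, -0.01, 0.0004), rnorm(300, 0.02, 0.0004))
  # the mode must sit in the heavy cluster; with explicit bins its bin
  # centre brackets the cluster mean to within half a bin width
  expect_lt(abs(modal_stress(bi) - (-0.01)), 0.005)
  bw <- diff(range(bi)) / 60
  expect_lt(abs(modal_stress(bi, bin_rule = 60) - (-0.01)), bw)
  x <- rnorm(200)
  m <- modal_stress(x)
  expect_gte(m, min(x)); expect_lte(m, max(x))
  expect_identical(m, modal_stress(sample(x)))
  # mode lies in the bin of maximal count
  h <- stress_histogram(x)
  ib <- findInterval(h$mode, h$bin_edges, rightmost.closed = TRUE)
  expect_equal(h$counts[ib], max(h$counts))
  expect_equal(sum(h$counts), h$n_samples)
})

test_that("fine-binned mode approaches the densest point of a unimodal sample", {
  set.seed(4)
  x <- rgamma(20000, shape = 4, rate = 20)   # skewed, mode at 3/20
  m <- modal_stress(x, bin_rule = 80)
  d <- density(x)
  peak <- d$x[which.max(d$y)]
  bw <- diff(range(x)) / 80
  expect_lt(abs(m - peak), 2 * bw)
})

test_that("modal pairs per ROI come from the macro principal stresses", {
  sol <- fix_macro(125)
  rois <- define_roi_layers(sol$mesh,
                            list(roi_layer_spec("beneath_wound", 0)))
  md <- roi_modal_stresses(sol, rois)[[1]]
  s <- collect_roi_stresses(sol, rois[[1]])
  expect_gte(md$sigma_max, min(s$sigma_max))
  expect_lte(md$sigma_max, max(s$sigma_max))
  expect_gte(md$sigma_min, min(s$sigma_min))
  expect_lte(md$sigma_min, max(s$sigma_min))
  expect_identical(md$sigma_max, md$hist_max$mode)
})
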