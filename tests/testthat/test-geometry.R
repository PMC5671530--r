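test_that("parameter invariants are enforced", {
  expect_error(limb_geometry_params(bone_radius = 8), "bone_radius")
  expect_error(limb_geometry_params(wound_radius = 7.5), "wound_radius")
  expect_error(limb_geometry_params(wound_depth = 20), "wound_depth")
  expect_error(limb_geometry_params(muscle_radius = -1), "positive")
  expect_error(limb_geometry_params(distal_cap = 0.5), "distal_cap")
})

test_that("wound opening and cavity areas match closed forms", {
  p <- limb_geometry_params()
  expect_equal(wound_opening_area(p), pi * 3.6^2, tolerance = 1e-12)
  expect_equal(wound_opening_area(p), 40.7, tolerance = 1e-2)
  p1 <- limb_geometry_params(wound_radius = 1)
  expect_equal(wound_opening_area(p1), pi, tolerance = 1e-12)
  expect_equal(wound_cavity_wall_area(p),
               pi * 3.6^2 + 2 * pi * 3.6 * 0.8, tolerance = 1e-12)
  expect_equal(wound_cavity_wall_area(p), 58.8, tolerance = 1e-3)
})

test_that("revolved mesh volumes match solids of revolution", {
  mesh <- fix_limb_mesh()
  p <- limb_geometry_params()
  expect_equal(mesh_volume(mesh, "filler") * 1e6, pi * 3.6^2 * 0.8,
               tolerance = 1e-9)
  vtot <- pi * 7^2 * 18 - pi * 1.5^2 * 14   # cylinder minus bone core
  expect_equal(mesh_volume(mesh) * 1e6, vtot, tolerance = 0.01)
  # refinement changes region volumes by < 0.5%
  fine <- build_limb_geometry(p, h_fine = 0.001, h_coarse = 0.004)
  expect_lt(abs(mesh_volume(fine, "filler") - mesh_volume(mesh, "filler")) /
              mesh_volume(mesh, "filler"), 0.005)
  expect_lt(abs(mesh_volume(fine) - mesh_volume(mesh)) / mesh_volume(mesh),
            0.005)
})

test_that("degenerate zero-radius wound yields a solid muscle mesh", {
  m <- build_limb_geometry(limb_geometry_params(wound_radius = 0),
                           h_fine = 0.003, h_coarse = 0.01)
  expect_false(any(m$region == "filler"))
  expect_false(any(m$edges$tag %in%
                     c("wound_lateral", "wound_bottom", "filler_top")))
})

test_that("round and sharp edges give equal volumes within the fillet correction", {
  hs <- c(0.002, 0.008)
  ms <- build_limb_geometry(limb_geometry_params(), hs[1], hs[2])
  mr <- build_limb_geometry(limb_geometry_params(edge_shape = "round"),
                            hs[1], hs[2])
  f <- 0.002
  # revolved area of one corner fillet sliver, at the wound radius
  corr <- 2 * pi * 0.038 * f^2 * (1 - pi / 4)
  dv <- abs(mesh_volume(mr, "filler") - mesh_volume(ms, "filler"))
  expect_lt(dv, 3 * corr)
  expect_false(any(element_areas(mr) <= 0))
})

test_that("ROI layers are non-empty, disjoint and direction-correct", {
  mesh <- fix_limb_mesh()
  specs <- c(lapply(c(0, 10, 15), function(o) roi_layer_spec("beneath_wound", o)),
             lapply(c(0, 5, 10), function(o) roi_layer_spec("beside_wound", o)))
  rois <- define_roi_layers(mesh, specs)
  expect_length(rois, 6)
  expect_true(all(lengths(rois) > 0))
  expect_false(anyDuplicated(unlist(rois[1:3])) > 0)
  expect_false(anyDuplicated(unlist(rois[4:6])) > 0)
  ctr <- element_centroids(mesh)
  zwb <- mesh$geom$z_wb
  # offset-0 layer touches the wound bed plane
  expect_lt(min(zwb - ctr[rois[[1]], 2]), 0.0021)
  expect_true(all(mesh$region[unlist(rois)] == "muscle"))
  # offset beyond the limb errors, naming the spec
  expect_error(define_roi_layers(mesh, roi_layer_spec("beneath_wound", 300)),
               "300")
})

test_that("ROI element sets are invariant under node renumbering", {
  mesh <- fix_limb_mesh()
  set.seed(7)
  perm <- sample(nrow(mesh$nodes))
  inv <- integer(length(perm)); inv[perm] <- seq_along(perm)
  m2 <- mesh
  m2$nodes <- mesh$nodes[perm, ]
  m2$elems[] <- inv[mesh$elems]
  m2$edges$n1 <- inv[m2$edges$n1]
  m2$edges$n2 <- inv[m2$edges$n2]
  m2$geom$wound_rim_node <- inv[mesh$geom$wound_rim_node]
  specs <- lapply(c(0, 10), function(o) roi_layer_spec("beneath_wound", o))
  expect_identical(define_roi_layers(mesh, specs),
                   define_roi_layers(m2, specs))
})
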