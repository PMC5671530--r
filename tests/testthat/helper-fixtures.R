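# Shared, lazily computed fixtures. The limb test mesh is coarser than the
# package default (2 mm at the wound interface, 8 mm far field); the macro
# quantities of interest change by < 1% between this and the next
# refinement level (asserted in test-macro-fe.R).

.fix <- new.env(parent = emptyenv())

fix_limb_mesh <- function() {
  if (is.null(.fix$limb))
    .fix$limb <- build_limb_geometry(limb_geometry_params(),
                                     h_fine = 0.002, h_coarse = 0.008)
  .fix$limb
}

fix_macro <- function(suction) {
  key <- paste0("macro", suction)
  if (is.null(.fix[[key]]))
    .fix[[key]] <- solve_macro(fix_limb_mesh(),
                               load = npwt_load_case(suction))
  .fix[[key]]
}

fix_cap_mesh <- function() {
  if (is.null(.fix$cap))
    .fix$cap <- build_capillary_mesh(capillary_geometry())
  .fix$cap
}

fix_cap_materials <- function() {
  m <- npwt_materials()
  list(wall = m$wall, tissue = m$tissue, frame = m$tissue)
}

fix_baseline <- function() {
  if (is.null(.fix$base))
    .fix$base <- solve_diffusion(fix_cap_mesh(), diffusion_params())
  .fix$base
}

# small axisymmetric cylinder fixture for element verification
fix_cylinder <- function(nr = 6, nz = 9, R = 0.01, H = 0.02) {
  g <- npwtox:::.rect_mesh(seq(0, R, length.out = nr),
                           seq(0, H, length.out = nz))
  g
}

cyl_edges <- function(mesh, tags) {
  e <- mesh$edges
  as.matrix(e[e$tag %in% tags, c("n1", "n2")])
}

cyl_fixed <- function(mesh) {
  c(2L * which(abs(mesh$nodes[, 1]) < 1e-12) - 1L,
    2L * which(abs(mesh$nodes[, 2]) < 1e-12))
}
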