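#' NPWT load case
#'
#' Suction magnitude applied to the wound faces (lateral wall and bottom)
#' and the pressure pushing on the exposed filler top. Loads are stored in
#' MPa using the exact conversion 1 mmHg = 133.322 Pa. In gauge terms the
#' net load on the filler top equals the suction level (atmosphere outside
#' versus the evacuated foam), which is the default.
#'
#' @param suction suction magnitude, positive (mmHg by default).
#' @param filler_top pressure on the filler top (defaults to `suction`).
#' @param units `"mmHg"` (default) or `"MPa"`; `"MPa"` accepts the rounded
#'   literature values (0.0093, 0.016, 0.019) directly.
#' @return object of class `npwt_load_case`.
#' @export
npwt_load_case <- function(suction, filler_top = suction,
                           units = c("mmHg", "MPa")) {
  units <- match.arg(units)
  to_mpa <- if (units == "mmHg") mmhg_to_mpa else identity
  if (suction < 0)
    stop("suction is a magnitude; use positive values")
  structure(list(suction_mpa = to_mpa(suction),
                 filler_top_mpa = to_mpa(filler_top),
                 suction_mmhg = if (units == "mmHg") suction
                                else suction / 133.322e-6),
            class = "npwt_load_case")
}

#' @export
print.npwt_load_case <- function(x, ...) {
  cat(sprintf(
    "<npwt_load_case> suction %.5g MPa (%.4g mmHg), filler top %.5g MPa\n",
    x$suction_mpa, x$suction_mmhg, x$filler_top_mpa))
  invisible(x)
}

# edges of the limb mesh carrying a given tag, as a 2-column matrix
.tag_edges <- function(mesh, tags) {
  e <- mesh$edges[mesh$edges$tag %in% tags, , drop = FALSE]
  as.matrix(e[, c("n1", "n2")])
}

# constrained dofs of the macro model: encastre proximal end, rigid bone
# interface, symmetry axis (radial dof only)
.macro_fixed_dofs <- function(mesh) {
  e <- mesh$edges
  nd <- function(tags) unique(unlist(e[e$tag %in% tags, c("n1", "n2")]))
  clamped <- nd(c("proximal_end", "bone_interface"))
  axis <- nd("symmetry_axis")
  unique(c(2L * clamped - 1L, 2L * clamped, 2L * axis - 1L))
}

#' Macro-scale NPWT solve
#'
#' Nonlinear static solution of the axisymmetric residual limb under NPWT
#' loading: suction (negative pressure) applied as follower tractions on
#' the wound lateral wall and bottom, pressure on the exposed filler top,
#' encastre proximal end, rigid bone interface, tied (node-sharing)
#' muscle--filler interface.
#'
#' @param mesh limb mesh from [build_limb_geometry()].
#' @param materials named region materials (default [npwt_materials()]).
#' @param load an [npwt_load_case()].
#' @param ... passed to [solve_hyperelastic()] (`nsteps`, `tol`, ...).
#' @return object of class `macro_solution`: nodal displacements `u`
#'   (metres), per-element Cauchy `stress` and `principal` stresses (MPa),
#'   equivalent pressure stress `p` (MPa), plus mesh and load.
#' @export
solve_macro <- function(mesh, materials = npwt_materials(),
                        load = npwt_load_case(125), ...) {
  stopifnot(inherits(load, "npwt_load_case"))
  loads <- list()
  suct <- .tag_edges(mesh, c("wound_lateral", "wound_bottom"))
  if (nrow(suct) > 0 && load$suction_mpa != 0)
    loads <- c(loads, list(list(edges = suct, p = -load$suction_mpa)))
  ftop <- .tag_edges(mesh, "filler_top")
  if (nrow(ftop) > 0 && load$filler_top_mpa != 0)
    loads <- c(loads, list(list(edges = ftop, p = load$filler_top_mpa)))
  sol <- solve_hyperelastic(mesh, materials, loads,
                            .macro_fixed_dofs(mesh), ...)
  structure(list(mesh = mesh, load = load, u = sol$u,
                 stress = sol$stress,
                 principal = principal_stresses(sol$stress),
                 p = pressure_stress(sol$stress),
                 residual = sol$residual, iterations = sol$iterations),
            class = "macro_solution")
}

#' @export
print.macro_solution <- function(x, ...) {
  cat(sprintf(
    "<macro_solution> suction %.4g mmHg: max deformation %.3f mm, wound area change %.2f%%\n",
    x$load$suction_mmhg, max_deformation(x), wound_area_change(x)))
  cat(sprintf("  Newton iterations %d, final residual %.2e\n",
              x$iterations, x$residual))
  invisible(x)
}

#' Maximum macro-deformation
#'
#' Maximum displacement magnitude over muscle nodes, in mm. Under NPWT
#' loading the maximum is attained at the wound edge region.
#'
#' @param sol a `macro_solution`.
#' @return length in mm.
#' @export
max_deformation <- function(sol) {
  stopifnot(inherits(sol, "macro_solution"))
  musc <- unique(as.vector(sol$mesh$elems[sol$mesh$region == "muscle", ]))
  1000 * max(sqrt(rowSums(sol$u[musc, , drop = FALSE]^2)))
}

#' Wound cross-sectional area change
#'
#' Relative reduction of the wound opening area,
#' `100 * (A0 - A) / A0`, computed from the deformed radius of the wound
#' rim (the node where the filler surface meets the skin); positive values
#' mean wound contraction.
#'
#' @param sol a `macro_solution`.
#' @return percent change (positive = contraction).
#' @export
wound_area_change <- function(sol) {
  stopifnot(inherits(sol, "macro_solution"))
  rim <- sol$mesh$geom$wound_rim_node
  if (is.na(rim)) stop("mesh has no wound (wound_radius = 0)")
  r0 <- sol$mesh$nodes[rim, 1]
  rd <- r0 + sol$u[rim, 1]
  100 * (1 - (rd / r0)^2)
}
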