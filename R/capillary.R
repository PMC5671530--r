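#' Krogh-cylinder capillary geometry
#'
#' Cross-sectional geometry of a single capillary and its supplied tissue
#' sleeve: lumen of radius 5 um, wall of thickness 0.5 um, tissue annulus
#' out to the 40 um Krogh radius.
#'
#' @param lumen_radius capillary lumen radius.
#' @param wall_thickness capillary wall thickness.
#' @param tissue_outer_radius Krogh cylinder (tissue sleeve) radius.
#' @param units length unit (default `"um"`).
#' @return object of class `capillary_geometry` (lengths in metres).
#' @export
capillary_geometry <- function(lumen_radius = 5, wall_thickness = 0.5,
                               tissue_outer_radius = 40, units = "um") {
  g <- list(lumen_radius = .len_to_m(lumen_radius, units),
            wall_thickness = .len_to_m(wall_thickness, units),
            tissue_outer_radius = .len_to_m(tissue_outer_radius, units))
  if (g$lumen_radius <= 0) stop("lumen_radius must be positive")
  if (g$wall_thickness < 0) stop("wall_thickness must be non-negative")
  if (g$lumen_radius + g$wall_thickness >= g$tissue_outer_radius)
    stop("lumen_radius + wall_thickness must be below tissue_outer_radius")
  structure(g, class = "capillary_geometry")
}

#' @export
print.capillary_geometry <- function(x, ...) {
  cat(sprintf(
    "<capillary_geometry> lumen %.2f um, wall %.2f um, Krogh radius %.1f um\n",
    x$lumen_radius * 1e6, x$wall_thickness * 1e6,
    x$tissue_outer_radius * 1e6))
  invisible(x)
}

#' Build the plane capillary mesh
#'
#' Polar-structured quadrilateral mesh of the capillary cross-section:
#' wall annulus, tissue annulus out to the Krogh radius, and a surrounding
#' tissue frame out to a square of side `frame_factor * tissue_outer_radius`
#' on which the far-field (ROI modal) tractions are applied; loading the
#' frame instead of the annulus rim keeps load-edge artefacts away from
#' the region where oxygen transport is evaluated. The diffusion solve
#' uses only the wall + tissue annulus.
#'
#' Regions: `wall`, `tissue` (annulus), `frame`. Boundary tags:
#' `lumen_surface` and the four square sides `xmin`, `xmax`, `ymin`,
#' `ymax` (the load edges).
#'
#' @param geom a [capillary_geometry()].
#' @param n_theta number of angular divisions.
#' @param nr_wall,nr_tissue,nr_frame radial layers in each band.
#' @param frame_factor square side as a multiple of the Krogh radius.
#' @return an [npwt_mesh()] (plane, metres) with polar indexing metadata
#'   in `$geom` used for interpolation and rasterisation.
#' @export
build_capillary_mesh <- function(geom, n_theta = 48, nr_wall = 2,
                                 nr_tissue = 14, nr_frame = 5,
                                 frame_factor = 2.2) {
  stopifnot(inherits(geom, "capillary_geometry"),
            n_theta >= 8, nr_tissue >= 2, nr_frame >= 1)
  Rl <- geom$lumen_radius
  Rw <- Rl + geom$wall_thickness
  Rt <- geom$tissue_outer_radius
  half <- frame_factor * Rt / 2
  if (half <= Rt) stop("frame_factor too small: square must contain annulus")
  # radial stations: wall uniform, tissue graded (finer near the wall)
  rw <- if (geom$wall_thickness > 0) {
    seq(Rl, Rw, length.out = nr_wall + 1)
  } else Rl
  ht0 <- (Rt - Rw) / nr_tissue / 1.6
  ht1 <- 2 * (Rt - Rw) / nr_tissue - ht0
  rt <- seq_graded(Rw, Rt, ht0, ht1)
  radii <- c(rw, rt[-1])
  k_out <- length(radii)               # ring index of the Krogh radius
  nwall <- length(rw) - 1L
  theta <- 2 * pi * (seq_len(n_theta) - 1) / n_theta
  # frame stations (fraction of the way from the circle to the square)
  tfrac <- seq(0, 1, length.out = nr_frame + 1)[-1]
  rho <- half / pmax(abs(cos(theta)), abs(sin(theta)))
  K <- length(radii) + nr_frame        # total rings
  nodes <- matrix(0, n_theta * K, 2)
  idx <- function(j, k) (k - 1L) * n_theta + ((j - 1L) %% n_theta) + 1L
  for (k in seq_along(radii))
    nodes[idx(seq_len(n_theta), k), ] <-
      cbind(radii[k] * cos(theta), radii[k] * sin(theta))
  for (kf in seq_along(tfrac)) {
    r <- Rt + tfrac[kf] * (rho - Rt)
    nodes[idx(seq_len(n_theta), length(radii) + kf), ] <-
      cbind(r * cos(theta), r * sin(theta))
  }
  j <- rep(seq_len(n_theta), times = K - 1L)
  k <- rep(seq_len(K - 1L), each = n_theta)
  elems <- cbind(idx(j, k), idx(j, k + 1L), idx(j + 1L, k + 1L), idx(j + 1L, k))
  band <- k                             # radial band of each element
  region <- ifelse(band <= nwall, "wall",
                   ifelse(band < k_out, "tissue", "frame"))
  if (nwall == 0) region[region == "wall"] <- "tissue"
  # boundary edges (lumen circle + outer square)
  ed <- .region_boundary_edges(elems)
  mid <- (nodes[ed[, 1], ] + nodes[ed[, 2], ]) / 2
  rmid <- sqrt(rowSums(mid^2))
  tag <- rep(NA_character_, nrow(ed))
  tag[rmid < Rl * 1.5] <- "lumen_surface"
  out <- is.na(tag)
  xside <- abs(mid[, 1]) >= abs(mid[, 2])
  tag[out & xside & mid[, 1] > 0] <- "xmax"
  tag[out & xside & mid[, 1] < 0] <- "xmin"
  tag[out & !xside & mid[, 2] > 0] <- "ymax"
  tag[out & !xside & mid[, 2] < 0] <- "ymin"
  mesh <- npwt_mesh(nodes, elems, region,
                    data.frame(n1 = ed[, 1], n2 = ed[, 2], tag = tag,
                               stringsAsFactors = FALSE),
                    axisymmetric = FALSE)
  mesh$geom <- list(capillary = geom, n_theta = n_theta, radii = radii,
                    k_out = k_out, nwall = nwall, half = half,
                    band = band, idx = idx)
  mesh
}

#' Capillary load case
#'
#' Luminal blood pressure plus the far-field principal stresses taken
#' from the ROI modal values of the macro model (tension positive). The
#' maximum principal stress is applied as a normal traction on the x-face
#' pair of the frame, the minimum on the y-face pair.
#'
#' @param sigma_max,sigma_min far-field principal stresses (MPa).
#' @param luminal_pressure luminal pressure (kPa, default 0.5).
#' @return object of class `capillary_load_case`.
#' @export
capillary_load_case <- function(sigma_max = 0, sigma_min = 0,
                                luminal_pressure = 0.5) {
  stopifnot(is.finite(sigma_max), is.finite(sigma_min),
            is.finite(luminal_pressure))
  structure(list(sigma_max = sigma_max, sigma_min = sigma_min,
                 luminal_mpa = kpa_to_mpa(luminal_pressure)),
            class = "capillary_load_case")
}

#' Plane-strain capillary structural solve
#'
#' Solves the meso-scale capillary model (Mooney-Rivlin wall and tissue)
#' under luminal pressure and far-field tractions, and derives the
#' equivalent pressure stress field that couples into the oxygen
#' diffusion model.
#'
#' @param mesh from [build_capillary_mesh()].
#' @param materials named materials; defaults to [npwt_materials()] with
#'   the tissue entry reused for the frame.
#' @param load a [capillary_load_case()].
#' @param ... passed to [solve_hyperelastic()].
#' @return object of class `capillary_solution` with displacements `u`,
#'   Cauchy `stress`, `principal` stresses and pressure stress `p` per
#'   element (MPa).
#' @export
solve_capillary <- function(mesh, materials = NULL,
                            load = capillary_load_case(), ...) {
  stopifnot(inherits(load, "capillary_load_case"))
  if (is.null(materials)) {
    mm <- npwt_materials()
    materials <- list(wall = mm$wall, tissue = mm$tissue, frame = mm$tissue)
  }
  if (is.null(materials$frame)) materials$frame <- materials$tissue
  loads <- list()
  if (load$luminal_mpa != 0)
    loads <- c(loads, list(list(edges = .tag_edges(mesh, "lumen_surface"),
                                p = load$luminal_mpa)))
  if (load$sigma_max != 0)
    loads <- c(loads, list(list(edges = .tag_edges(mesh, c("xmin", "xmax")),
                                p = -load$sigma_max)))
  if (load$sigma_min != 0)
    loads <- c(loads, list(list(edges = .tag_edges(mesh, c("ymin", "ymax")),
                                p = -load$sigma_min)))
  # pin rigid-body modes at three frame corners-of-symmetry; the load set
  # is self-equilibrated so the reactions vanish
  half <- mesh$geom$half
  pick <- function(x, y) which.min((mesh$nodes[, 1] - x)^2 +
                                     (mesh$nodes[, 2] - y)^2)
  fixed <- c(2L * pick(half, 0), 2L * pick(-half, 0),
             2L * pick(0, half) - 1L)
  sol <- solve_hyperelastic(mesh, materials, loads, fixed, ...)
  structure(list(mesh = mesh, load = load, u = sol$u,
                 stress = sol$stress,
                 principal = principal_stresses(sol$stress),
                 p = pressure_stress(sol$stress),
                 residual = sol$residual, iterations = sol$iterations),
            class = "capillary_solution")
}

#' @export
print.capillary_solution <- function(x, ...) {
  cat(sprintf(
    "<capillary_solution> sigma_max %.4g, sigma_min %.4g MPa, luminal %.4g MPa\n",
    x$load$sigma_max, x$load$sigma_min, x$load$luminal_mpa))
  ann <- x$mesh$region %in% c("wall", "tissue")
  cat(sprintf("  pressure stress over annulus: [%.4g, %.4g] MPa\n",
              min(x$p[ann]), max(x$p[ann])))
  invisible(x)
}
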