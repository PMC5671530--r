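#' Parametric axisymmetric residual-limb geometry
#'
#' Parameter set for the synthetic trans-femoral residual limb: a rigid
#' bone core surrounded by hyperelastic muscle, with a circumferentially
#' symmetric wound cavity of given radius and depth at the distal end,
#' filled by an identically sized polyurethane foam filler. The default
#' wound (radius 3.6 cm, depth 0.8 cm) has an opening area of about
#' 40 cm^2; muscle and bone radii are not part of the published subject
#' description and are exposed here with documented defaults.
#'
#' @param limb_length length of the modelled residual limb segment.
#' @param muscle_radius outer radius of the muscle envelope.
#' @param bone_radius radius of the (rigid) femur core.
#' @param wound_radius radius of the circular wound cavity (0 allowed as a
#'   degenerate no-wound limit).
#' @param wound_depth depth of the wound cavity below the distal surface.
#' @param edge_shape `"sharp"` (right-angled cavity corners) or `"round"`
#'   (cavity corners filleted with `edge_fillet_radius`).
#' @param edge_fillet_radius fillet radius used when `edge_shape = "round"`.
#' @param distal_cap distance from the distal skin surface to the bone tip
#'   (soft-tissue pad covering the resected femur).
#' @param units unit of all lengths above: `"cm"` (default), `"mm"` or `"m"`.
#' @return an object of class `limb_geometry_params` with lengths stored in
#'   metres.
#' @export
limb_geometry_params <- function(limb_length = 18, muscle_radius = 7,
                                 bone_radius = 1.5, wound_radius = 3.6,
                                 wound_depth = 0.8,
                                 edge_shape = c("sharp", "round"),
                                 edge_fillet_radius = 0.2,
                                 distal_cap = 4, units = "cm") {
  edge_shape <- match.arg(edge_shape)
  p <- list(
    limb_length = .len_to_m(limb_length, units),
    muscle_radius = .len_to_m(muscle_radius, units),
    bone_radius = .len_to_m(bone_radius, units),
    wound_radius = .len_to_m(wound_radius, units),
    wound_depth = .len_to_m(wound_depth, units),
    edge_shape = edge_shape,
    edge_fillet_radius = .len_to_m(edge_fillet_radius, units),
    distal_cap = .len_to_m(distal_cap, units))
  with(p, {
    if (limb_length <= 0 || muscle_radius <= 0 || bone_radius <= 0)
      stop("all lengths must be positive")
    if (wound_radius < 0 || wound_depth < 0)
      stop("wound dimensions must be non-negative")
    if (bone_radius >= muscle_radius)
      stop("bone_radius must be smaller than muscle_radius")
    if (wound_radius >= muscle_radius)
      stop("wound_radius must be smaller than muscle_radius")
    if (wound_depth >= limb_length)
      stop("wound_depth must be smaller than limb_length")
    if (distal_cap <= wound_depth)
      stop("distal_cap must exceed wound_depth (wound must stay in muscle)")
    if (distal_cap >= limb_length)
      stop("distal_cap must be smaller than limb_length")
  })
  structure(p, class = "limb_geometry_params")
}

#' @export
print.limb_geometry_params <- function(x, ...) {
  cat(sprintf(paste0(
    "<limb_geometry_params> limb %.1f cm, muscle r %.1f cm, bone r %.1f cm\n",
    "  wound: r %.2f cm, depth %.2f cm, %s edges"),
    x$limb_length * 100, x$muscle_radius * 100, x$bone_radius * 100,
    x$wound_radius * 100, x$wound_depth * 100, x$edge_shape))
  if (x$edge_shape == "round")
    cat(sprintf(" (fillet %.1f mm)", x$edge_fillet_radius * 1000))
  cat("\n")
  invisible(x)
}

#' Wound opening area
#'
#' Cross-sectional (opening) area of the circular wound, `pi * r^2`. With
#' the default radius of 3.6 cm this is 40.7 cm^2, the "approximately
#' 40 cm^2" wound commonly taken as representative of a trans-femoral
#' NPWT dressing.
#'
#' @param params a [limb_geometry_params()].
#' @return area in cm^2.
#' @export
wound_opening_area <- function(params) {
  r <- params$wound_radius * 100
  if (r <= 0) stop("wound_radius must be positive")
  pi * r^2
}

#' Full wound cavity wall area (diagnostic)
#'
#' Bottom plus lateral wall area of the cylindrical cavity,
#' `pi r^2 + 2 pi r d`, in cm^2.
#'
#' @inheritParams wound_opening_area
#' @export
wound_cavity_wall_area <- function(params) {
  r <- params$wound_radius * 100
  d <- params$wound_depth * 100
  if (r <= 0) stop("wound_radius must be positive")
  pi * r^2 + 2 * pi * r * d
}

# internal: radial corner-rounding map. Nodes in the quadrant pointing
# from centre O towards the corner (axis signs s1, s2) with
# max(u1, u2) <= f are rescaled from distance d to max(u1, u2), taking
# the L-inf sphere (the square corner walls) onto the arc of radius f.
.fillet_map <- function(nodes, O, s1, s2, f) {
  u1 <- (nodes[, 1] - O[1]) * s1
  u2 <- (nodes[, 2] - O[2]) * s2
  dn <- pmax(u1, u2)
  sel <- u1 > -1e-12 & u2 > -1e-12 & dn <= f * (1 + 1e-9) & dn > 0
  d <- sqrt(u1[sel]^2 + u2[sel]^2)
  sc <- dn[sel] / d
  nodes[sel, 1] <- O[1] + (nodes[sel, 1] - O[1]) * sc
  nodes[sel, 2] <- O[2] + (nodes[sel, 2] - O[2]) * sc
  nodes
}

# internal: graded target element size at position x, refined towards the
# focus intervals (list of c(lo, hi)), with ramp length `ramp`
.h_graded <- function(x, focus, h_fine, h_coarse, ramp = 0.03) {
  if (length(focus) == 0) return(rep(h_coarse, length(x)))
  d <- do.call(pmin, lapply(focus, function(f)
    pmax(0, pmax(f[1] - x, x - f[2]))))
  pmin(h_coarse, h_fine + (h_coarse - h_fine) * d / ramp)
}

#' Build the axisymmetric limb mesh
#'
#' Generates a conforming, graded quadrilateral mesh of the muscle and the
#' foam filler in the (r, z) meridian plane. The bone core is not meshed
#' (it is rigid; its surface becomes the fixed `bone_interface` boundary).
#' The mesh is refined towards the wound--filler interface.
#'
#' Boundary/interface tags: `proximal_end` (z = 0), `symmetry_axis` (r = 0),
#' `bone_interface`, `outer_skin` (lateral skin and distal skin outside the
#' wound), `wound_lateral` and `wound_bottom` (muscle side of the
#' muscle--filler interface, split by facet normal direction) and
#' `filler_top` (exposed filler surface).
#'
#' @param params a [limb_geometry_params()].
#' @param h_fine target element size (m) near the wound--filler interface.
#' @param h_coarse target element size (m) in the far field.
#' @param jitter relative interior-node jitter (fraction of local spacing,
#'   0--0.3); grid lines carrying region interfaces are never moved.
#' @param roi_extent depth/width (m) around the wound over which the fine
#'   element size is held, so that thin ROI layers remain resolved.
#' @return an [npwt_mesh()] with a `geom` field describing the generated
#'   geometry (breakpoints, wound rim node, parameters).
#' @export
build_limb_geometry <- function(params, h_fine = 0.001, h_coarse = 0.005,
                                jitter = 0, roi_extent = 0.02) {
  stopifnot(inherits(params, "limb_geometry_params"),
            h_fine > 0, h_coarse >= h_fine, jitter >= 0, jitter <= 0.3)
  L <- params$limb_length
  Rm <- params$muscle_radius
  Rb <- params$bone_radius
  rw <- params$wound_radius
  dw <- params$wound_depth
  z_wb <- L - dw          # wound bed (cavity bottom) plane
  z_b <- L - params$distal_cap  # bone tip plane
  f <- if (params$edge_shape == "round") params$edge_fillet_radius else 0
  if (f > 0 && (f > dw || f >= rw))
    stop("edge_fillet_radius must not exceed wound_depth or wound_radius")

  focus_r <- if (rw > 0) {
    list(c(max(0, rw - 0.2 * roi_extent), min(Rm, rw + roi_extent)))
  } else list()
  focus_z <- if (rw > 0) {
    list(c(max(0, z_wb - roi_extent), L))
  } else list()
  rbreaks <- sort(unique(c(0, Rb, if (rw > 0) rw,
                           unlist(focus_r), Rm)))
  zbreaks <- sort(unique(c(0, z_b, if (rw > 0) z_wb,
                           unlist(focus_z), L)))
  rbreaks <- rbreaks[rbreaks >= 0 & rbreaks <= Rm]
  zbreaks <- zbreaks[zbreaks >= 0 & zbreaks <= L]
  rbreaks <- rbreaks[c(TRUE, diff(rbreaks) > 1e-9)]
  zbreaks <- zbreaks[c(TRUE, diff(zbreaks) > 1e-9)]
  grade_axis <- function(breaks, focus) {
    out <- breaks[1]
    for (k in seq_len(length(breaks) - 1L)) {
      a <- breaks[k]; b <- breaks[k + 1L]
      ha <- .h_graded(a, focus, h_fine, h_coarse)
      hb <- .h_graded(b, focus, h_fine, h_coarse)
      out <- c(out, seq_graded(a, b, ha, hb)[-1])
    }
    out
  }
  rc <- grade_axis(rbreaks, focus_r)
  zc <- grade_axis(zbreaks, focus_z)
  g <- .grid_mesh(rc, zc)

  cx <- (g$nodes[g$elems[, 1], 1] + g$nodes[g$elems[, 2], 1] +
         g$nodes[g$elems[, 3], 1] + g$nodes[g$elems[, 4], 1]) / 4
  cz <- (g$nodes[g$elems[, 1], 2] + g$nodes[g$elems[, 2], 2] +
         g$nodes[g$elems[, 3], 2] + g$nodes[g$elems[, 4], 2]) / 4

  keep <- !(cx < Rb & cz < z_b)      # remove rigid bone core
  elems <- g$elems[keep, , drop = FALSE]
  cx <- cx[keep]; cz <- cz[keep]
  # drop nodes only referenced by the removed bone elements
  used <- sort(unique(as.vector(elems)))
  remap <- integer(nrow(g$nodes))
  remap[used] <- seq_along(used)
  g$nodes <- g$nodes[used, , drop = FALSE]
  elems[] <- remap[elems]
  region <- rep("muscle", nrow(elems))
  if (rw > 0) region[cx < rw & cz > z_wb] <- "filler"

  nodes <- g$nodes
  if (jitter > 0) {
    hr <- diff(rc); hz <- diff(zc)
    onbreak_r <- vapply(nodes[, 1], function(v) any(abs(v - rbreaks) < 1e-12), TRUE)
    onbreak_z <- vapply(nodes[, 2], function(v) any(abs(v - zbreaks) < 1e-12), TRUE)
    ir <- findInterval(nodes[, 1], rc, rightmost.closed = TRUE)
    iz <- findInterval(nodes[, 2], zc, rightmost.closed = TRUE)
    hloc_r <- pmin(hr[pmax(ir - 1L, 1L)], hr[pmin(ir, length(hr))])
    hloc_z <- pmin(hz[pmax(iz - 1L, 1L)], hz[pmin(iz, length(hz))])
    mov <- !onbreak_r & !onbreak_z
    n <- sum(mov)
    nodes[mov, 1] <- nodes[mov, 1] + jitter * hloc_r[mov] * (stats::runif(n) - 0.5)
    nodes[mov, 2] <- nodes[mov, 2] + jitter * hloc_z[mov] * (stats::runif(n) - 0.5)
  }

  # boundary edges of the meshed domain, oriented CCW (region on the left)
  ne <- nrow(elems)
  ed_all <- .elem_edges(elems)
  ed_el <- rep(seq_len(ne), times = 4L)
  key <- paste(pmin(ed_all[, 1], ed_all[, 2]), pmax(ed_all[, 1], ed_all[, 2]))
  cnt <- table(key)
  onb <- cnt[key] == 1L
  bed <- ed_all[onb, , drop = FALSE]
  bel <- ed_el[onb]
  mx <- (nodes[bed[, 1], 1] + nodes[bed[, 2], 1]) / 2
  mz <- (nodes[bed[, 1], 2] + nodes[bed[, 2], 2]) / 2
  tol <- 1e-9
  tag <- rep(NA_character_, nrow(bed))
  tag[abs(mz) < tol] <- "proximal_end"
  tag[abs(mx) < tol] <- "symmetry_axis"
  onbone <- (abs(mx - Rb) < tol & mz < z_b + tol) |
            (abs(mz - z_b) < tol & mx < Rb + tol)
  tag[is.na(tag) & onbone] <- "bone_interface"
  distal <- is.na(tag) & abs(mz - L) < tol
  tag[distal & region[bel] == "filler"] <- "filler_top"
  tag[distal & region[bel] == "muscle"] <- "outer_skin"
  tag[is.na(tag) & abs(mx - Rm) < tol] <- "outer_skin"
  if (anyNA(tag)) stop("internal error: untagged boundary facet")
  edges <- data.frame(n1 = bed[, 1], n2 = bed[, 2], tag = tag,
                      stringsAsFactors = FALSE)

  # muscle--filler interface, oriented CCW w.r.t. the muscle element so the
  # outward normal points into the cavity
  if (rw > 0 && any(region == "filler")) {
    dup <- key %in% names(cnt)[cnt == 2L]
    ord <- order(key[dup])
    dd <- ed_all[dup, , drop = FALSE][ord, , drop = FALSE]
    de <- ed_el[dup][ord]
    odd <- seq(1, nrow(dd), by = 2)
    r1 <- region[de[odd]]; r2 <- region[de[odd + 1]]
    mix <- r1 != r2
    pick <- ifelse(r1[mix] == "muscle", odd[mix], odd[mix] + 1)
    ied <- dd[pick, , drop = FALSE]
    dr <- nodes[ied[, 2], 1] - nodes[ied[, 1], 1]
    dz <- nodes[ied[, 2], 2] - nodes[ied[, 1], 2]
    # outward normal of muscle: (dz, -dr)
    itag <- ifelse(abs(dz) >= abs(dr), "wound_lateral", "wound_bottom")
    edges <- rbind(edges, data.frame(n1 = ied[, 1], n2 = ied[, 2],
                                     tag = itag, stringsAsFactors = FALSE))
  }

  if (rw > 0 && f > 0) {
    # round edges: map the L-inf ball of nodes around each cavity corner
    # onto the L2 ball, which carries the square corner (the two straight
    # walls) exactly onto the fillet arc; connectivity, regions and tags
    # are untouched, so the fillet is represented at any mesh resolution
    nodes <- .fillet_map(nodes, c(rw - f, z_wb + f), +1, -1, f)  # wound bed
    nodes <- .fillet_map(nodes, c(rw + f, L - f), -1, +1, f)     # wound rim
  }
  mesh <- npwt_mesh(nodes, elems, region, edges, axisymmetric = TRUE)
  rim <- NA_integer_
  if (rw > 0) {
    ftn <- unique(c(edges$n1[edges$tag == "filler_top"],
                    edges$n2[edges$tag == "filler_top"]))
    rim <- ftn[which.max(nodes[ftn, 1])]
  }
  mesh$geom <- list(params = params, z_wb = z_wb, z_b = z_b,
                    rbreaks = rbreaks, zbreaks = zbreaks,
                    h_fine = h_fine, h_coarse = h_coarse,
                    wound_rim_node = rim)
  mesh
}

#' ROI layer specification
#'
#' A tissue layer at a given distance from the wound-bed surface, used to
#' summarise principal stresses. `beneath_wound` layers are horizontal
#' slabs below the cavity bottom (lateral to the wound depth);
#' `beside_wound` layers are annular shells outside the cavity wall
#' spanning the wound depth (lateral to the wound width).
#'
#' @param direction `"beneath_wound"` or `"beside_wound"`.
#' @param offset distance of the layer from the wound-bed surface.
#' @param thickness layer thickness.
#' @param units length unit for `offset`/`thickness` (default `"mm"`).
#' @return an object of class `roi_layer_spec`.
#' @export
roi_layer_spec <- function(direction = c("beneath_wound", "beside_wound"),
                           offset, thickness = 2, units = "mm") {
  direction <- match.arg(direction)
  offset <- .len_to_m(offset, units)
  thickness <- .len_to_m(thickness, units)
  if (offset < 0) stop("offset must be non-negative")
  if (thickness <= 0) stop("thickness must be positive")
  structure(list(direction = direction, offset = offset,
                 thickness = thickness),
            class = "roi_layer_spec")
}

#' Select ROI layer elements
#'
#' Returns, for each layer specification, the muscle elements whose centroid
#' distance from the wound-bed surface (measured along the layer direction)
#' lies in `[offset, offset + thickness)`. Layers at different offsets in
#' the same direction are disjoint by construction.
#'
#' @param mesh a limb mesh from [build_limb_geometry()].
#' @param specs a list of [roi_layer_spec()] objects (a single spec is also
#'   accepted).
#' @return named list of integer element-index vectors.
#' @export
define_roi_layers <- function(mesh, specs) {
  if (inherits(specs, "roi_layer_spec")) specs <- list(specs)
  stopifnot(all(vapply(specs, inherits, TRUE, "roi_layer_spec")))
  if (is.null(mesh$geom)) stop("mesh lacks geometry metadata")
  p <- mesh$geom$params
  if (p$wound_radius <= 0) stop("ROI layers require a wound (wound_radius > 0)")
  z_wb <- mesh$geom$z_wb
  L <- p$limb_length
  rw <- p$wound_radius
  ctr <- element_centroids(mesh)
  musc <- mesh$region == "muscle"
  out <- vector("list", length(specs))
  nm <- character(length(specs))
  for (k in seq_along(specs)) {
    s <- specs[[k]]
    if (s$direction == "beneath_wound") {
      d <- z_wb - ctr[, 2]
      sel <- musc & ctr[, 1] < rw & d >= s$offset & d < s$offset + s$thickness
    } else {
      d <- ctr[, 1] - rw
      sel <- musc & ctr[, 2] >= z_wb & ctr[, 2] <= L &
        d >= s$offset & d < s$offset + s$thickness
    }
    if (!any(sel))
      stop(sprintf("empty ROI layer: %s at offset %.1f mm",
                   s$direction, s$offset * 1000))
    out[[k]] <- which(sel)
    nm[k] <- sprintf("%s_%gmm", s$direction, s$offset * 1000)
  }
  names(out) <- nm
  out
}
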