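#' Oxygen diffusion parameters
#'
#' Parameters of the capillary oxygen transport model. Diffusion follows
#' the extended flux law `J = -D grad(C) - s*K_P*grad(p)`: ordinary
#' Fickian diffusion plus a drift down gradients of the equivalent
#' pressure stress `p` from the capillary structural solve. A positive
#' pressure stress factor `K_P` drives oxygen from compressed towards
#' unloaded tissue; `K_P` has no literature value and is calibrated at
#' pipeline level (see [calibrate_pressure_factor()]).
#'
#' The transient solve is evaluated at the dimensionless time
#' `tau = D_tissue * t / R_out^2` (default 0.1): the true steady state
#' with a zero-flux outer boundary and no tissue consumption is uniform
#' and threshold-degenerate, so oxygenated-area comparisons are made at a
#' fixed developing-gradient time, identical for baseline and coupled
#' runs.
#'
#' @param D_tissue,D_wall oxygen diffusivities (cm^2/s).
#' @param solubility oxygen solubility s (ml O2 / ml / mmHg).
#' @param K_P pressure stress factor (uM m^2 / (s MPa) per unit
#'   solubility; signed).
#' @param wall_concentration Dirichlet concentration at the lumen surface
#'   (uM), normally the mid-length Krogh axial value 40.32 uM.
#' @param threshold oxygenation sufficiency threshold (uM, default 10).
#' @param tau_end dimensionless evaluation time.
#' @param dtau dimensionless implicit-Euler step.
#' @return object of class `diffusion_params`.
#' @export
diffusion_params <- function(D_tissue = 2e-5, D_wall = 1e-5,
                             solubility = 3.89e-5, K_P = 0,
                             wall_concentration = 40.32, threshold = 10,
                             tau_end = 0.1, dtau = 1e-3) {
  if (D_tissue <= 0 || D_wall <= 0) stop("diffusivities must be positive")
  if (threshold <= 0) stop("threshold must be positive")
  if (wall_concentration <= threshold)
    stop("wall_concentration must exceed the threshold at baseline")
  if (tau_end <= 0 || dtau <= 0 || dtau > tau_end)
    stop("invalid time parameters")
  structure(list(D_tissue = D_tissue * 1e-4, D_wall = D_wall * 1e-4,  # m^2/s
                 solubility = solubility, K_P = K_P,
                 wall_concentration = wall_concentration,
                 threshold = threshold, tau_end = tau_end, dtau = dtau),
            class = "diffusion_params")
}

# scalar-field (P1 on quads) matrices for a set of blocks
.scalar_matrices <- function(mesh, blocks, Dmap) {
  ndof <- nrow(mesh$nodes)
  ti <- list(); tj <- list(); tmx <- list(); tkx <- list()
  for (bn in names(blocks)) {
    blk <- blocks[[bn]]
    D <- Dmap[[bn]]
    nel <- length(blk$els)
    Me <- array(0, c(nel, 4, 4))
    Ke <- array(0, c(nel, 4, 4))
    for (gp in blk$gps) {
      for (a in 1:4) for (b in a:4) {
        mv <- gp$w * gp$N[a] * gp$N[b]
        kv <- gp$w * D * (gp$dN1[, a] * gp$dN1[, b] +
                            gp$dN2[, a] * gp$dN2[, b])
        Me[, a, b] <- Me[, a, b] + mv
        Ke[, a, b] <- Ke[, a, b] + kv
        if (b > a) { Me[, b, a] <- Me[, b, a] + mv; Ke[, b, a] <- Ke[, b, a] + kv }
      }
    }
    ti[[bn]] <- as.vector(blk$el[, rep(1:4, times = 4)])
    tj[[bn]] <- as.vector(blk$el[, rep(1:4, each = 4)])
    tmx[[bn]] <- as.vector(Me)
    tkx[[bn]] <- as.vector(Ke)
  }
  list(M = Matrix::sparseMatrix(i = unlist(ti), j = unlist(tj),
                                x = unlist(tmx), dims = c(ndof, ndof)),
       K = Matrix::sparseMatrix(i = unlist(ti), j = unlist(tj),
                                x = unlist(tkx), dims = c(ndof, ndof)))
}

# drift load vector b_a = -int grad(N_a) . (s K_P grad p) over the blocks;
# p is a nodal field
.drift_vector <- function(mesh, blocks, p_nodal, coef) {
  b <- numeric(nrow(mesh$nodes))
  for (bn in names(blocks)) {
    blk <- blocks[[bn]]
    pe <- matrix(p_nodal[blk$el], length(blk$els), 4)
    be <- matrix(0, length(blk$els), 4)
    for (gp in blk$gps) {
      gpx <- rowSums(pe * gp$dN1)
      gpy <- rowSums(pe * gp$dN2)
      for (a in 1:4)
        be[, a] <- be[, a] - gp$w * coef *
          (gp$dN1[, a] * gpx + gp$dN2[, a] * gpy)
    }
    ag <- rowsum(as.vector(be), as.vector(blk$el))
    b[as.integer(rownames(ag))] <- b[as.integer(rownames(ag))] + ag[, 1]
  }
  b
}

# area-weighted projection of an element field to nodes
.elem_to_nodal <- function(mesh, v) {
  a <- element_areas(mesh)
  w <- rowsum(rep(a / 4, 4), as.vector(mesh$elems))
  s <- rowsum(rep(v * a / 4, 4), as.vector(mesh$elems))
  out <- numeric(nrow(mesh$nodes))
  out[as.integer(rownames(w))] <- s[, 1] / w[, 1]
  out
}

# wall + tissue annulus submesh of a capillary mesh (nodes/elements of the
# polar rings are contiguous, so the subset keeps its indexing metadata)
.annulus_submesh <- function(mesh) {
  keep <- mesh$region %in% c("wall", "tissue")
  els <- which(keep)
  nodes_keep <- seq_len(max(mesh$elems[els, ]))
  sub <- npwt_mesh(mesh$nodes[nodes_keep, , drop = FALSE],
                   mesh$elems[els, , drop = FALSE],
                   mesh$region[els],
                   mesh$edges[mesh$edges$tag == "lumen_surface", ,
                              drop = FALSE],
                   axisymmetric = FALSE)
  sub$geom <- mesh$geom
  sub
}

#' Transient oxygen diffusion around the capillary
#'
#' Implicit-Euler solve of `dC/dt = div(D grad C + s K_P grad p)` on the
#' wall + tissue annulus: Dirichlet concentration at the lumen surface,
#' zero total flux at the Krogh outer boundary, zero initial tissue
#' concentration. With `p_field = NULL` (or `K_P = 0`) this is the
#' uncoupled Fickian baseline.
#'
#' @param mesh capillary mesh from [build_capillary_mesh()] (the annulus
#'   submesh is extracted internally).
#' @param params a [diffusion_params()].
#' @param p_field per-element equivalent pressure stress (MPa) on `mesh`
#'   (e.g. `solve_capillary(...)$p`), or `NULL` for the baseline.
#' @return object of class `concentration_field`: nodal concentrations
#'   `C` (uM) on the annulus submesh, mass-balance diagnostics, and the
#'   submesh itself.
#' @export
solve_diffusion <- function(mesh, params, p_field = NULL) {
  stopifnot(inherits(params, "diffusion_params"))
  if (params$K_P != 0 && is.null(p_field))
    stop("K_P is nonzero but no pressure stress field was supplied")
  sub <- .annulus_submesh(mesh)
  blocks <- .fem_blocks(sub)
  mats <- .scalar_matrices(sub, blocks,
                           list(wall = params$D_wall,
                                tissue = params$D_tissue))
  b <- if (!is.null(p_field) && params$K_P != 0) {
    pf <- if (length(p_field) == nrow(mesh$elems)) {
      p_field[seq_len(nrow(sub$elems))]
    } else p_field
    stopifnot(length(pf) == nrow(sub$elems))
    p_nodal <- .elem_to_nodal(sub, pf)
    .drift_vector(sub, blocks, p_nodal, params$solubility * params$K_P)
  } else numeric(nrow(sub$nodes))
  Rt <- sub$geom$capillary$tissue_outer_radius
  dt <- params$dtau * Rt^2 / params$D_tissue
  nt <- as.integer(round(params$tau_end / params$dtau))
  diri <- sort(unique(unlist(sub$edges[, c("n1", "n2")])))
  nfree <- setdiff(seq_len(nrow(sub$nodes)), diri)
  C <- numeric(nrow(sub$nodes))
  C[diri] <- params$wall_concentration
  A <- mats$M / dt + mats$K
  Aff <- A[nfree, nfree, drop = FALSE]
  Afd <- A[nfree, diri, drop = FALSE]
  fac <- Matrix::Cholesky(Matrix::forceSymmetric(Aff))
  mass <- numeric(nt + 1L)
  influx <- numeric(nt)
  one <- rep(1, nrow(sub$nodes))
  mass[1] <- sum(mats$M %*% C)
  for (n in seq_len(nt)) {
    rhs <- (mats$M %*% C / dt + b)[nfree] - Afd %*% C[diri]
    Cn <- C
    Cn[nfree] <- as.vector(Matrix::solve(fac, rhs))
    # inflow through the Dirichlet (lumen) nodes from their residual
    r <- mats$M %*% (Cn - C) / dt + mats$K %*% Cn - b
    influx[n] <- sum(r[diri])
    C <- Cn
    mass[n + 1L] <- sum(mats$M %*% C)
  }
  structure(list(C = as.vector(C), mesh = sub, params = params,
                 coupled = !is.null(p_field) && params$K_P != 0,
                 mass = mass, influx = influx, dt = dt),
            class = "concentration_field")
}

#' @export
print.concentration_field <- function(x, ...) {
  cat(sprintf(
    "<concentration_field> %s, %d nodes, C in [%.3g, %.3g] uM, oxygenated fraction %.3f\n",
    if (x$coupled) "coupled" else "baseline (uncoupled)",
    length(x$C), min(x$C), max(x$C),
    oxygenated_area(x)))
  invisible(x)
}

#' Oxygenated tissue-area fraction
#'
#' Fraction of the tissue annulus (wall excluded) whose oxygen
#' concentration is at or above the sufficiency threshold, by element-wise
#' quadrature of the indicator (element mean nodal concentration).
#'
#' @param conc a `concentration_field`.
#' @param threshold threshold in uM (defaults to the solve's parameter).
#' @return area fraction in `[0, 1]`.
#' @export
oxygenated_area <- function(conc, threshold = NULL) {
  stopifnot(inherits(conc, "concentration_field"))
  if (is.null(threshold)) threshold <- conc$params$threshold
  sel <- conc$mesh$region == "tissue"
  a <- element_areas(conc$mesh)[sel]
  ce <- rowMeans(matrix(conc$C[conc$mesh$elems[sel, ]], ncol = 4))
  sum(a * (ce >= threshold)) / sum(a)
}

#' Relative change of oxygenated area
#'
#' `100 * (coupled - baseline) / baseline`, signed (negative = loss of
#' oxygenated area).
#'
#' @param coupled,baseline area fractions in `[0, 1]`.
#' @return percent change.
#' @export
area_change <- function(coupled, baseline) {
  if (baseline <= 0) stop("baseline oxygenated area is zero")
  100 * (coupled - baseline) / baseline
}

#' Binary oxygenation mask
#'
#' Rasterises the concentration field over the Krogh annulus: white
#' (1) where `C >= threshold`, black (0) below the threshold or outside
#' the annulus. Uses bilinear interpolation on the polar node grid.
#'
#' @param conc a `concentration_field`.
#' @param threshold threshold in uM (defaults to the solve's parameter).
#' @param n raster size (n x n pixels).
#' @param file optional PNG path.
#' @return 0/1 integer matrix (invisibly if `file` is given).
#' @export
export_binary_mask <- function(conc, threshold = NULL, n = 512,
                               file = NULL) {
  stopifnot(inherits(conc, "concentration_field"))
  if (is.null(threshold)) threshold <- conc$params$threshold
  g <- conc$mesh$geom
  Rt <- g$capillary$tissue_outer_radius
  Rl <- g$radii[1]
  xs <- seq(-Rt, Rt, length.out = n)
  px <- matrix(rep(xs, times = n), n, n)
  py <- matrix(rep(xs, each = n), n, n)
  r <- sqrt(px^2 + py^2)
  th <- atan2(py, px) %% (2 * pi)
  nt <- g$n_theta
  radii <- g$radii
  jr <- th / (2 * pi) * nt              # fractional angular index (0-based)
  j0 <- floor(jr); fj <- jr - j0
  k0 <- findInterval(r, radii)
  inside <- r >= Rl & r <= radii[length(radii)]
  k0p <- pmin(pmax(k0, 1L), length(radii) - 1L)
  fk <- (r - radii[k0p]) / (radii[k0p + 1L] - radii[k0p])
  fk <- pmin(pmax(fk, 0), 1)
  nid <- function(j, k) (k - 1L) * nt + (j %% nt) + 1L
  Cv <- conc$C
  val <- (1 - fj) * ((1 - fk) * Cv[nid(j0, k0p)] + fk * Cv[nid(j0, k0p + 1L)]) +
    fj * ((1 - fk) * Cv[nid(j0 + 1L, k0p)] + fk * Cv[nid(j0 + 1L, k0p + 1L)])
  mask <- matrix(0L, n, n)
  mask[inside & val >= threshold] <- 1L
  if (!is.null(file)) {
    png::writePNG(mask * 1, target = file)
    return(invisible(mask))
  }
  mask
}
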