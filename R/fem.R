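## Nonlinear hyperelastic finite-element core.
##
## Total-Lagrangian bilinear quadrilaterals, axisymmetric (r,z) or plane
## strain. Nearly incompressible Mooney-Rivlin regions use the mean
## dilatation (B-bar) treatment: the isochoric stress is integrated with
## the full 2x2 Gauss rule while the volumetric pressure is evaluated from
## the element-averaged volume ratio, p_bar = U'(J_bar), which removes
## volumetric locking and passes the axisymmetric patch test (a 1-point
## volumetric rule does not: the dN/dz * r integrand it drops is
## quadratic). Compressible hyperfoam regions are fully integrated.
## External pressures are follower loads evaluated on the deformed
## surface, with their load stiffness in the Newton matrix. All element
## loops are vectorised over elements.

# Q4 shape functions at a quadrature point; corner order (-1,-1), (1,-1),
# (1,1), (-1,1) matching the CCW connectivity
.q4_shape <- function(xi, eta) {
  xs <- c(-1, 1, 1, -1)
  es <- c(-1, -1, 1, 1)
  list(N = 0.25 * (1 + xi * xs) * (1 + eta * es),
       dNxi = 0.25 * xs * (1 + eta * es),
       dNeta = 0.25 * es * (1 + xi * xs))
}

# reference-configuration data for one element block at one quadrature pt
.gp_data <- function(X1, X2, sh, w, axisym) {
  J11 <- 0; J12 <- 0; J21 <- 0; J22 <- 0
  for (a in 1:4) {
    J11 <- J11 + X1[, a] * sh$dNxi[a]
    J12 <- J12 + X1[, a] * sh$dNeta[a]
    J21 <- J21 + X2[, a] * sh$dNxi[a]
    J22 <- J22 + X2[, a] * sh$dNeta[a]
  }
  detJ <- J11 * J22 - J12 * J21
  nel <- length(detJ)
  dN1 <- matrix(0, nel, 4)
  dN2 <- matrix(0, nel, 4)
  for (a in 1:4) {
    dN1[, a] <- (J22 * sh$dNxi[a] - J21 * sh$dNeta[a]) / detJ
    dN2[, a] <- (-J12 * sh$dNxi[a] + J11 * sh$dNeta[a]) / detJ
  }
  R <- as.vector(X1 %*% sh$N)
  wgt <- w * detJ * (if (axisym) 2 * pi * R else 1)
  list(N = sh$N, dN1 = dN1, dN2 = dN2, detJ = detJ, R = R, w = wgt)
}

# per-region element blocks with precomputed quadrature data
.fem_blocks <- function(mesh) {
  g <- 1 / sqrt(3)
  qpts <- list(c(-g, -g), c(g, -g), c(g, g), c(-g, g))
  lapply(split(seq_len(nrow(mesh$elems)), mesh$region), function(els) {
    el <- mesh$elems[els, , drop = FALSE]
    X1 <- matrix(mesh$nodes[el, 1], ncol = 4)
    X2 <- matrix(mesh$nodes[el, 2], ncol = 4)
    dof <- matrix(0L, length(els), 8)
    dof[, seq(1, 8, 2)] <- 2L * el - 1L
    dof[, seq(2, 8, 2)] <- 2L * el
    gps <- lapply(qpts, function(q)
      .gp_data(X1, X2, .q4_shape(q[1], q[2]), 1, mesh$axisymmetric))
    ctr <- .gp_data(X1, X2, .q4_shape(0, 0), 4, mesh$axisymmetric)
    list(els = els, el = el, X1 = X1, X2 = X2, dof = dof,
         gps = gps, ctr = ctr)
  })
}

# kinematics at one quadrature point: deformation gradient and C
.gp_kinematics <- function(gp, ue, axisym) {
  nel <- nrow(ue)
  ur <- ue[, seq(1, 8, 2), drop = FALSE]
  uz <- ue[, seq(2, 8, 2), drop = FALSE]
  H11 <- rowSums(ur * gp$dN1); H12 <- rowSums(ur * gp$dN2)
  H21 <- rowSums(uz * gp$dN1); H22 <- rowSums(uz * gp$dN2)
  F11 <- 1 + H11; F12 <- H12; F21 <- H21; F22 <- 1 + H22
  F33 <- if (axisym) 1 + as.vector(ur %*% gp$N) / gp$R else rep(1, nel)
  C <- cbind(F11^2 + F21^2, F12^2 + F22^2, F33^2, F11 * F12 + F21 * F22)
  list(F11 = F11, F12 = F12, F21 = F21, F22 = F22, F33 = F33, C = C)
}

# strain-displacement operator B (nel x 4 x 8) at the current state
.gp_bmat <- function(gp, kin, axisym) {
  nel <- length(kin$F11)
  B <- array(0, c(nel, 4, 8))
  for (a in 1:4) {
    cr <- 2 * a - 1; cz <- 2 * a
    B[, 1, cr] <- kin$F11 * gp$dN1[, a]
    B[, 1, cz] <- kin$F21 * gp$dN1[, a]
    B[, 2, cr] <- kin$F12 * gp$dN2[, a]
    B[, 2, cz] <- kin$F22 * gp$dN2[, a]
    if (axisym) B[, 3, cr] <- kin$F33 * gp$N[a] / gp$R
    B[, 4, cr] <- kin$F11 * gp$dN2[, a] + kin$F12 * gp$dN1[, a]
    B[, 4, cz] <- kin$F21 * gp$dN2[, a] + kin$F22 * gp$dN1[, a]
  }
  B
}

# accumulate w * (B' S) into fe (nel x 8) and w * (B' D B + geometric)
# into Ke (nel x 8 x 8)
.gp_accumulate <- function(fe, Ke, gp, kin, S, D, axisym, with_K) {
  B <- .gp_bmat(gp, kin, axisym)
  w <- gp$w
  for (j in 1:8)
    fe[, j] <- fe[, j] + w * (B[, 1, j] * S[, 1] + B[, 2, j] * S[, 2] +
                                B[, 3, j] * S[, 3] + B[, 4, j] * S[, 4])
  if (with_K) {
    DB <- array(0, c(length(w), 4, 8))
    for (a in 1:4) for (j in 1:8)
      DB[, a, j] <- D[, a, 1] * B[, 1, j] + D[, a, 2] * B[, 2, j] +
        D[, a, 3] * B[, 3, j] + D[, a, 4] * B[, 4, j]
    for (i in 1:8) for (j in i:8) {
      v <- w * (B[, 1, i] * DB[, 1, j] + B[, 2, i] * DB[, 2, j] +
                  B[, 3, i] * DB[, 3, j] + B[, 4, i] * DB[, 4, j])
      Ke[, i, j] <- Ke[, i, j] + v
      if (j > i) Ke[, j, i] <- Ke[, j, i] + v
    }
    # geometric stiffness: dN' S dN on both dof families + hoop term
    for (a in 1:4) for (b in 1:4) {
      gab <- w * (gp$dN1[, a] * S[, 1] * gp$dN1[, b] +
                    gp$dN2[, a] * S[, 2] * gp$dN2[, b] +
                    (gp$dN1[, a] * gp$dN2[, b] +
                       gp$dN2[, a] * gp$dN1[, b]) * S[, 4])
      Ke[, 2 * a - 1, 2 * b - 1] <- Ke[, 2 * a - 1, 2 * b - 1] + gab
      Ke[, 2 * a, 2 * b] <- Ke[, 2 * a, 2 * b] + gab
      if (axisym)
        Ke[, 2 * a - 1, 2 * b - 1] <- Ke[, 2 * a - 1, 2 * b - 1] +
          w * gp$N[a] * S[, 3] * gp$N[b] / gp$R^2
    }
  }
  list(fe = fe, Ke = Ke)
}

# internal force and (optionally) tangent triplets for the whole mesh
.assemble_internal <- function(mesh, blocks, materials, u, with_K = TRUE) {
  ndof <- 2 * nrow(mesh$nodes)
  fint <- numeric(ndof)
  ti <- list(); tj <- list(); tx <- list()
  bad <- FALSE
  for (bn in names(blocks)) {
    blk <- blocks[[bn]]
    mat <- materials[[bn]]
    if (is.null(mat)) stop("no material for region ", bn)
    nel <- length(blk$els)
    ue <- matrix(u[blk$dof], nel, 8)
    fe <- matrix(0, nel, 8)
    Ke <- if (with_K) array(0, c(nel, 8, 8)) else NULL
    split <- .mat_split(mat)
    kins <- lapply(blk$gps, .gp_kinematics, ue = ue,
                   axisym = mesh$axisymmetric)
    Jg <- lapply(kins, function(k) {
      J <- k$F33 * (k$F11 * k$F22 - k$F12 * k$F21)
      if (any(!is.finite(J)) || any(J <= 0)) bad <<- TRUE
      J
    })
    if (split) {
      Ve <- Reduce(`+`, lapply(blk$gps, function(g) g$w))
      Jbar <- Reduce(`+`, Map(function(g, J) g$w * J, blk$gps, Jg)) / Ve
      pbar <- mat$kappa * (Jbar - 1)
      ge <- matrix(0, nel, 8)       # d(Ve*Jbar)/du, for the rank-one term
    }
    D <- NULL
    for (q in seq_along(blk$gps)) {
      gp <- blk$gps[[q]]; kin <- kins[[q]]; J <- Jg[[q]]
      if (!split) {
        S <- .mat_stress(kin$C, mat, "both")
        D <- if (with_K) .mat_tangent(kin$C, mat, "both")
      } else {
        iv <- .C_invariants(kin$C)
        S <- .mat_stress(kin$C, mat, "iso") + pbar * J * iv$Ci
        if (with_K) {
          D <- .mat_tangent(kin$C, mat, "iso") +
            pbar * J * (.outer4(iv$Ci, iv$Ci) - 2 * .sym4_Ci(iv$Ci))
        }
        B <- .gp_bmat(gp, kin, mesh$axisymmetric)
        JCi <- J * iv$Ci
        for (j in 1:8)
          ge[, j] <- ge[, j] + gp$w *
            (B[, 1, j] * JCi[, 1] + B[, 2, j] * JCi[, 2] +
               B[, 3, j] * JCi[, 3] + B[, 4, j] * JCi[, 4])
      }
      acc <- .gp_accumulate(fe, Ke, gp, kin, S, D, mesh$axisymmetric, with_K)
      fe <- acc$fe; Ke <- acc$Ke
    }
    if (split && with_K) {
      for (i in 1:8) for (j in 1:8)
        Ke[, i, j] <- Ke[, i, j] + (mat$kappa / Ve) * ge[, i] * ge[, j]
    }
    fi <- tapply(as.vector(fe), as.vector(blk$dof), sum)
    fint[as.integer(names(fi))] <- fint[as.integer(names(fi))] + as.vector(fi)
    if (with_K) {
      ti[[bn]] <- as.vector(blk$dof[, rep(1:8, times = 8)])
      tj[[bn]] <- as.vector(blk$dof[, rep(1:8, each = 8)])
      tx[[bn]] <- as.vector(Ke)
    }
  }
  list(fint = fint, ti = unlist(ti), tj = unlist(tj), tx = unlist(tx),
       bad = bad)
}

# follower pressure on oriented facets (region left of n1 -> n2, outward
# normal to the right). p > 0 pushes against the surface; p < 0 is
# suction. Returns nodal force vector and load-stiffness triplets.
.pressure_load <- function(mesh, u, edges, p, with_K = TRUE) {
  n1 <- edges[, 1]; n2 <- edges[, 2]
  x1 <- mesh$nodes[n1, 1] + u[2 * n1 - 1]
  y1 <- mesh$nodes[n1, 2] + u[2 * n1]
  x2 <- mesh$nodes[n2, 1] + u[2 * n2 - 1]
  y2 <- mesh$nodes[n2, 2] + u[2 * n2]
  dx <- x2 - x1; dy <- y2 - y1
  ndof <- 2 * nrow(mesh$nodes)
  f <- numeric(ndof)
  if (mesh$axisymmetric) {
    q <- 2 * pi * p
    m1 <- (2 * x1 + x2) / 6
    m2 <- (x1 + 2 * x2) / 6
    fe <- cbind(-q * dy * m1, q * dx * m1, -q * dy * m2, q * dx * m2)
    dofs <- cbind(2 * n1 - 1, 2 * n1, 2 * n2 - 1, 2 * n2)
    ag <- tapply(as.vector(fe), as.vector(dofs), sum)
    f[as.integer(names(ag))] <- as.vector(ag)
    if (!with_K) return(list(f = f, ti = NULL, tj = NULL, tx = NULL))
    ne <- length(n1)
    Ke <- array(0, c(ne, 4, 4))     # d fe / d (u_r1, u_z1, u_r2, u_z2)
    Ke[, 1, 1] <- -q * dy / 3;  Ke[, 1, 2] <- q * m1
    Ke[, 1, 3] <- -q * dy / 6;  Ke[, 1, 4] <- -q * m1
    Ke[, 2, 1] <- q * (-m1 + dx / 3)
    Ke[, 2, 3] <- q * (m1 + dx / 6)
    Ke[, 3, 1] <- -q * dy / 6;  Ke[, 3, 2] <- q * m2
    Ke[, 3, 3] <- -q * dy / 3;  Ke[, 3, 4] <- -q * m2
    Ke[, 4, 1] <- q * (-m2 + dx / 6)
    Ke[, 4, 3] <- q * (m2 + dx / 3)
  } else {
    fe <- cbind(-p * dy / 2, p * dx / 2, -p * dy / 2, p * dx / 2)
    dofs <- cbind(2 * n1 - 1, 2 * n1, 2 * n2 - 1, 2 * n2)
    ag <- tapply(as.vector(fe), as.vector(dofs), sum)
    f[as.integer(names(ag))] <- as.vector(ag)
    if (!with_K) return(list(f = f, ti = NULL, tj = NULL, tx = NULL))
    ne <- length(n1)
    Ke <- array(0, c(ne, 4, 4))
    Ke[, 1, 2] <- p / 2;  Ke[, 1, 4] <- -p / 2
    Ke[, 2, 1] <- -p / 2; Ke[, 2, 3] <- p / 2
    Ke[, 3, 2] <- p / 2;  Ke[, 3, 4] <- -p / 2
    Ke[, 4, 1] <- -p / 2; Ke[, 4, 3] <- p / 2
  }
  list(f = f,
       ti = as.vector(dofs[, rep(1:4, times = 4)]),
       tj = as.vector(dofs[, rep(1:4, each = 4)]),
       tx = as.vector(Ke))
}

#' Nonlinear static hyperelastic solve
#'
#' Newton solution of the total-Lagrangian equilibrium equations with
#' incremental follower pressure loading and adaptive load-step cut-back.
#'
#' @param mesh an [npwt_mesh()].
#' @param materials named list mapping each mesh region to an
#'   `npwt_material` ([mooney_rivlin()] or [hyperfoam()]).
#' @param loads list of pressure loads, each `list(edges =, p =)` where
#'   `edges` is a 2-column matrix of oriented facets (region to the left)
#'   and `p` the pressure in MPa (positive pushes against the surface,
#'   negative sucks).
#' @param fixed integer vector of constrained dof indices (dofs are
#'   `2*node - 1` for r/x and `2*node` for z/y); fixed dofs are held at 0.
#' @param nsteps number of uniform load increments.
#' @param tol relative residual tolerance.
#' @param stall_tol acceptance floor: when rounding noise (dominated by the
#'   near-incompressibility penalty at very small loads) stops the residual
#'   from improving, the increment is accepted once the residual is below
#'   this value.
#' @param maxit Newton iterations per increment before cut-back.
#' @param min_step smallest allowed load increment before giving up.
#' @param quiet suppress per-increment messages.
#' @return list with the nodal displacement matrix `u` (n x 2, metres),
#'   per-element Cauchy stress `stress` (ne x 4: 11, 22, hoop/out-of-plane,
#'   12; MPa), the final relative residual and iteration counts.
#' @export
solve_hyperelastic <- function(mesh, materials, loads, fixed,
                               nsteps = 10, tol = 1e-8, stall_tol = 1e-6,
                               maxit = 30, min_step = 1 / 160,
                               quiet = TRUE) {
  blocks <- .fem_blocks(mesh)
  ndof <- 2 * nrow(mesh$nodes)
  fixed <- sort(unique(as.integer(fixed)))
  free <- setdiff(seq_len(ndof), fixed)
  u <- numeric(ndof)
  lam <- 0
  dlam <- 1 / nsteps
  u_last <- u
  total_it <- 0L
  final_res <- NA_real_
  external <- function(u, lam, with_K) {
    f <- numeric(ndof); ti <- list(); tj <- list(); tx <- list()
    for (k in seq_along(loads)) {
      pl <- .pressure_load(mesh, u, loads[[k]]$edges, lam * loads[[k]]$p,
                           with_K)
      f <- f + pl$f
      if (with_K) { ti[[k]] <- pl$ti; tj[[k]] <- pl$tj; tx[[k]] <- pl$tx }
    }
    list(f = f, ti = unlist(ti), tj = unlist(tj), tx = unlist(tx))
  }
  while (lam < 1 - 1e-12) {
    lam_t <- min(1, lam + dlam)
    ok <- FALSE
    res_prev <- Inf
    for (it in seq_len(maxit)) {
      asm <- .assemble_internal(mesh, blocks, materials, u, with_K = TRUE)
      ext <- external(u, lam_t, with_K = TRUE)
      if (asm$bad || any(!is.finite(asm$fint))) break
      R <- asm$fint - ext$f
      ref <- max(sqrt(sum(ext$f[free]^2)), 1e-30)
      res <- sqrt(sum(R[free]^2)) / ref
      total_it <- total_it + 1L
      if (!quiet)
        message(sprintf("  lambda %.4f it %d residual %.3e", lam_t, it, res))
      if (is.finite(res) && res < tol) { ok <- TRUE; final_res <- res; break }
      if (is.finite(res) && res < stall_tol && res > 0.5 * res_prev) {
        # rounding-noise floor reached; no further improvement possible
        ok <- TRUE; final_res <- res; break
      }
      res_prev <- res
      K <- Matrix::sparseMatrix(
        i = c(asm$ti, ext$ti), j = c(asm$tj, ext$tj),
        x = c(asm$tx, -ext$tx), dims = c(ndof, ndof))
      du <- tryCatch(
        as.vector(Matrix::solve(K[free, free, drop = FALSE], -R[free])),
        error = function(e) NULL)
      if (is.null(du) || any(!is.finite(du))) break
      u[free] <- u[free] + du
    }
    if (ok) {
      lam <- lam_t
      u_last <- u
    } else {
      dlam <- dlam / 2
      u <- u_last
      if (dlam < min_step)
        stop(sprintf(
          "Newton failed to converge (load level %.3f, last residual %.3e)",
          lam_t, if (exists("res")) res else NA))
    }
  }
  stress <- .recover_stress(mesh, blocks, materials, u)
  list(u = matrix(u, ncol = 2, byrow = TRUE), stress = stress,
       residual = final_res, iterations = total_it)
}

# element-average Cauchy stress (ne x 4: 11, 22, 33, 12)
.recover_stress <- function(mesh, blocks, materials, u) {
  sig <- matrix(0, nrow(mesh$elems), 4)
  for (bn in names(blocks)) {
    blk <- blocks[[bn]]
    mat <- materials[[bn]]
    nel <- length(blk$els)
    ue <- matrix(u[blk$dof], nel, 8)
    split <- .mat_split(mat)
    kins <- lapply(blk$gps, .gp_kinematics, ue = ue,
                   axisym = mesh$axisymmetric)
    pbar <- if (split) {
      Jg <- lapply(kins, function(k)
        k$F33 * (k$F11 * k$F22 - k$F12 * k$F21))
      Ve <- Reduce(`+`, lapply(blk$gps, function(g) g$w))
      Jbar <- Reduce(`+`, Map(function(g, J) g$w * J, blk$gps, Jg)) / Ve
      mat$kappa * (Jbar - 1)
    }
    acc <- matrix(0, nel, 4)
    for (q in seq_along(blk$gps)) {
      kin <- kins[[q]]
      S <- .mat_stress(kin$C, mat, if (split) "iso" else "both")
      if (split) {
        # volumetric Cauchy part is p_bar * I exactly; add its PK2 image
        S <- S + pbar * (kin$F33 * (kin$F11 * kin$F22 - kin$F12 * kin$F21)) *
          .C_invariants(kin$C)$Ci
      }
      J <- kin$F33 * (kin$F11 * kin$F22 - kin$F12 * kin$F21)
      A11 <- kin$F11 * S[, 1] + kin$F12 * S[, 4]
      A12 <- kin$F11 * S[, 4] + kin$F12 * S[, 2]
      A21 <- kin$F21 * S[, 1] + kin$F22 * S[, 4]
      A22 <- kin$F21 * S[, 4] + kin$F22 * S[, 2]
      acc <- acc + cbind(
        (A11 * kin$F11 + A12 * kin$F12) / J,
        (A21 * kin$F21 + A22 * kin$F22) / J,
        kin$F33^2 * S[, 3] / J,
        (A11 * kin$F21 + A12 * kin$F22) / J)
    }
    sig[blk$els, ] <- acc / length(blk$gps)
  }
  sig
}

#' Principal Cauchy stresses
#'
#' Eigenvalues of the per-element stress tensor (in-plane pair plus the
#' hoop/out-of-plane direct stress), sorted so that column 1 is the
#' maximum and column 3 the minimum principal stress.
#'
#' @param stress ne x 4 stress matrix (components 11, 22, 33, 12; MPa).
#' @return ne x 3 matrix of principal stresses (MPa).
#' @export
principal_stresses <- function(stress) {
  av <- (stress[, 1] + stress[, 2]) / 2
  rad <- sqrt(((stress[, 1] - stress[, 2]) / 2)^2 + stress[, 4]^2)
  p <- cbind(av + rad, av - rad, stress[, 3])
  t(apply(p, 1, sort, decreasing = TRUE))
}

#' Equivalent pressure stress
#'
#' `p = -tr(sigma)/3`: the negative mean normal stress, positive in
#' compression. Drives the pressure-stress term of the extended diffusion
#' law.
#'
#' @param stress ne x 4 stress matrix (components 11, 22, 33, 12; MPa).
#' @return numeric vector (MPa).
#' @export
pressure_stress <- function(stress) {
  -(stress[, 1] + stress[, 2] + stress[, 3]) / 3
}
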