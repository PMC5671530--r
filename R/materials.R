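#' Mooney-Rivlin hyperelastic material
#'
#' Two-parameter Mooney-Rivlin model with strain energy
#' `W = C1*(I1b - 3) + C2*(I2b - 3) + U(J)` where `I1b`, `I2b` are the
#' isochoric (deviatoric) strain invariants. The volumetric part is
#' `U(J) = (1/D) (J - 1)^2` when a compressibility parameter `D > 0` is
#' given (so the initial bulk modulus is `2/D`); with `D = 0` the material
#' is incompressible and is regularised by a penalty bulk modulus
#' `bulk_ratio * mu0`, `mu0 = 2*(C1 + C2)` being the initial shear modulus.
#'
#' @param C1,C2 deviatoric constants (MPa).
#' @param D compressibility parameter (1/MPa); 0 means incompressible.
#' @param bulk_ratio penalty bulk-to-shear ratio used when `D = 0`.
#' @return object of class `c("mooney_rivlin", "npwt_material")`.
#' @export
mooney_rivlin <- function(C1, C2, D = 0, bulk_ratio = 1000) {
  if (C1 < 0 || C2 < 0 || C1 + C2 <= 0)
    stop("require C1 >= 0, C2 >= 0, C1 + C2 > 0")
  if (D < 0) stop("D must be non-negative")
  mu0 <- 2 * (C1 + C2)
  kappa <- if (D > 0) 2 / D else bulk_ratio * mu0
  structure(list(C1 = C1, C2 = C2, D = D, mu0 = mu0, kappa = kappa),
            class = c("mooney_rivlin", "npwt_material"))
}

#' @export
print.mooney_rivlin <- function(x, ...) {
  cat(sprintf(
    "<mooney_rivlin> C1 = %g MPa, C2 = %g MPa, D = %g (mu0 = %g, kappa = %g MPa)\n",
    x$C1, x$C2, x$D, x$mu0, x$kappa))
  invisible(x)
}

#' Ogden-type hyperfoam material (single term)
#'
#' Compressible foam energy
#' `U = (2 mu / alpha^2) * (l1^a + l2^a + l3^a - 3 + (J^(-a*b) - 1)/b)`
#' in the principal stretches, with `a = alpha`, `b = beta`. The effective
#' initial Poisson ratio is `beta / (1 + 2*beta)`.
#'
#' @param mu modulus-like constant (MPa).
#' @param alpha stretch exponent (nonzero).
#' @param beta volumetric exponent (> 0).
#' @return object of class `c("hyperfoam", "npwt_material")`.
#' @export
hyperfoam <- function(mu, alpha, beta) {
  if (mu <= 0) stop("mu must be positive")
  if (alpha == 0) stop("alpha must be nonzero")
  if (beta <= 0) stop("beta must be positive")
  structure(list(mu = mu, alpha = alpha, beta = beta),
            class = c("hyperfoam", "npwt_material"))
}

#' @export
print.hyperfoam <- function(x, ...) {
  cat(sprintf("<hyperfoam> mu = %g MPa, alpha = %g, beta = %g\n",
              x$mu, x$alpha, x$beta))
  invisible(x)
}

#' Default material set
#'
#' Literature-derived constants used throughout: muscle and capillary
#' surrounding tissue are Mooney-Rivlin with C1 = 0.0094 MPa,
#' C2 = 0.082 MPa, incompressible (D = 0); the polyurethane foam filler is
#' hyperfoam with mu = 0.907e-2, alpha = 0.213e-2, beta = 0.844e-2; the
#' capillary wall is Mooney-Rivlin with C1 = 0.257 MPa, C2 = 0.00257 MPa,
#' D = 1e-6.
#'
#' @param bulk_ratio penalty bulk-to-shear ratio for incompressible
#'   Mooney-Rivlin entries.
#' @return named list with entries `muscle`, `filler`, `wall`, `tissue`.
#' @export
npwt_materials <- function(bulk_ratio = 1000) {
  muscle <- mooney_rivlin(0.0094, 0.082, 0, bulk_ratio = bulk_ratio)
  list(muscle = muscle,
       filler = hyperfoam(0.907e-2, 0.213e-2, 0.844e-2),
       wall = mooney_rivlin(0.257, 0.00257, 1e-6, bulk_ratio = bulk_ratio),
       tissue = muscle)
}

#' Mooney-Rivlin strain-energy density
#'
#' Direct evaluation of `W = C1*(I1 - 3) + C2*(I2 - 3)` plus, when the
#' material has `D > 0` and a volume ratio is supplied, the volumetric
#' penalty `(1/D)*(J - 1)^2`.
#'
#' @param I1,I2 first and second strain invariants.
#' @param params a [mooney_rivlin()] material.
#' @param J volume ratio (default 1).
#' @return energy density (MPa).
#' @export
mr_energy <- function(I1, I2, params, J = 1) {
  stopifnot(inherits(params, "mooney_rivlin"))
  W <- params$C1 * (I1 - 3) + params$C2 * (I2 - 3)
  if (params$D > 0) W <- W + (1 / params$D) * (J - 1)^2
  W
}

#' Incompressible uniaxial Mooney-Rivlin stress (closed form)
#'
#' Cauchy stress of an incompressible Mooney-Rivlin bar at uniaxial
#' stretch `lambda`: `2*(lambda^2 - 1/lambda)*(C1 + C2/lambda)`. Used as a
#' closed-form verification oracle for the finite-element kernels.
#'
#' @param lambda uniaxial stretch (> 0).
#' @param params a [mooney_rivlin()] material.
#' @return Cauchy stress (MPa).
#' @export
mr_uniaxial_stress <- function(lambda, params) {
  stopifnot(inherits(params, "mooney_rivlin"))
  if (any(lambda <= 0)) stop("lambda must be positive")
  2 * (lambda^2 - 1 / lambda) * (params$C1 + params$C2 / lambda)
}

## ---------------------------------------------------------------------
## Internal vectorised constitutive kernels.
##
## Symmetric tensors with the axisymmetric/plane structure (no 13/23
## coupling) are stored as n x 4 matrices with columns (11, 22, 33, 12);
## 33 is the hoop (axisymmetric) or out-of-plane (plane strain) direction.
## PK2 stress S is returned in the same layout; tangents are n x 4 x 4 in
## the Voigt convention where the work-conjugate strain vector is
## (E11, E22, E33, 2*E12).
## ---------------------------------------------------------------------

.C_invariants <- function(C) {
  d2 <- C[, 1] * C[, 2] - C[, 4]^2
  detC <- C[, 3] * d2
  list(
    I1 = C[, 1] + C[, 2] + C[, 3],
    I2 = d2 + C[, 3] * (C[, 1] + C[, 2]),
    J = sqrt(detC),
    Ci = cbind(C[, 2] / d2, C[, 1] / d2, 1 / C[, 3], -C[, 4] / d2))
}

# outer product of two n x 4 symmetric tensors -> n x 4 x 4
.outer4 <- function(X, Y) {
  n <- nrow(X)
  out <- array(0, c(n, 4, 4))
  for (a in 1:4) for (b in 1:4) out[, a, b] <- X[, a] * Y[, b]
  out
}

# S_Ci[a,b] = 1/2 (Ci_ik Ci_jl + Ci_il Ci_jk) in Voigt layout, for tensors
# with Ci13 = Ci23 = 0
.sym4_Ci <- function(Ci) {
  n <- nrow(Ci)
  out <- array(0, c(n, 4, 4))
  out[, 1, 1] <- Ci[, 1]^2
  out[, 2, 2] <- Ci[, 2]^2
  out[, 3, 3] <- Ci[, 3]^2
  out[, 1, 2] <- out[, 2, 1] <- Ci[, 4]^2
  out[, 1, 4] <- out[, 4, 1] <- Ci[, 1] * Ci[, 4]
  out[, 2, 4] <- out[, 4, 2] <- Ci[, 2] * Ci[, 4]
  out[, 4, 4] <- 0.5 * (Ci[, 1] * Ci[, 2] + Ci[, 4]^2)
  out
}

# Mooney-Rivlin PK2 stress; part = "iso", "vol" or "both"
.mr_stress <- function(C, pars, part = "both") {
  iv <- .C_invariants(C)
  n <- nrow(C)
  S <- matrix(0, n, 4)
  Id <- matrix(rep(c(1, 1, 1, 0), each = n), n, 4)
  if (part %in% c("iso", "both")) {
    A <- iv$J^(-2 / 3)
    B <- iv$J^(-4 / 3)
    Y <- iv$I1 * Id - C
    S <- S + 2 * pars$C1 * A * (Id - (iv$I1 / 3) * iv$Ci) +
      2 * pars$C2 * B * (Y - (2 * iv$I2 / 3) * iv$Ci)
  }
  if (part %in% c("vol", "both")) {
    S <- S + pars$kappa * iv$J * (iv$J - 1) * iv$Ci
  }
  S
}

# Mooney-Rivlin material tangent (2 dS/dC), Voigt n x 4 x 4
.mr_tangent <- function(C, pars, part = "both") {
  iv <- .C_invariants(C)
  n <- nrow(C)
  Id <- matrix(rep(c(1, 1, 1, 0), each = n), n, 4)
  SCi <- .sym4_Ci(iv$Ci)
  CiCi <- .outer4(iv$Ci, iv$Ci)
  D <- array(0, c(n, 4, 4))
  if (part %in% c("iso", "both")) {
    A <- iv$J^(-2 / 3)
    B <- iv$J^(-4 / 3)
    Y <- iv$I1 * Id - C
    IxCi <- .outer4(Id, iv$Ci)
    CixI <- .outer4(iv$Ci, Id)
    D <- D + 4 * pars$C1 * A *
      (-(IxCi + CixI) / 3 + (iv$I1 / 9) * CiCi + (iv$I1 / 3) * SCi)
    II <- .outer4(Id, Id)
    Isym <- array(0, c(n, 4, 4))
    Isym[, 1, 1] <- Isym[, 2, 2] <- Isym[, 3, 3] <- 1
    Isym[, 4, 4] <- 0.5
    YxCi <- .outer4(Y, iv$Ci)
    CixY <- .outer4(iv$Ci, Y)
    D <- D + 4 * pars$C2 *
      (B * (II - Isym) - (2 * B / 3) * (YxCi + CixY) +
         (4 * B * iv$I2 / 9) * CiCi + (2 * B * iv$I2 / 3) * SCi)
  }
  if (part %in% c("vol", "both")) {
    D <- D + pars$kappa *
      (iv$J * (2 * iv$J - 1) * CiCi - 2 * iv$J * (iv$J - 1) * SCi)
  }
  D
}

# principal stretches of C (n x 4): in-plane pair + out-of-plane, with
# in-plane eigenvector cosine/sine (stable at coalescence)
.C_principal <- function(C) {
  av <- (C[, 1] + C[, 2]) / 2
  df <- (C[, 1] - C[, 2]) / 2
  rad <- sqrt(df^2 + C[, 4]^2)
  l1sq <- av + rad
  l2sq <- av - rad
  deg <- rad < 1e-14 * pmax(1, av)
  # eigenvector for l1sq: (l1sq - C22, C12) if C11 dominates, else
  # (C12, l1sq - C11); both satisfy (C - l1sq I) v = 0
  vx <- ifelse(df >= 0, rad + df, C[, 4])
  vy <- ifelse(df >= 0, C[, 4], rad - df)
  nv <- sqrt(vx^2 + vy^2)
  cs <- ifelse(deg | nv < 1e-300, 1, vx / pmax(nv, 1e-300))
  sn <- ifelse(deg | nv < 1e-300, 0, vy / pmax(nv, 1e-300))
  list(l1sq = l1sq, l2sq = l2sq, l3sq = C[, 3], cs = cs, sn = sn)
}

# hyperfoam PK2 stress from principal stretches; the small printed alpha
# makes lambda^alpha - J^(-alpha*beta) a difference of numbers near 1, so
# it is evaluated with expm1 to avoid cancellation
.foam_stress <- function(C, pars) {
  pr <- .C_principal(C)
  ll1 <- 0.5 * log(pr$l1sq); ll2 <- 0.5 * log(pr$l2sq); ll3 <- 0.5 * log(pr$l3sq)
  lnJ <- ll1 + ll2 + ll3
  a <- pars$alpha
  eJ <- expm1(-a * pars$beta * lnJ)
  fac <- 2 * pars$mu / a
  S1 <- fac * (expm1(a * ll1) - eJ) / pr$l1sq
  S2 <- fac * (expm1(a * ll2) - eJ) / pr$l2sq
  S3 <- fac * (expm1(a * ll3) - eJ) / pr$l3sq
  c2 <- pr$cs^2; s2 <- pr$sn^2; csn <- pr$cs * pr$sn
  cbind(S1 * c2 + S2 * s2, S1 * s2 + S2 * c2, S3, (S1 - S2) * csn)
}

# numerical material tangent (2 dS/dC) by central differences on the
# symmetric components of C; exact Voigt bookkeeping (see vignette)
.num_tangent <- function(stress_fun, C, h = 1e-7) {
  n <- nrow(C)
  D <- array(0, c(n, 4, 4))
  for (b in 1:4) {
    hb <- h * pmax(1, abs(C[, b]))
    Cp <- C; Cm <- C
    Cp[, b] <- Cp[, b] + hb
    Cm[, b] <- Cm[, b] - hb
    G <- (stress_fun(Cp) - stress_fun(Cm)) / (2 * hb)
    D[, , b] <- if (b == 4) G else 2 * G
  }
  # symmetrise (minor asymmetry from finite differencing)
  for (a in 1:3) for (b in (a + 1):4) {
    m <- (D[, a, b] + D[, b, a]) / 2
    D[, a, b] <- m; D[, b, a] <- m
  }
  D
}

.foam_tangent <- function(C, pars) {
  .num_tangent(function(Cx) .foam_stress(Cx, pars), C)
}

# energy densities used by verification tests
.mr_energy_C <- function(C, pars) {
  iv <- .C_invariants(C)
  J23 <- iv$J^(-2 / 3)
  pars$C1 * (J23 * iv$I1 - 3) + pars$C2 * (J23^2 * iv$I2 - 3) +
    pars$kappa / 2 * (iv$J - 1)^2
}

.foam_energy_C <- function(C, pars) {
  pr <- .C_principal(C)
  ll1 <- 0.5 * log(pr$l1sq); ll2 <- 0.5 * log(pr$l2sq); ll3 <- 0.5 * log(pr$l3sq)
  lnJ <- ll1 + ll2 + ll3
  a <- pars$alpha
  2 * pars$mu / a^2 *
    (expm1(a * ll1) + expm1(a * ll2) + expm1(a * ll3) +
       expm1(-a * pars$beta * lnJ) / pars$beta)
}

# dispatch: stress and tangent for any npwt_material
.mat_stress <- function(C, mat, part = "both") {
  if (inherits(mat, "mooney_rivlin")) .mr_stress(C, mat, part)
  else .foam_stress(C, mat)
}

.mat_tangent <- function(C, mat, part = "both") {
  if (inherits(mat, "mooney_rivlin")) .mr_tangent(C, mat, part)
  else .foam_tangent(C, mat)
}

# does this material use the split (SRI) integration scheme?
.mat_split <- function(mat) inherits(mat, "mooney_rivlin")
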