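# Independent 1D radial finite-volume oracle for uncoupled diffusion on
# the wall + tissue annulus: vertex-centred control volumes, harmonic-mean
# face diffusivities, implicit Euler with the same dimensionless step as
# the 2D solver.
radial_fd_oracle <- function(nr = 1600, tau_end = 0.1, dtau = 1e-3,
                             Rl = 5e-6, Rw = 5.5e-6, Rt = 40e-6,
                             Dw = 1e-9, Dt = 2e-9, C_wall = 40.32) {
  r <- seq(Rl, Rt, length.out = nr + 1)
  h <- r[2] - r[1]
  Dfun <- function(rr) ifelse(rr < Rw, Dw, Dt)
  rf <- (r[-1] + r[-length(r)]) / 2
  Df <- 2 / (1 / Dfun(r[-1]) + 1 / Dfun(r[-length(r)]))
  G <- Df * rf / h
  V <- numeric(nr + 1)
  V[1] <- (rf[1]^2 - r[1]^2) / 2
  V[nr + 1] <- (r[nr + 1]^2 - rf[nr]^2) / 2
  V[2:nr] <- (rf[2:nr]^2 - rf[1:(nr - 1)]^2) / 2
  dt <- dtau * Rt^2 / Dt
  nsteps <- as.integer(round(tau_end / dtau))
  ii <- rep(seq_len(nr), each = 4) + rep(c(0L, 0L, 1L, 1L), nr)
  jj <- rep(seq_len(nr), each = 4) + rep(c(0L, 1L, 0L, 1L), nr)
  xx <- rep(G, each = 4) * rep(c(1, -1, -1, 1), nr)
  L <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                            dims = c(nr + 1, nr + 1))
  A <- Matrix::Diagonal(x = V / dt) + L
  free <- 2:(nr + 1)
  fc <- Matrix::Cholesky(Matrix::forceSymmetric(A[free, free]))
  Ad <- A[free, 1, drop = FALSE]
  C <- numeric(nr + 1)
  C[1] <- C_wall
  for (n in seq_len(nsteps)) {
    rhs <- (V / dt * C)[free] - Ad %*% C[1]
    C[free] <- as.vector(Matrix::solve(fc, rhs))
  }
  list(r = r, C = C)
}

# ring-average of a nodal field on the polar capillary (sub)mesh
ring_means <- function(conc) {
  nt <- conc$mesh$geom$n_theta
  nr <- length(conc$mesh$geom$radii)
  colMeans(matrix(conc$C, nt, nr))
}
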