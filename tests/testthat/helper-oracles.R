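# Independent oracles used by the tests. Each deliberately takes a
# different computational route than the package implementation it checks.

# Horn's quaternion method for optimal superposition: the rotation comes
# from the leading eigenvector of the 4x4 key matrix, not from an SVD.
quaternion_rotation <- function(P, Q) {
  Pc <- sweep(P, 2, colMeans(P))
  Qc <- sweep(Q, 2, colMeans(Q))
  M <- crossprod(Pc, Qc)
  Sxx <- M[1, 1]; Sxy <- M[1, 2]; Sxz <- M[1, 3]
  Syx <- M[2, 1]; Syy <- M[2, 2]; Syz <- M[2, 3]
  Szx <- M[3, 1]; Szy <- M[3, 2]; Szz <- M[3, 3]
  K <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy,       Szx - Sxz,       Sxy - Syx,
    Syz - Szy,       Sxx - Syy - Szz, Sxy + Syx,       Szx + Sxz,
    Szx - Sxz,       Sxy + Syx,       -Sxx + Syy - Szz, Syz + Szy,
    Sxy - Syx,       Szx + Sxz,       Syz + Szy,       -Sxx - Syy + Szz),
    4, 4, byrow = TRUE)
  q <- eigen(K, symmetric = TRUE)$vectors[, 1]
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  # rotation acting on row vectors as P %*% R
  t(matrix(c(
    w^2 + x^2 - y^2 - z^2, 2 * (x * y - w * z),   2 * (x * z + w * y),
    2 * (x * y + w * z),   w^2 - x^2 + y^2 - z^2, 2 * (y * z - w * x),
    2 * (x * z - w * y),   2 * (y * z + w * x),   w^2 - x^2 - y^2 + z^2),
    3, 3, byrow = TRUE))
}

# Mass-action equilibrium for independent sites by 1D root-finding on the
# complex concentration (no closed-form quadratic).
mass_action_complex <- function(M_tot, X_tot, Kd, n) {
  f <- function(C) (n * M_tot - C) * (X_tot - C) - Kd * C
  stats::uniroot(f, c(0, min(n * M_tot, X_tot)),
                 tol = .Machine$double.eps)$root
}

# Brute-force grid search for the best-fitting exponential rate; I0 is
# profiled out analytically at each candidate rate.
grid_search_rate <- function(t, y, lo = 0.1, hi = 20, n_grid = 1e4) {
  rates <- seq(lo, hi, length.out = n_grid)
  sse <- vapply(rates, function(R) {
    e <- exp(-R * t)
    I0 <- sum(y * e) / sum(e^2)
    sum((y - I0 * e)^2)
  }, numeric(1))
  rates[which.min(sse)]
}

# Random proper rotation.
random_rotation <- function() {
  R <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

# Write restraint records back out as XPLOR assign statements (fixture
# builder for parser/classifier tests).
write_xplor_fixture <- function(path, seps, hbond = 0, start_res = 10L) {
  lines <- c("! NOE distance restraints")
  res_i <- start_res
  for (s in seps) {
    lines <- c(lines, sprintf(
      "assign (resid %d and name HA)(resid %d and name HN) 4.00 2.20 1.00",
      res_i, res_i + s))
    res_i <- res_i + 1L
  }
  if (hbond > 0) {
    lines <- c(lines, "! hydrogen bonds")
    for (k in seq_len(hbond)) {
      lines <- c(lines, sprintf(
        "assign (resid %d and name N)(resid %d and name O) 2.90 0.50 0.50",
        k, k + 30L))
    }
  }
  writeLines(lines, path)
  path
}
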