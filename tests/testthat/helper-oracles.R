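# Independent oracles used across the suite.

# numerically locate the minimum of a quad_fes by golden-section search,
# independent of the closed-form expressions in the package
num_minimum <- function(fes, lower, upper) {
  opt <- stats::optimize(function(x) predict(fes, x), c(lower, upper),
                         tol = 1e-13)
  c(x = opt$minimum, V = opt$objective)
}

# brute-force Coulomb double loop (scalar arithmetic, no matrix algebra)
brute_coulomb <- function(qa, pa, qb, pb) {
  kC <- 14.3996
  e <- 0
  for (i in seq_along(qa)) for (j in seq_along(qb)) {
    r <- sqrt(sum((pa[i, ] - pb[j, ])^2))
    e <- e + kC * qa[i] * qb[j] / r
  }
  e
}

# random rotation matrix (QR of a Gaussian matrix, det +1)
random_rotation <- function() {
  qr_d <- qr(matrix(stats::rnorm(9), 3))
  Q <- qr.Q(qr_d)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

kT300 <- physical_constants()$kB_eV * 300
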