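# Mie partial-wave series for homogeneous spheres (Bohren-Huffman style
# recurrences), vectorized over the size parameter so that (n, d) model
# grids are cheap to build. Used by the forward scattering model that maps
# (refractive index, diameter) to forward- and backward-cap cross-sections.

# Mie coefficients a_n, b_n for relative index m and size parameters x
# (vector). Returns nmax x length(x) matrices.
mie_ab <- function(m, x) {
  stopifnot(all(x > 0), length(m) == 1)
  xmax <- max(x)
  nmax <- ceiling(xmax + 4 * xmax^(1 / 3) + 2)
  if (nmax > 2000) stop("size parameter beyond series convergence guard")
  nx <- length(x)
  mx <- m * x

  # logarithmic derivative D_n(mx) by downward recurrence
  nmx <- max(nmax, ceiling(max(Mod(mx)))) + 16
  D <- matrix(0 + 0i, nmx + 1, nx)
  for (n in nmx:1) {
    D[n, ] <- (n + 1) / mx - 1 / (D[n + 1, ] + (n + 1) / mx)
  }

  # Riccati-Bessel psi_n(x), chi_n(x) by upward recurrence
  psi0 <- sin(x); psi_m1 <- cos(x)       # psi_0, psi_{-1}
  chi0 <- cos(x); chi_m1 <- -sin(x)
  a <- matrix(0 + 0i, nmax, nx)
  b <- matrix(0 + 0i, nmax, nx)
  psi_nm1 <- psi0; psi_nm2 <- psi_m1
  chi_nm1 <- chi0; chi_nm2 <- chi_m1
  for (n in seq_len(nmax)) {
    psi <- (2 * n - 1) / x * psi_nm1 - psi_nm2
    chi <- (2 * n - 1) / x * chi_nm1 - chi_nm2
    xi <- psi - 1i * chi
    xi_nm1 <- psi_nm1 - 1i * chi_nm1
    da <- D[n, ] / m + n / x
    db <- D[n, ] * m + n / x
    a[n, ] <- (da * psi - psi_nm1) / (da * xi - xi_nm1)
    b[n, ] <- (db * psi - psi_nm1) / (db * xi - xi_nm1)
    psi_nm2 <- psi_nm1; psi_nm1 <- psi
    chi_nm2 <- chi_nm1; chi_nm1 <- chi
  }
  list(a = a, b = b, nmax = nmax)
}

# angular functions pi_n(mu), tau_n(mu); mu = cos(theta) vector.
# Returns nmax x length(mu) matrices.
mie_pitau <- function(nmax, mu) {
  nmu <- length(mu)
  Pi <- matrix(0, nmax, nmu)
  Tau <- matrix(0, nmax, nmu)
  Pi[1, ] <- 1
  Tau[1, ] <- mu
  if (nmax >= 2) {
    Pi[2, ] <- 3 * mu
    Tau[2, ] <- 2 * mu * Pi[2, ] - 3 * Pi[1, ]
    if (nmax >= 3) {
      for (n in 3:nmax) {
        Pi[n, ] <- (2 * n - 1) / (n - 1) * mu * Pi[n - 1, ] -
          n / (n - 1) * Pi[n - 2, ]
        Tau[n, ] <- n * mu * Pi[n, ] - (n + 1) * Pi[n - 1, ]
      }
    }
  }
  list(Pi = Pi, Tau = Tau)
}

#' Mie scattering amplitudes
#'
#' Complex amplitude functions S1 and S2 of a homogeneous sphere, from the
#' partial-wave (Mie) series.
#'
#' @param m Relative refractive index (particle / medium).
#' @param x Size parameter `pi * d * n_medium / wavelength` (scalar or
#'   vector).
#' @param theta Scattering angles (radians), 0 = forward.
#' @return List with complex matrices `S1`, `S2` of shape
#'   `length(x) x length(theta)`.
#' @export
mie_amplitudes <- function(m, x, theta) {
  ab <- mie_ab(m, x)
  pt <- mie_pitau(ab$nmax, cos(theta))
  n <- seq_len(ab$nmax)
  w <- (2 * n + 1) / (n * (n + 1))
  A <- ab$a * w
  B <- ab$b * w
  list(S1 = t(A) %*% pt$Pi + t(B) %*% pt$Tau,
       S2 = t(A) %*% pt$Tau + t(B) %*% pt$Pi)
}

# unpolarized differential cross-section integrated over a polar cap
# [theta0, theta1]; wavelength in the same length unit as the returned
# sigma^(1/2). Vectorized over x. Returns sigma in wavelength-unit^2.
mie_cap_sigma <- function(m, x, wavelength, medium_index, theta0, theta1,
                          n_nodes = 96) {
  k <- 2 * pi * medium_index / wavelength
  gl <- pracma::gaussLegendre(n_nodes, theta0, theta1)
  S <- mie_amplitudes(m, x, gl$x)
  integ <- (Mod(S$S1)^2 + Mod(S$S2)^2) %*% (gl$w * sin(gl$x))
  as.numeric(pi / k^2 * integ)
}
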