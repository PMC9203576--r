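# Lorenz-Mie partial-wave coefficients and plane-wave efficiencies.
#
# Standard Bohren & Huffman formulation: logarithmic derivative D_n by
# downward recurrence, Riccati-Bessel psi/chi by upward recurrence.

#' Mie partial-wave coefficients a_n, b_n
#'
#' @param x Size parameter `k a` with `k` the wavenumber in the medium.
#' @param m Relative refractive index `n_bead / n_medium`.
#' @param nmax Number of partial waves; default Wiscombe-style
#'   `x + 4 x^(1/3) + 2`.
#' @return List with complex vectors `a`, `b` of length `nmax`.
#' @keywords internal
mie_ab <- function(x, m, nmax = NULL) {
  stopifnot(x > 0)
  if (is.null(nmax)) nmax <- max(3L, ceiling(x + 4 * x^(1 / 3) + 2))
  mx <- m * x
  # log derivative by downward recurrence
  nstart <- nmax + 15L
  D <- complex(nstart + 1)  # D[n+1] = D_n
  for (n in nstart:1) {
    D[n] <- n / mx - 1 / (D[n + 1] + n / mx)
  }
  D <- D[2:(nmax + 1)]  # D_1 .. D_nmax
  # Riccati-Bessel psi_n(x), chi_n(x) upward
  psi <- numeric(nmax + 1)  # psi[n+1] = psi_n, n = 0..nmax
  chi <- numeric(nmax + 1)
  psi0 <- sin(x); psim1 <- cos(x)       # psi_0, psi_{-1}
  chi0 <- cos(x); chim1 <- -sin(x)      # chi_0, chi_{-1}
  psi[1] <- psi0; chi[1] <- chi0
  pm2 <- psim1; pm1 <- psi0
  cm2 <- chim1; cm1 <- chi0
  for (n in 1:nmax) {
    pn <- (2 * n - 1) / x * pm1 - pm2
    cn <- (2 * n - 1) / x * cm1 - cm2
    psi[n + 1] <- pn; chi[n + 1] <- cn
    pm2 <- pm1; pm1 <- pn
    cm2 <- cm1; cm1 <- cn
  }
  xi <- psi - 1i * chi
  n <- 1:nmax
  psin <- psi[n + 1]; psin1 <- psi[n]
  xin <- xi[n + 1]; xin1 <- xi[n]
  fa <- D / m + n / x
  fb <- D * m + n / x
  a <- (fa * psin - psin1) / (fa * xin - xin1)
  b <- (fb * psin - psin1) / (fb * xin - xin1)
  if (any(!is.finite(Mod(a))) || any(!is.finite(Mod(b)))) {
    stop("Mie series failed to converge with ", nmax, " terms")
  }
  list(a = a, b = b, nmax = nmax)
}

#' Plane-wave Mie efficiencies
#'
#' Extinction, scattering, asymmetry-weighted scattering and radiation
#' pressure efficiencies for plane-wave illumination. Used as the
#' plane-wave limit of the shaped-beam force model.
#'
#' @inheritParams mie_ab
#' @return List with `q_ext`, `q_sca`, `g_qsca`, `q_pr`.
#' @keywords internal
mie_efficiencies <- function(x, m, nmax = NULL) {
  ab <- mie_ab(x, m, nmax)
  a <- ab$a; b <- ab$b
  n <- seq_along(a)
  q_ext <- (2 / x^2) * sum((2 * n + 1) * Re(a + b))
  q_sca <- (2 / x^2) * sum((2 * n + 1) * (Mod(a)^2 + Mod(b)^2))
  a1 <- c(a[-1], 0); b1 <- c(b[-1], 0)
  g_qsca <- (4 / x^2) * (
    sum(n * (n + 2) / (n + 1) * Re(a * Conj(a1) + b * Conj(b1))) +
    sum((2 * n + 1) / (n * (n + 1)) * Re(a * Conj(b)))
  )
  list(q_ext = q_ext, q_sca = q_sca, g_qsca = g_qsca,
       q_pr = q_ext - g_qsca)
}
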