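# Kuramoto oscillators coupled through a diffusive external medium.
#
# Each quorum-sensing cell just beyond its Hopf point reduces to a phase
# oscillator; the bulk reduces to a complex medium amplitude z = a e^{i psi}:
#   dtheta_j/dt = omega_j + kappa_hat a sum_k W_jk sin(psi - theta_k)
#   dz/dt = (alpha kappa_hat / N) sum_{j,k} W_jk (e^{i theta_k} - z)
#           - (gamma0 + i omega0) z
# W = I recovers the classical medium-coupled Kuramoto model; a general W
# carries the finite-diffusion Green's-function corrections of the reduced
# quorum-sensing system.  The order parameter is
# zbar = mean(e^{i theta}) = abar e^{i psibar}, 0 <= abar <= 1.

#' Construct a medium-coupled Kuramoto system
#'
#' @param N number of oscillators.
#' @param kappa_hat exchange rate.
#' @param alpha compartment volume fraction.
#' @param gamma0 medium decay rate.
#' @param omega0 medium rotation rate (rotating-frame offset).
#' @param g_sd standard deviation of the (normal, even) natural frequency
#'   distribution in the rotating frame; 0 for identical oscillators.
#' @param W optional N x N coupling matrix (default identity).
#' @param seed seed for the frequency draw and initial phases.
#' @export
kuramoto_system <- function(N, kappa_hat, alpha = 1, gamma0 = 0.5,
                            omega0 = 0, g_sd = 0, W = NULL, seed = 1L) {
  set.seed(seed)
  omega <- if (g_sd > 0) stats::rnorm(N, 0, g_sd) else rep(0, N)
  theta0 <- stats::runif(N, 0, 2 * pi)
  if (is.null(W)) W <- diag(N)
  structure(list(N = N, kappa_hat = kappa_hat, alpha = alpha,
                 gamma0 = gamma0, omega0 = omega0, omega = omega,
                 theta0 = theta0, W = W, seed = seed),
            class = "kuramoto_system")
}

#' Simulate the medium-coupled Kuramoto dynamics
#'
#' @param ksys a [kuramoto_system()].
#' @param horizon,n_out integration horizon and output grid size.
#' @param z0 initial medium state (complex).
#' @return matrix with columns time, theta_j..., Re(z), Im(z), `abar`
#'   (order-parameter modulus).
#' @export
kuramoto_simulate <- function(ksys, horizon, n_out = 400, z0 = 0 + 0i) {
  N <- ksys$N
  y0 <- c(ksys$theta0, Re(z0), Im(z0))
  f <- function(t, y, parms) {
    th <- y[seq_len(N)]
    zr <- y[N + 1L]; zi <- y[N + 2L]
    a <- sqrt(zr^2 + zi^2)
    psi <- atan2(zi, zr)
    sinterm <- as.vector(ksys$W %*% sin(psi - th))
    dth <- ksys$omega + ksys$kappa_hat * a * sinterm
    e_r <- cos(th); e_i <- sin(th)
    we_r <- as.vector(ksys$W %*% e_r); we_i <- as.vector(ksys$W %*% e_i)
    wsum <- sum(ksys$W)
    pre <- ksys$alpha * ksys$kappa_hat / N
    dzr <- pre * (sum(we_r) - wsum * zr) -
      (ksys$gamma0 * zr - ksys$omega0 * zi)
    dzi <- pre * (sum(we_i) - wsum * zi) -
      (ksys$gamma0 * zi + ksys$omega0 * zr)
    if (!all(is.finite(c(dth, dzr, dzi)))) stop("non-finite Kuramoto state")
    list(c(dth, dzr, dzi))
  }
  times <- seq(0, horizon, length.out = n_out)
  out <- deSolve::lsoda(y0, times, f, NULL, rtol = 1e-10, atol = 1e-12)
  colnames(out) <- c("time", paste0("theta", seq_len(N)), "z_re", "z_im")
  th <- out[, 1 + seq_len(N), drop = FALSE]
  abar <- sqrt(rowMeans(cos(th))^2 + rowMeans(sin(th))^2)
  cbind(out, abar = abar)
}
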