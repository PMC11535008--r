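# Log-space modified Bessel helpers.
#
# The addition-theorem series for the disk and sphere Green's functions pair
# K_n (which overflows at large order) with I_n (which underflows); individual
# terms are well scaled only as products, so all series coefficients are
# assembled in log space.  base::besselI/besselK are used whenever they do not
# under/overflow; otherwise the leading small-argument asymptotics
# I_nu(x) ~ (x/2)^nu/Gamma(nu+1), K_nu(x) ~ Gamma(nu)(2/x)^nu/2 take over
# (accurate to < 1e-15 relative once base R has under/overflowed at the
# argument sizes used here, x = O(1), nu > 100).

log_besselI <- function(x, nu) {
  out <- rep(NA_real_, length(x))
  ok <- x > 1e-200   # below this base R warns about precision; use the series
  if (any(ok)) {
    v <- besselI(x[ok], nu, expon.scaled = TRUE)
    out[ok] <- ifelse(is.finite(v) & v > 0, log(v) + x[ok], NA_real_)
  }
  bad <- which(!is.finite(out))
  if (length(bad)) {
    xb <- if (length(x) == 1L) rep(x, length(bad)) else x[bad]
    t1 <- xb^2 / (4 * (nu + 1))
    out[bad] <- nu * log(xb / 2) - lgamma(nu + 1) +
      log1p(t1 * (1 + xb^2 / (8 * (nu + 2))))
  }
  out
}

log_besselK <- function(x, nu) {
  nu <- abs(nu)
  v <- besselK(x, nu, expon.scaled = TRUE)
  out <- ifelse(is.finite(v) & v > 0, log(v) - x, NA_real_)
  bad <- which(!is.finite(out))
  if (length(bad)) {
    xb <- if (length(x) == 1L) rep(x, length(bad)) else x[bad]
    t1 <- xb^2 / (4 * (nu - 1))
    out[bad] <- log(0.5) + lgamma(nu) + nu * log(2 / xb) +
      log1p(-t1 * (1 - xb^2 / (8 * (nu - 2))))
  }
  out
}

logsumexp2 <- function(a, b) {
  m <- pmax(a, b)
  m + log1p(exp(pmin(a, b) - m))
}

logdiffexp <- function(a, b) {
  # log(e^a - e^b) for a > b
  a + log1p(-exp(b - a))
}

# log of the Neumann reflection coefficient for the unit disk:
#   c_n = -K_n'(beta)/I_n'(beta) = (K_{n-1}+K_{n+1})/(I_{n-1}+I_{n+1})  (> 0)
log_disk_coef <- function(n, beta) {
  lk <- logsumexp2(log_besselK(beta, abs(n - 1)), log_besselK(beta, n + 1))
  li <- logsumexp2(log_besselI(beta, abs(n - 1)), log_besselI(beta, n + 1))
  lk - li
}

# Modified spherical Bessel functions (log scale):
#   i_l(x) = sqrt(pi/(2x)) I_{l+1/2}(x),  k_l(x) = sqrt(2/(pi x)) K_{l+1/2}(x)
log_sph_i <- function(x, l) 0.5 * log(pi / (2 * x)) + log_besselI(x, l + 0.5)
log_sph_k <- function(x, l) 0.5 * log(2 / (pi * x)) + log_besselK(x, l + 0.5)

# i_l'(x) = i_{l-1}(x) - ((l+1)/x) i_l(x)   (positive; i_{-1}(x) = cosh(x)/x)
# k_l'(x) = -k_{l-1}(x) - ((l+1)/x) k_l(x)  (negative; k_{-1} = k_0)
# Neumann reflection coefficient for the unit sphere: c_l = -k_l'/i_l'  (> 0)
log_sphere_coef <- function(l, beta) {
  lk <- logsumexp2(log_sph_k(beta, max(l - 1, 0)),
                   log(l + 1) - log(beta) + log_sph_k(beta, l))
  li_lo <- if (l == 0) log(cosh(beta)) - log(beta) else log_sph_i(beta, l - 1)
  li_hi <- log(l + 1) - log(beta) + log_sph_i(beta, l)
  lk - logdiffexp(li_lo, li_hi)
}

# complementary error function
erfc_ <- function(x) 2 * stats::pnorm(-x * sqrt(2))
erf_ <- function(x) 1 - erfc_(x)

# Legendre polynomials P_0..P_lmax at a vector of arguments; returns a
# length(x) x (lmax+1) matrix built by the three-term recurrence.
legendre_table <- function(x, lmax) {
  out <- matrix(0, length(x), lmax + 1L)
  out[, 1] <- 1
  if (lmax >= 1) out[, 2] <- x
  if (lmax >= 2) {
    for (l in 2:lmax)
      out[, l + 1] <- ((2 * l - 1) * x * out[, l] - (l - 1) * out[, l - 1]) / l
  }
  out
}

# Gauss-Legendre nodes/weights on [a, b] (Golub-Welsch via symmetric
# tridiagonal eigen decomposition; exact for polynomials of degree 2n-1).
gauss_legendre <- function(n, a = -1, b = 1) {
  if (n == 1L) {
    x <- 0; w <- 2
  } else {
    i <- seq_len(n - 1)
    off <- i / sqrt(4 * i^2 - 1)
    J <- matrix(0, n, n)
    J[cbind(i, i + 1)] <- off
    J[cbind(i + 1, i)] <- off
    e <- eigen(J, symmetric = TRUE)
    x <- rev(e$values)
    w <- 2 * rev(e$vectors[1, ]^2)
  }
  list(nodes = (b - a) / 2 * x + (a + b) / 2, weights = (b - a) / 2 * w)
}
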