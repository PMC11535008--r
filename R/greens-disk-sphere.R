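# Green's functions of the modified Helmholtz operator with reflecting
# boundary, unit disk and unit sphere.
#
# Both are built from the free-space screened kernel plus an
# addition-theorem correction series whose coefficients cancel the normal
# derivative on the unit boundary:
#   2D:  G = (1/2piD) [ K0(beta R) + sum_n e_n c_n I_n(beta r) I_n(beta r') cos(n dtheta) ]
#        with c_n = -K_n'(beta)/I_n'(beta),
#   3D:  G = (1/4piD) [ exp(-beta R)/R
#              + beta sum_l (2l+1) c_l i_l(beta r) i_l(beta r') P_l(cos gamma) ]
#        with c_l = -k_l'(beta)/i_l'(beta),
# beta = sqrt((gamma0+s)/D).  The correction series converge geometrically
# like (r r')^n for interior points, so they are truncated once the term
# bound falls below `tol` times the running sum.

EULER_GAMMA <- 0.57721566490153286

# ---- unit disk, gamma0 + s > 0 ---------------------------------------------

disk_series_coefs <- function(beta, lr, lr0, tol, nmax = 600L) {
  # returns data.frame n, logc for terms that can matter given log I bounds
  ns <- 0:nmax
  lc <- vapply(ns, function(n) log_disk_coef(n, beta), 0)
  keep <- which(lc + lr + lr0 > log(tol) - 34)  # generous absolute floor
  list(n = ns, logc = lc, keep = keep)
}

greens_disk2d_value <- function(x, x0, beta, D, tol) {
  x <- rbind(x)
  r <- sqrt(rowSums(x^2)); r0 <- sqrt(sum(x0^2))
  dx <- x[, 1] - x0[1]; dy <- x[, 2] - x0[2]
  R <- sqrt(dx * dx + dy * dy)
  th <- atan2(x[, 2], x[, 1]); th0 <- atan2(x0[2], x0[1])
  out <- besselK(beta * R, 0)
  rmax <- max(r)
  acc_scale <- max(abs(out), 1)
  n <- 0L
  repeat {
    lc <- log_disk_coef(n, beta)
    li0 <- log_besselI(beta * max(r0, 1e-300), n)
    # term bound over all points
    lbound <- lc + li0 + log_besselI(beta * max(rmax, 1e-300), n)
    if (n > 0 && lbound < log(tol * acc_scale) - 3) break
    term <- exp(lc + li0 + log_besselI(beta * pmax(r, 1e-300), n))
    if (n == 0L && r0 == 0) {
      out <- out + term  # only n = 0 survives when the source is central
      # higher orders vanish identically
      n <- n + 1L
      if (beta * rmax == 0) break
      next
    }
    en <- if (n == 0L) 1 else 2
    out <- out + en * term * cos(n * (th - th0))
    n <- n + 1L
    if (n > 600L) break
  }
  out / (2 * pi * D)
}

greens_disk2d_regular <- function(x0, beta, D, tol) {
  r0 <- sqrt(sum(x0^2))
  acc <- -log(beta / 2) - EULER_GAMMA
  n <- 0L
  repeat {
    lc <- log_disk_coef(n, beta)
    lt <- lc + 2 * log_besselI(beta * max(r0, 1e-300), n)
    term <- exp(lt)
    en <- if (n == 0L) 1 else 2
    acc <- acc + en * term
    if (n > 0 && lt < log(tol * max(abs(acc), 1)) - 3) break
    if (r0 == 0 && n == 0L) break  # higher orders vanish at the centre
    n <- n + 1L
    if (n > 600L) break
  }
  acc / (2 * pi * D)
}

# pseudo-Green's function of the unit disk (zero degradation), closed form:
#   G0 = (1/2piD)[ -ln|x-x'| - ln(|x'| |x - x'/|x'|^2|) + (|x|^2+|x'|^2)/2 - 3/4 ]
greens_disk2d_pseudo <- function(x, x0, D) {
  x <- rbind(x)
  dx <- x[, 1] - x0[1]; dy <- x[, 2] - x0[2]
  R2 <- dx * dx + dy * dy
  r2 <- rowSums(x^2); r02 <- sum(x0^2)
  img2 <- r2 * r02 - 2 * (x[, 1] * x0[1] + x[, 2] * x0[2]) + 1
  (-0.5 * log(R2) - 0.5 * log(img2) + (r2 + r02) / 2 - 0.75) / (2 * pi * D)
}

greens_disk2d_pseudo_regular <- function(x0, D) {
  r02 <- sum(x0^2)
  (-log(1 - r02) + r02 - 0.75) / (2 * pi * D)
}

# ---- unit sphere, gamma0 + s > 0 -------------------------------------------

greens_sphere3d_value <- function(x, x0, beta, D, tol) {
  x <- rbind(x)
  r <- sqrt(rowSums(x^2)); r0 <- sqrt(sum(x0^2))
  d <- sweep(x, 2, x0)
  R <- sqrt(rowSums(d^2))
  out <- exp(-beta * R) / R
  if (r0 == 0) {
    # only l = 0 survives
    lc <- log_sphere_coef(0, beta)
    out <- out + beta * exp(lc + log_sph_i(beta * pmax(r, 1e-300), 0) + 0)
    # i_0(0) = 1 -> log term 0
    return(out / (4 * pi * D))
  }
  cosg <- (x %*% x0) / pmax(r * r0, 1e-300)
  cosg <- pmin(pmax(as.vector(cosg), -1), 1)
  rmax <- max(max(r), 1e-300)
  # truncation scan
  lmax <- 4L
  repeat {
    lb <- log_sphere_coef(lmax, beta) +
      log_sph_i(beta * rmax, lmax) + log_sph_i(beta * r0, lmax) +
      log(2 * lmax + 1) + log(beta)
    if (lb < log(tol * max(max(abs(out)), 1)) - 3 || lmax > 400L) break
    lmax <- lmax + 4L
  }
  P <- legendre_table(cosg, lmax)
  for (l in 0:lmax) {
    lc <- log_sphere_coef(l, beta)
    term <- exp(lc + log_sph_i(beta * pmax(r, 1e-300), l) +
                  log_sph_i(beta * r0, l))
    out <- out + beta * (2 * l + 1) * term * P[, l + 1]
  }
  out / (4 * pi * D)
}

greens_sphere3d_regular <- function(x0, beta, D, tol) {
  r0 <- sqrt(sum(x0^2))
  acc <- -beta
  l <- 0L
  repeat {
    lc <- log_sphere_coef(l, beta)
    li <- if (r0 == 0) {
      if (l == 0) 0 else -Inf
    } else log_sph_i(beta * r0, l)
    lt <- lc + 2 * li + log(2 * l + 1) + log(beta)
    acc <- acc + beta * (2 * l + 1) * exp(lc + 2 * li)
    if (l > 0 && lt < log(tol * max(abs(acc), 1)) - 3) break
    if (r0 == 0 && l == 0L) break
    l <- l + 1L
    if (l > 400L) break
  }
  acc / (4 * pi * D)
}

# pseudo-Green's function of the unit sphere (zero degradation), closed form
# from the narrow-escape literature; rp = |x'| |x - x'/|x'|^2|:
#   G0 = (1/D)[ 1/(4 pi R) + 1/(4 pi rp)
#               + (1/4pi) ln( 2/(1 - x.x' + rp) )
#               + (|x|^2 + |x'|^2)/(8 pi) - 7/(10 pi) ]
greens_sphere3d_pseudo <- function(x, x0, D) {
  x <- rbind(x)
  d <- sweep(x, 2, x0)
  R <- sqrt(rowSums(d^2))
  r2 <- rowSums(x^2); r02 <- sum(x0^2)
  dot <- as.vector(x %*% x0)
  rp <- sqrt(pmax(r2 * r02 - 2 * dot + 1, 0))
  (1 / (4 * pi * R) + 1 / (4 * pi * rp) +
     log(2 / (1 - dot + rp)) / (4 * pi) +
     (r2 + r02) / (8 * pi) - 7 / (10 * pi)) / D
}

greens_sphere3d_pseudo_regular <- function(x0, D) {
  r02 <- sum(x0^2)
  (1 / (4 * pi * (1 - r02)) - log(1 - r02) / (4 * pi) +
     r02 / (4 * pi) - 7 / (10 * pi)) / D
}
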