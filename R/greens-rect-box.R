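# Green's functions for the rectangle and box with reflecting walls.
#
# For gamma0 + s > 0 the screened free-space kernels decay exponentially, so
# the method of images over the reflection lattice converges at desk scale:
#   2D: G = (1/2piD) sum_i K0(beta d_i),   3D: G = (1/4piD) sum_i exp(-beta d_i)/d_i.
# The s-derivative H = dG/ds at s = 0 is obtained term-wise:
#   2D: dK0(beta d)/ds = -d K1(beta d)/(2 D beta),
#   3D: d[exp(-beta d)/d]/ds = -exp(-beta d)/(2 D beta).
#
# The zero-degradation pseudo-Green's functions use
#   rect2d: a cosine-mode expansion across the short side whose oscillatory
#           part is resummed exactly into image logarithms
#           (sum_n q^n cos(n phi)/n = -log(1 - 2 q cos phi + q^2)/2),
#   box3d:  Ewald summation of the zero-mean periodic Coulomb potential on the
#           doubled torus, folded over the eight reflection images.

# reflection images of a source point x0 within distance rcut of the domain
reflection_images <- function(x0, size, rcut) {
  d <- length(size)
  per_dim <- vector("list", d)
  for (i in seq_len(d)) {
    L <- size[i]
    M <- ceiling((rcut + L) / (2 * L)) + 1L
    m <- seq(-M, M)
    vals <- c(outer(2 * L * m, c(x0[i], -x0[i]), `+`))
    per_dim[[i]] <- vals[vals > -rcut & vals < L + rcut]
  }
  img <- as.matrix(expand.grid(per_dim))
  colnames(img) <- NULL
  # keep images within rcut of the domain (box) in max metric sense
  keep <- rep(TRUE, nrow(img))
  for (i in seq_len(d))
    keep <- keep & img[, i] > -rcut & img[, i] < size[i] + rcut
  img[keep, , drop = FALSE]
}

image_distances <- function(x, img) {
  # x: P x d, img: I x d -> P x I distance matrix
  P <- nrow(x); I <- nrow(img); d <- ncol(x)
  acc <- matrix(0, P, I)
  for (i in seq_len(d))
    acc <- acc + (matrix(x[, i], P, I) -
                    matrix(img[, i], P, I, byrow = TRUE))^2
  sqrt(acc)
}

# ---- rectangle, gamma0 + s > 0 ---------------------------------------------

rect_rcut <- function(beta, tol) max(34, -log(tol) + 8) / beta

greens_rect2d_value <- function(x, x0, beta, D, size, tol) {
  x <- rbind(x)
  img <- reflection_images(x0, size, rect_rcut(beta, tol))
  dmat <- image_distances(x, img)
  rowSums(besselK(beta * dmat, 0)) / (2 * pi * D)
}

greens_rect2d_regular <- function(x0, beta, D, size, tol) {
  img <- reflection_images(x0, size, rect_rcut(beta, tol))
  self <- which(abs(img[, 1] - x0[1]) + abs(img[, 2] - x0[2]) < 1e-14)[1]
  d <- image_distances(rbind(x0), img[-self, , drop = FALSE])
  (-log(beta / 2) - EULER_GAMMA + sum(besselK(beta * d, 0))) / (2 * pi * D)
}

greens_rect2d_sderiv <- function(x, x0, beta, D, size, tol) {
  x <- rbind(x)
  img <- reflection_images(x0, size, rect_rcut(beta, tol))
  dmat <- image_distances(x, img)
  -rowSums(dmat * besselK(beta * dmat, 1)) / (4 * pi * D^2 * beta)
}

greens_rect2d_regular_sderiv <- function(x0, beta, D, size, tol) {
  img <- reflection_images(x0, size, rect_rcut(beta, tol))
  self <- which(abs(img[, 1] - x0[1]) + abs(img[, 2] - x0[2]) < 1e-14)[1]
  d <- image_distances(rbind(x0), img[-self, , drop = FALSE])
  -1 / (4 * pi * D^2 * beta^2) -
    sum(d * besselK(beta * d, 1)) / (4 * pi * D^2 * beta)
}

# ---- rectangle, pseudo-Green's function ------------------------------------

# Modes run across the shorter side b; images are reflected along the longer
# side a.  With u the coordinate along a and v along b:
#   G0 = (1/(bD)) [ (u^2+u'^2)/(2a) - max(u,u') + a/3 ]
#        - (1/4piD) sum_d [ ln E(d, v-v') + ln E(d, v+v') ]
# over the 1D image offsets d of u' (families |u-u'|+2ma, (u+u')+2ma,
# 2(m+1)a-(u+u'), 2(m+1)a-|u-u'|), with
#   E(d, w) = 1 - 2 exp(-pi d/b) cos(pi w/b) + exp(-2 pi d/b).
rect_orient <- function(size) {
  if (size[2] <= size[1]) list(a = size[1], b = size[2], iu = 1L, iv = 2L)
  else list(a = size[2], b = size[1], iu = 2L, iv = 1L)
}

rect_pseudo_offsets <- function(du_abs, su, a, b, tol) {
  # du_abs = |u - u'| , su = u + u'; returns vector of image offsets d >= 0
  M <- ceiling(b * (-log(tol) + 6) / (2 * pi * a)) + 1L
  m <- 0:M
  c(du_abs + 2 * a * m, su + 2 * a * m, 2 * (m + 1) * a - su,
    2 * (m + 1) * a - du_abs)
}

logE <- function(d, w, b) {
  q <- exp(-pi * d / b)
  log1p(q * (q - 2 * cos(pi * w / b)))
}

greens_rect2d_pseudo <- function(x, x0, D, size, tol) {
  x <- rbind(x)
  o <- rect_orient(size)
  u <- x[, o$iu]; v <- x[, o$iv]
  u0 <- x0[o$iu]; v0 <- x0[o$iv]
  a <- o$a; b <- o$b
  g0 <- ((u^2 + u0^2) / (2 * a) - pmax(u, u0) + a / 3) / (b * D)
  osc <- numeric(nrow(x))
  for (p in seq_len(nrow(x))) {
    dvec <- rect_pseudo_offsets(abs(u[p] - u0), u[p] + u0, a, b, tol)
    osc[p] <- -sum(logE(dvec, v[p] - v0, b) + logE(dvec, v[p] + v0, b)) /
      (4 * pi * D)
  }
  g0 + osc
}

greens_rect2d_pseudo_regular <- function(x0, D, size, tol) {
  o <- rect_orient(size)
  u0 <- x0[o$iu]; v0 <- x0[o$iv]
  a <- o$a; b <- o$b
  g0 <- (u0^2 / a - u0 + a / 3) / (b * D)
  M <- ceiling(b * (-log(tol) + 6) / (2 * pi * a)) + 1L
  m <- 0:M
  # offsets at coincidence, self (d = 0, w = 0) excluded:
  d_other <- c(2 * a * m[-1], 2 * u0 + 2 * a * m, 2 * (m + 1) * a - 2 * u0,
               2 * (m + 1) * a)
  acc <- -log(pi / b) / (2 * pi * D)                       # from the self term
  acc <- acc - logE(0, 2 * v0, b) / (4 * pi * D)           # d = 0 companion
  acc <- acc - sum(logE(d_other, 0, b) + logE(d_other, 2 * v0, b)) /
    (4 * pi * D)
  g0 + acc
}

# ---- box, gamma0 + s > 0 (Ewald-split Yukawa image sum) --------------------

# The bare Yukawa image sum needs O(beta^-3) images for small beta, so the
# periodic screened Coulomb sum on the doubled torus is Ewald-split instead:
#   phi_Y(r) = [exp(-beta r) erfc(eta r - beta/2eta)
#               + exp(E) erfcx(eta r + beta/2eta)] / (8 pi r)   (real space)
#   + (1/V) sum_k exp(-(k^2+beta^2)/4eta^2)/(k^2+beta^2) cos(k.r)
# with E = -eta^2 r^2 - beta^2/4eta^2 (the overflow-safe form of
# exp(+beta r) erfc(eta r + beta/2eta)).  Folding the eight reflection images
# turns the reciprocal sum into a separable cosine series, exactly as for the
# pseudo-Green's function but including the k = 0 term.

erfcx_ <- function(x) {
  out <- numeric(length(x))
  lo <- x < 4
  out[lo] <- exp(x[lo]^2) * erfc_(x[lo])
  if (any(!lo)) {
    xi <- x[!lo]
    # asymptotic series, relative error < 1e-13 for x > 4 with 5 terms
    z <- 1 / (2 * xi^2)
    out[!lo] <- (1 - z * (1 - 3 * z * (1 - 5 * z * (1 - 7 * z * (1 - 9 * z))))) /
      (xi * sqrt(pi))
  }
  out
}

box_yukawa_setup <- function(size, beta, eta = 2.4, tol = 1e-14) {
  V <- 8 * prod(size)
  kmax <- 2 * eta * sqrt(-log(tol) + 4)
  nmax <- pmax(1L, ceiling(kmax * size / pi))
  grid <- as.matrix(expand.grid(0:nmax[1], 0:nmax[2], 0:nmax[3]))
  k2 <- (pi * grid[, 1] / size[1])^2 + (pi * grid[, 2] / size[2])^2 +
    (pi * grid[, 3] / size[3])^2
  w_raw <- exp(-(k2 + beta^2) / (4 * eta^2)) / (k2 + beta^2)
  keep <- w_raw > tol * 1e-3 * max(w_raw)
  grid <- grid[keep, , drop = FALSE]; k2 <- k2[keep]; w_raw <- w_raw[keep]
  mult <- 2^rowSums(grid > 0)
  list(eta = eta, V = V, n = grid, w = (8 / V) * mult * w_raw,
       rcut = 6.2 / eta)
}

box_yukawa_real <- function(r, beta, eta) {
  # Ewald real-space Yukawa kernel (times 8 pi r removed): value of phi * 8 pi r
  E <- -eta^2 * r^2 - beta^2 / (4 * eta^2)
  exp(-beta * r) * erfc_(eta * r - beta / (2 * eta)) +
    exp(E) * erfcx_(eta * r + beta / (2 * eta))
}

box_yukawa_real_dbeta <- function(r, beta, eta) {
  # d/dbeta of the real-space kernel times 8 pi (i.e. d(phi*8pi)/dbeta * 1/r
  # cancelled):  d phi_real/d beta = [exp(E) erfcx(v) - exp(-beta r) erfc(u)]/(8 pi)
  E <- -eta^2 * r^2 - beta^2 / (4 * eta^2)
  exp(E) * erfcx_(eta * r + beta / (2 * eta)) -
    exp(-beta * r) * erfc_(eta * r - beta / (2 * eta))
}

.box_cache <- new.env(parent = emptyenv())

box_yukawa_cached <- function(size, beta) {
  key <- paste0(paste(size, collapse = "_"), "@", format(beta, digits = 17))
  got <- get0(key, envir = .box_cache)
  if (is.null(got)) {
    got <- box_yukawa_setup(size, beta)
    assign(key, got, envir = .box_cache)
  }
  got
}

# separable cosine sum, chunked over field points to bound memory; cosines
# are evaluated once per unique mode index per dimension and gathered.
box_cos_sum <- function(x, size, n, cn, chunk = 4e6) {
  P <- nrow(x); K <- nrow(n)
  out <- numeric(P)
  u1 <- sort(unique(n[, 1])); u2 <- sort(unique(n[, 2]))
  u3 <- sort(unique(n[, 3]))
  i1 <- match(n[, 1], u1); i2 <- match(n[, 2], u2); i3 <- match(n[, 3], u3)
  step <- max(1L, floor(chunk / max(K, 1L)))
  i <- 1L
  while (i <= P) {
    j <- min(P, i + step - 1L)
    c1 <- cos(outer(x[i:j, 1], pi * u1 / size[1]))
    c2 <- cos(outer(x[i:j, 2], pi * u2 / size[2]))
    c3 <- cos(outer(x[i:j, 3], pi * u3 / size[3]))
    out[i:j] <- as.vector((c1[, i1, drop = FALSE] * c2[, i2, drop = FALSE] *
                             c3[, i3, drop = FALSE]) %*% cn)
    i <- j + 1L
  }
  out
}

box_yukawa_recip <- function(x, x0, size, yw) {
  x <- rbind(x)
  cn <- yw$w *
    cos(pi * yw$n[, 1] * x0[1] / size[1]) *
    cos(pi * yw$n[, 2] * x0[2] / size[2]) *
    cos(pi * yw$n[, 3] * x0[3] / size[3])
  box_cos_sum(x, size, yw$n, cn)
}

box_yukawa_recip_dbeta <- function(x, x0, size, yw, beta) {
  x <- rbind(x)
  k2 <- (pi * yw$n[, 1] / size[1])^2 + (pi * yw$n[, 2] / size[2])^2 +
    (pi * yw$n[, 3] / size[3])^2
  fac <- -2 * beta * (1 / (4 * yw$eta^2) + 1 / (k2 + beta^2))
  cn <- yw$w * fac *
    cos(pi * yw$n[, 1] * x0[1] / size[1]) *
    cos(pi * yw$n[, 2] * x0[2] / size[2]) *
    cos(pi * yw$n[, 3] * x0[3] / size[3])
  box_cos_sum(x, size, yw$n, cn)
}

greens_box3d_value <- function(x, x0, beta, D, size, tol) {
  x <- rbind(x)
  yw <- box_yukawa_cached(size, beta)
  img <- reflection_images(x0, size, yw$rcut)
  dmat <- image_distances(x, img)
  real <- rowSums(box_yukawa_real(dmat, beta, yw$eta) / dmat) / (8 * pi)
  (real + box_yukawa_recip(x, x0, size, yw)) / D
}

greens_box3d_regular <- function(x0, beta, D, size, tol) {
  yw <- box_yukawa_cached(size, beta)
  img <- reflection_images(x0, size, yw$rcut)
  self <- which(rowSums(abs(sweep(img, 2, x0))) < 1e-14)[1]
  d <- image_distances(rbind(x0), img[-self, , drop = FALSE])
  # central image: lim_{r->0} [phi_real(r) - 1/(4 pi r)]
  #   = -[beta erf(beta/2eta)
  #       + (2 eta/sqrt(pi)) exp(-beta^2/4eta^2)] / (4 pi)
  cen <- -(beta * erf_(beta / (2 * yw$eta)) +
             2 * yw$eta / sqrt(pi) * exp(-beta^2 / (4 * yw$eta^2))) / (4 * pi)
  real <- sum(box_yukawa_real(d, beta, yw$eta) / d) / (8 * pi) + cen
  (real + box_yukawa_recip(rbind(x0), x0, size, yw)) / D
}

greens_box3d_sderiv <- function(x, x0, beta, D, size, tol) {
  x <- rbind(x)
  yw <- box_yukawa_cached(size, beta)
  img <- reflection_images(x0, size, yw$rcut)
  dmat <- image_distances(x, img)
  real <- rowSums(box_yukawa_real_dbeta(dmat, beta, yw$eta)) / (8 * pi)
  (real + box_yukawa_recip_dbeta(x, x0, size, yw, beta)) / (2 * D^2 * beta)
}

greens_box3d_regular_sderiv <- function(x0, beta, D, size, tol) {
  yw <- box_yukawa_cached(size, beta)
  img <- reflection_images(x0, size, yw$rcut)
  self <- which(rowSums(abs(sweep(img, 2, x0))) < 1e-14)[1]
  d <- image_distances(rbind(x0), img[-self, , drop = FALSE])
  cen <- box_yukawa_real_dbeta(0, beta, yw$eta)  # finite: -erf(beta/2eta)*2...
  real <- (sum(box_yukawa_real_dbeta(d, beta, yw$eta)) + cen) / (8 * pi)
  (real + box_yukawa_recip_dbeta(rbind(x0), x0, size, yw, beta)) /
    (2 * D^2 * beta)
}

# ---- box, pseudo-Green's function (Ewald) ----------------------------------

# Periodic zero-mean Coulomb potential on the doubled torus (sides 2 L_i),
# folded over the eight reflection images of the source:
#   D G0(x,x') = sum_images erfc(eta d)/(4 pi d)
#                + (8/V) sum_{n >= 0, n != 0} 2^{m(n)} w_n
#                    prod_i cos(pi n_i x_i/L_i) prod_i cos(pi n_i x'_i/L_i)
#                - 8/(4 eta^2 V),
# w_n = exp(-|k|^2/(4 eta^2))/|k|^2 at k_i = pi n_i/L_i, V = 8 L1 L2 L3.
box_ewald_setup <- function(size, eta = 2.4, tol = 1e-14) {
  V <- 8 * prod(size)
  kmax <- 2 * eta * sqrt(-log(tol) + 4)
  nmax <- pmax(1L, ceiling(kmax * size / pi))
  grid <- as.matrix(expand.grid(0:nmax[1], 0:nmax[2], 0:nmax[3]))
  grid <- grid[rowSums(grid) > 0, , drop = FALSE]
  k2 <- (pi * grid[, 1] / size[1])^2 + (pi * grid[, 2] / size[2])^2 +
    (pi * grid[, 3] / size[3])^2
  keep <- exp(-k2 / (4 * eta^2)) > tol * 1e-3
  grid <- grid[keep, , drop = FALSE]; k2 <- k2[keep]
  mult <- 2^rowSums(grid > 0)
  w <- (8 / V) * mult * exp(-k2 / (4 * eta^2)) / k2
  list(eta = eta, V = V, n = grid, w = w,
       const = -8 / (4 * eta^2 * V),
       rcut = 6.2 / eta)
}

box_ewald_recip <- function(x, x0, size, ew) {
  # sum_n w_n prod cos(pi n_i x_i/L_i) prod cos(pi n_i x0_i/L_i)
  x <- rbind(x)
  cn <- ew$w *
    cos(pi * ew$n[, 1] * x0[1] / size[1]) *
    cos(pi * ew$n[, 2] * x0[2] / size[2]) *
    cos(pi * ew$n[, 3] * x0[3] / size[3])
  box_cos_sum(x, size, ew$n, cn)
}

greens_box3d_pseudo <- function(x, x0, D, size, ew) {
  x <- rbind(x)
  img <- reflection_images(x0, size, ew$rcut)
  dmat <- image_distances(x, img)
  real <- rowSums(erfc_(ew$eta * dmat) / dmat) / (4 * pi)
  (real + box_ewald_recip(x, x0, size, ew) + ew$const) / D
}

greens_box3d_pseudo_regular <- function(x0, D, size, ew) {
  img <- reflection_images(x0, size, ew$rcut)
  self <- which(rowSums(abs(sweep(img, 2, x0))) < 1e-14)[1]
  d <- image_distances(rbind(x0), img[-self, , drop = FALSE])
  real <- sum(erfc_(ew$eta * d) / d) / (4 * pi) - ew$eta / (2 * pi^1.5)
  (real + box_ewald_recip(rbind(x0), x0, size, ew) + ew$const) / D
}
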