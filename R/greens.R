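#' Green's function provider for a bulk domain
#'
#' Constructs an evaluator object for the Neumann Green's function
#' \eqn{G(x,x';s)} of the modified Helmholtz equation
#' \eqn{D\nabla^2 G - (\gamma_0+s)G = -\delta(x-x')} with reflecting outer
#' boundary and \eqn{\int_\Omega G\,dx = 1/(\gamma_0+s)}, its regular part
#' \eqn{R}, the zero-degradation pseudo-Green's function \eqn{G_0}
#' (satisfying \eqn{D\nabla^2 G_0 = 1/|\Omega| - \delta},
#' \eqn{\int_\Omega G_0\,dx = 0}) with regular part \eqn{R_0}, and the
#' Laplace-variable derivative \eqn{H = \partial_s G|_{s=0}} used by
#' accumulation times.
#'
#' Disk and sphere use addition-theorem Bessel series with reflection
#' coefficients; rectangle and box use exponentially convergent image sums of
#' the screened kernels; pseudo-Green's functions use closed forms (disk,
#' sphere), a resummed cosine-mode expansion (rectangle) and Ewald summation
#' (box).
#'
#' @param domain a [domain_spec()].
#' @param tol series/image truncation tolerance (dimensionless).
#' @param boundary_margin regular-part evaluations closer than this to the
#'   outer boundary are refused (the asymptotics assume compartments are
#'   O(1) from the boundary and the image singularities approach coincidence
#'   there).
#' @return an object of class `"greens_provider"`.
#' @export
make_greens_provider <- function(domain, tol = 1e-12, boundary_margin = 0.02) {
  if (!inherits(domain, "domain_spec"))
    stop("domain must be a domain_spec")
  if (!domain$kind %in% c("disk2d", "rect2d", "sphere3d", "box3d"))
    stop("geometry not implemented: ", domain$kind)
  ew <- if (domain$kind == "box3d") box_ewald_setup(domain$size) else NULL
  structure(list(domain = domain, tol = tol,
                 boundary_margin = boundary_margin, ewald = ew),
            class = "greens_provider")
}

#' @export
print.greens_provider <- function(x, ...) {
  cat(sprintf("<greens_provider> %s  D=%g  gamma0=%g  tol=%g\n",
              x$domain$kind, x$domain$D, x$domain$gamma0, x$tol))
  invisible(x)
}

check_point_in_domain <- function(provider, x, what = "point") {
  ok <- domain_contains(provider$domain, x, margin = -1e-12)
  if (!all(ok))
    stop(what, " outside the domain closure")
}

#' Evaluate the Green's function
#'
#' @param provider a [make_greens_provider()] object.
#' @param x evaluation point(s): vector of length d or a matrix with d
#'   columns.
#' @param x0 source point (length-d vector), distinct from every row of `x`.
#' @param s Laplace rate shift (\eqn{\ge 0}); the effective rate is
#'   \eqn{\gamma_0 + s}, which must be positive (use [greens_pseudo()] for
#'   the zero-degradation function).
#' @return numeric vector of \eqn{G(x, x_0; s)} values.
#' @export
greens_value <- function(provider, x, x0, s = 0) {
  x <- rbind(x); x0 <- as.numeric(x0)
  check_point_in_domain(provider, x, "evaluation point")
  check_point_in_domain(provider, rbind(x0), "source point")
  d2 <- rowSums(sweep(x, 2, x0)^2)
  if (any(d2 == 0))
    stop("coincident points: use regular part")
  g <- provider$domain$gamma0 + s
  if (g <= 0)
    stop("gamma0 + s must be positive; use greens_pseudo() for the ",
         "zero-degradation pseudo-Green's function")
  D <- provider$domain$D
  beta <- sqrt(g / D)
  switch(provider$domain$kind,
    disk2d   = greens_disk2d_value(x, x0, beta, D, provider$tol),
    rect2d   = greens_rect2d_value(x, x0, beta, D, provider$domain$size,
                                   provider$tol),
    sphere3d = greens_sphere3d_value(x, x0, beta, D, provider$tol),
    box3d    = greens_box3d_value(x, x0, beta, D, provider$domain$size,
                                  provider$tol))
}

#' Regular part of the Green's function at coincidence
#'
#' Returns \eqn{R(x_0, x_0; s)}, the finite remainder of \eqn{G} after
#' subtracting the free-space singularity (\eqn{-\log|x-x'|/2\pi D} in 2D,
#' \eqn{1/4\pi D|x-x'|} in 3D).
#'
#' @inheritParams greens_value
#' @param x0 strictly interior point, at least `boundary_margin` from the
#'   outer boundary.
#' @export
greens_regular <- function(provider, x0, s = 0) {
  x0 <- as.numeric(x0)
  check_point_in_domain(provider, rbind(x0), "source point")
  if (domain_boundary_distance(provider$domain, x0) < provider$boundary_margin)
    stop("regular part diverges near the boundary: point within ",
         provider$boundary_margin, " of the outer boundary refused")
  g <- provider$domain$gamma0 + s
  if (g <= 0)
    stop("gamma0 + s must be positive; use greens_pseudo_regular()")
  D <- provider$domain$D
  beta <- sqrt(g / D)
  switch(provider$domain$kind,
    disk2d   = greens_disk2d_regular(x0, beta, D, provider$tol),
    rect2d   = greens_rect2d_regular(x0, beta, D, provider$domain$size,
                                     provider$tol),
    sphere3d = greens_sphere3d_regular(x0, beta, D, provider$tol),
    box3d    = greens_box3d_regular(x0, beta, D, provider$domain$size,
                                    provider$tol))
}

#' Pseudo-Green's function (zero degradation)
#'
#' The generalised Neumann Green's function \eqn{G_0} of
#' \eqn{D\nabla^2 G_0 = 1/|\Omega| - \delta(x - x_0)} with reflecting outer
#' boundary and \eqn{\int_\Omega G_0 = 0}.
#'
#' @inheritParams greens_value
#' @export
greens_pseudo <- function(provider, x, x0) {
  x <- rbind(x); x0 <- as.numeric(x0)
  check_point_in_domain(provider, x, "evaluation point")
  check_point_in_domain(provider, rbind(x0), "source point")
  if (any(rowSums(sweep(x, 2, x0)^2) == 0))
    stop("coincident points: use regular part")
  D <- provider$domain$D
  switch(provider$domain$kind,
    disk2d   = greens_disk2d_pseudo(x, x0, D),
    rect2d   = greens_rect2d_pseudo(x, x0, D, provider$domain$size,
                                    provider$tol),
    sphere3d = greens_sphere3d_pseudo(x, x0, D),
    box3d    = greens_box3d_pseudo(x, x0, D, provider$domain$size,
                                   provider$ewald))
}

#' Regular part of the pseudo-Green's function at coincidence
#' @inheritParams greens_regular
#' @export
greens_pseudo_regular <- function(provider, x0) {
  x0 <- as.numeric(x0)
  check_point_in_domain(provider, rbind(x0), "source point")
  if (domain_boundary_distance(provider$domain, x0) < provider$boundary_margin)
    stop("regular part diverges near the boundary: point within ",
         provider$boundary_margin, " of the outer boundary refused")
  D <- provider$domain$D
  switch(provider$domain$kind,
    disk2d   = greens_disk2d_pseudo_regular(x0, D),
    rect2d   = greens_rect2d_pseudo_regular(x0, D, provider$domain$size,
                                            provider$tol),
    sphere3d = greens_sphere3d_pseudo_regular(x0, D),
    box3d    = greens_box3d_pseudo_regular(x0, D, provider$domain$size,
                                           provider$ewald))
}

#' Laplace-variable derivative of the Green's function at s = 0
#'
#' \eqn{H(x, x_0) = \partial_s G(x, x_0; s)|_{s=0}}, defined for
#' \eqn{\gamma_0 > 0} only (for \eqn{\gamma_0 = 0} the Green's function has a
#' simple pole at \eqn{s = 0}).  Coincident arguments return the
#' s-derivative of the regular part.  Rectangle and box differentiate the
#' image sums term-wise; disk and sphere use Richardson-extrapolated central
#' differences in \eqn{s}.
#'
#' @inheritParams greens_value
#' @export
greens_s_derivative <- function(provider, x, x0) {
  x <- rbind(x); x0 <- as.numeric(x0)
  if (provider$domain$gamma0 <= 0)
    stop("pole at s=0: accumulation-time branch unsupported for gamma0 = 0")
  D <- provider$domain$D
  g0 <- provider$domain$gamma0
  coincident <- rowSums(sweep(x, 2, x0)^2) == 0
  out <- numeric(nrow(x))
  beta <- sqrt(g0 / D)
  kind <- provider$domain$kind
  if (kind %in% c("rect2d", "box3d")) {
    if (any(!coincident)) {
      xs <- x[!coincident, , drop = FALSE]
      out[!coincident] <- if (kind == "rect2d")
        greens_rect2d_sderiv(xs, x0, beta, D, provider$domain$size,
                             provider$tol)
      else greens_box3d_sderiv(xs, x0, beta, D, provider$domain$size,
                               provider$tol)
    }
    if (any(coincident)) {
      out[coincident] <- if (kind == "rect2d")
        greens_rect2d_regular_sderiv(x0, beta, D, provider$domain$size,
                                     provider$tol)
      else greens_box3d_regular_sderiv(x0, beta, D, provider$domain$size,
                                       provider$tol)
    }
  } else {
    h <- 0.01 * g0
    fd <- function(f) {
      d1 <- (f(h) - f(-h)) / (2 * h)
      d2 <- (f(h / 2) - f(-h / 2)) / h
      (4 * d2 - d1) / 3
    }
    if (any(!coincident)) {
      xs <- x[!coincident, , drop = FALSE]
      out[!coincident] <- fd(function(s) greens_value(provider, xs, x0, s))
    }
    if (any(coincident))
      out[coincident] <- fd(function(s) greens_regular(provider, x0, s))
  }
  out
}

# s-derivative of the coincident regular part (diagonal of M'(0))
greens_regular_sderiv <- function(provider, x0) {
  greens_s_derivative(provider, rbind(as.numeric(x0)), x0)
}

# ---------------------------------------------------------------------------
# Normalisation quadrature: independent check of int_Omega G dx = 1/(gamma0+s)
# and int_Omega G0 dx = 0.  The free-space singularity is integrated in
# closed form; the remainder is smooth and handled by Gauss-Legendre rules
# (polar around the source in 2D, axisymmetric spherical rule in the ball,
# tensor rule plus the closed-form box Newtonian potential in the box).

# int over [0,a]x[0,b]x[0,c] of 1/sqrt(x^2+y^2+z^2)
corner_inv_r <- function(a, b, c) {
  if (a == 0 || b == 0 || c == 0) {
    # at most a 2D integral remains only when one side collapses; the
    # integral itself tends to 0 with the volume only if two sides collapse.
    if ((a == 0) + (b == 0) + (c == 0) >= 2) return(0)
    # reduce: dimension with zero extent contributes nothing to the volume
    return(0)
  }
  r <- sqrt(a^2 + b^2 + c^2)
  b * c * asinh(a / sqrt(b^2 + c^2)) +
    a * c * asinh(b / sqrt(a^2 + c^2)) +
    a * b * asinh(c / sqrt(a^2 + b^2)) -
    a^2 / 2 * atan(b * c / (a * r)) -
    b^2 / 2 * atan(a * c / (b * r)) -
    c^2 / 2 * atan(a * b / (c * r))
}

newton_box_integral <- function(p, size) {
  # int_box 1/|x - p| dx for p strictly inside the box [0,size]
  acc <- 0
  for (sx in c(p[1], size[1] - p[1]))
    for (sy in c(p[2], size[2] - p[2]))
      for (sz in c(p[3], size[3] - p[3]))
        acc <- acc + corner_inv_r(sx, sy, sz)
  acc
}

# angular segment boundaries for the 2D polar rule (corner splits for rect)
polar_segments <- function(domain, x0) {
  if (domain$kind == "disk2d") return(c(0, 2 * pi))
  cs <- rbind(c(0, 0), c(domain$size[1], 0), domain$size, c(0, domain$size[2]))
  ang <- sort(atan2(cs[, 2] - x0[2], cs[, 1] - x0[1]))
  c(ang, ang[1] + 2 * pi)
}

#' Quadrature check of the Green's function normalisation
#'
#' Independently integrates the Green's function (or pseudo-Green's function)
#' over the domain and returns the integral together with its analytic target
#' (\eqn{1/(\gamma_0+s)}, or 0 for the pseudo function).
#'
#' @inheritParams greens_value
#' @param pseudo integrate the pseudo-Green's function instead.
#' @param n_r,n_ang quadrature resolution (radial / angular).
#' @return list with `integral`, `target`, `residual`.
#' @export
greens_normalization <- function(provider, x0, s = 0, pseudo = FALSE,
                                 n_r = 64, n_ang = 128) {
  x0 <- as.numeric(x0)
  dom <- provider$domain
  D <- dom$D
  evalG <- if (pseudo) function(x) greens_pseudo(provider, x, x0)
           else function(x) greens_value(provider, x, x0, s)
  target <- if (pseudo) 0 else 1 / (dom$gamma0 + s)

  if (dom$dim == 2L) {
    segs <- polar_segments(dom, x0)
    gr <- gauss_legendre(n_r, 0, 1)
    total <- 0
    for (i in seq_len(length(segs) - 1L)) {
      ga <- gauss_legendre(max(16, round(n_ang * (segs[i + 1] - segs[i]) /
                                           (2 * pi))), segs[i], segs[i + 1])
      for (j in seq_along(ga$nodes)) {
        th <- ga$nodes[j]
        u <- c(cos(th), sin(th))
        rmax <- domain_ray_length(dom, x0, u)
        r <- gr$nodes * rmax
        w <- gr$weights * rmax
        pts <- cbind(x0[1] + r * u[1], x0[2] + r * u[2])
        fs <- evalG(pts) + log(r) / (2 * pi * D)   # smooth remainder
        rad <- sum(w * r * fs) -
          (rmax^2 * (2 * log(rmax) - 1) / 4) / (2 * pi * D)
        total <- total + ga$weights[j] * rad
      }
    }
    return(list(integral = total, target = target,
                residual = total - target))
  }

  if (dom$kind == "sphere3d") {
    # axisymmetric about the x0 axis
    r0 <- sqrt(sum(x0^2))
    axis <- if (r0 > 0) x0 / r0 else c(0, 0, 1)
    # orthonormal frame
    tmp <- if (abs(axis[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    e1 <- tmp - sum(tmp * axis) * axis; e1 <- e1 / sqrt(sum(e1^2))
    ga <- gauss_legendre(n_ang, -1, 1)   # in cos(alpha)
    gr <- gauss_legendre(n_r, 0, 1)
    total <- 0
    for (j in seq_along(ga$nodes)) {
      ca <- ga$nodes[j]; sa <- sqrt(1 - ca^2)
      u <- ca * axis + sa * e1
      rmax <- domain_ray_length(dom, x0, u)
      r <- gr$nodes * rmax
      w <- gr$weights * rmax
      pts <- cbind(x0[1] + r * u[1], x0[2] + r * u[2], x0[3] + r * u[3])
      total <- total + 2 * pi * ga$weights[j] * sum(w * r^2 * evalG(pts))
    }
    return(list(integral = total, target = target,
                residual = total - target))
  }

  # box3d: tensor rule on the smooth remainder + closed-form 1/r integral
  gx <- gauss_legendre(36, 0, dom$size[1])
  gy <- gauss_legendre(36, 0, dom$size[2])
  gz <- gauss_legendre(36, 0, dom$size[3])
  pts <- as.matrix(expand.grid(gx$nodes, gy$nodes, gz$nodes))
  wts <- as.vector(outer(outer(gx$weights, gy$weights), gz$weights))
  rr <- sqrt(rowSums(sweep(pts, 2, x0)^2))
  fs <- evalG(pts) - 1 / (4 * pi * D * rr)
  total <- sum(wts * fs) + newton_box_integral(x0, dom$size) / (4 * pi * D)
  list(integral = total, target = target, residual = total - target)
}

#' Diagnostic table of Green's-function identities
#'
#' For a set of interior source points, reports the normalisation residuals
#' of \eqn{G} and \eqn{G_0}, the symmetry residual
#' \eqn{G(x,x') - G(x',x)} at a paired point, and the boundary Neumann
#' residual estimated by one-sided finite differences along the outward
#' normal.
#'
#' @inheritParams greens_value
#' @param points matrix of interior source points (rows).
#' @return a data.frame, one row per source point.
#' @export
greens_check <- function(provider, points, s = 0) {
  points <- rbind(points)
  dom <- provider$domain
  out <- data.frame(norm_G = NA_real_, norm_G0 = NA_real_,
                    symmetry = NA_real_, neumann = NA_real_)
  out <- out[rep(1, nrow(points)), , drop = FALSE]
  rownames(out) <- NULL
  for (i in seq_len(nrow(points))) {
    x0 <- points[i, ]
    if (dom$gamma0 + s > 0) {
      nr <- greens_normalization(provider, x0, s)
      out$norm_G[i] <- nr$residual * (dom$gamma0 + s)  # relative
    }
    n0 <- greens_normalization(provider, x0, pseudo = TRUE)
    out$norm_G0[i] <- n0$residual
    # symmetry against a shifted partner point
    x1 <- x0 * 0.5 + 0.12 * seq_len(dom$dim) / dom$dim
    if (dom$kind %in% c("rect2d", "box3d")) x1 <- pmin(pmax(x1, 0.1),
                                                       dom$size - 0.1)
    g12 <- if (dom$gamma0 + s > 0) greens_value(provider, rbind(x1), x0, s)
           else greens_pseudo(provider, rbind(x1), x0)
    g21 <- if (dom$gamma0 + s > 0) greens_value(provider, rbind(x0), x1, s)
           else greens_pseudo(provider, rbind(x0), x1)
    out$symmetry[i] <- g12 - g21
    # Neumann residual at a boundary point
    bp_dir <- switch(dom$kind,
      disk2d = , sphere3d = {
        u <- x0 / max(sqrt(sum(x0^2)), 1e-12)
        list(p = u, n = u)
      },
      rect2d = , box3d = {
        p <- x0; p[1] <- dom$size[1]
        n <- numeric(dom$dim); n[1] <- 1
        list(p = p, n = n)
      })
    h <- 1e-4
    pts <- rbind(bp_dir$p - h * bp_dir$n, bp_dir$p - 2 * h * bp_dir$n)
    gv <- if (dom$gamma0 + s > 0) greens_value(provider, pts, x0, s)
          else greens_pseudo(provider, pts, x0)
    g_b <- if (dom$gamma0 + s > 0)
      greens_value(provider, rbind(bp_dir$p * (1 - 1e-12)), x0, s)
    else greens_pseudo(provider, rbind(bp_dir$p * (1 - 1e-12)), x0)
    # one-sided second-order derivative estimate along the inward offset
    out$neumann[i] <- (3 * g_b - 4 * gv[1] + gv[2]) / (2 * h)
  }
  out
}
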