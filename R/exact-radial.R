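# Exact radial reference solutions: one concentric compartment in the unit
# disk/sphere, modified Helmholtz bulk, Robin condition at r = eps*ell
# (reactivity kappa/eps, as in the unscaled problem) and no-flux at r = 1.
# These are the closed-form oracles certifying both the asymptotic solvers
# and the finite-difference Robin implementation.

#' Exact annulus solution (2D, single concentric compartment)
#'
#' Solves \eqn{D u'' + D u'/r - \gamma_0 u = 0} on \eqn{(\epsilon\ell, 1)}
#' with \eqn{D u'(\epsilon\ell) = (\kappa/\epsilon)(u(\epsilon\ell) - c_0)}
#' and \eqn{u'(1) = 0}.  The no-flux combination
#' \eqn{I_0(\beta r) + (I_1(\beta)/K_1(\beta)) K_0(\beta r)} satisfies the
#' outer condition identically; the Robin condition fixes the amplitude.
#'
#' @param ell scaled compartment radius; physical radius is `eps * ell`.
#' @param eps the small parameter.
#' @param kappa reactivity (post-rescaling; `Inf` for Dirichlet).
#' @param c0 boundary level.
#' @param D,gamma0 bulk diffusivity and degradation (`gamma0 > 0`).
#' @return list with the evaluator `u(r)`, its derivative `du(r)`, and the
#'   Robin residual at the inner boundary.
#' @export
exact_annulus_2d <- function(ell, eps, kappa, c0, D, gamma0) {
  if (gamma0 <= 0) stop("gamma0 > 0 required")
  if (eps * ell <= 0 || eps * ell >= 1) stop("0 < eps*ell < 1 required")
  beta <- sqrt(gamma0 / D)
  a <- eps * ell
  cc <- besselI(beta, 1) / besselK(beta, 1)
  f <- function(r) besselI(beta * r, 0) + cc * besselK(beta * r, 0)
  df <- function(r) beta * (besselI(beta * r, 1) - cc * besselK(beta * r, 1))
  # Robin: D A f'(a) = (kappa/eps) (A f(a) - c0)
  A <- if (is.finite(kappa)) {
    k_eff <- kappa / eps
    (-k_eff * c0) / (D * df(a) - k_eff * f(a))
  } else c0 / f(a)
  res <- if (is.finite(kappa))
    D * A * df(a) - (kappa / eps) * (A * f(a) - c0)
  else A * f(a) - c0
  list(u = function(r) A * f(r), du = function(r) A * df(r),
       A = A, robin_residual = res)
}

#' Exact shell solution (3D, single concentric compartment)
#'
#' As [exact_annulus_2d()] but in the unit ball, with fundamental solutions
#' \eqn{e^{\pm\beta r}/r}.
#' @inheritParams exact_annulus_2d
#' @export
exact_shell_3d <- function(ell, eps, kappa, c0, D, gamma0) {
  if (gamma0 < 0) stop("gamma0 >= 0 required")
  if (eps * ell <= 0 || eps * ell >= 1) stop("0 < eps*ell < 1 required")
  a <- eps * ell
  if (gamma0 == 0) {
    # harmonic branch: u = A + B/r with no-flux at 1 forcing B = 0; the
    # Robin condition then gives the uniform state u = c0
    return(list(u = function(r) rep(c0, length(r)),
                du = function(r) rep(0, length(r)),
                robin_residual = 0))
  }
  beta <- sqrt(gamma0 / D)
  # basis: f1 = exp(-beta r)/r, f2 = exp(beta r)/r (scaled to avoid overflow)
  f1 <- function(r) exp(-beta * r) / r
  f2 <- function(r) exp(beta * (r - 1)) / r
  df1 <- function(r) -exp(-beta * r) * (beta * r + 1) / r^2
  df2 <- function(r) exp(beta * (r - 1)) * (beta * r - 1) / r^2
  # no-flux at r=1:  c1 df1(1) + c2 df2(1) = 0
  c2 <- -df1(1); c1 <- df2(1)
  f <- function(r) c1 * f1(r) + c2 * f2(r)
  df <- function(r) c1 * df1(r) + c2 * df2(r)
  A <- if (is.finite(kappa)) {
    k_eff <- kappa / eps
    (-k_eff * c0) / (D * df(a) - k_eff * f(a))
  } else c0 / f(a)
  res <- if (is.finite(kappa))
    D * A * df(a) - (kappa / eps) * (A * f(a) - c0)
  else A * f(a) - c0
  list(u = function(r) A * f(r), du = function(r) A * df(r),
       A = A, robin_residual = res)
}

#' Electrostatic capacitance of simple trap shapes
#'
#' The 3D asymptotics extend to non-spherical compartments by replacing the
#' scaled radius \eqn{\ell_j} with the shape capacitance \eqn{C_j} (units of
#' length): sphere \eqn{a}; hemisphere \eqn{2a(1-1/\sqrt3)}; prolate
#' spheroid \eqn{\sqrt{a^2-b^2}/\cosh^{-1}(a/b)}; oblate spheroid
#' \eqn{\sqrt{a^2-b^2}/\cos^{-1}(b/a)}.  (The oblate formula is sometimes
#' printed with \eqn{\cosh^{-1}(b/a)}, whose real branch is undefined for
#' \eqn{b<a}; the standard electrostatics result with \eqn{\cos^{-1}} is
#' used here.)
#'
#' @param shape one of `"sphere"`, `"hemisphere"`, `"prolate"`, `"oblate"`.
#' @param a semi-major axis (or radius).
#' @param b semi-minor axis (spheroids only), `b <= a`.
#' @export
capacitance <- function(shape = c("sphere", "hemisphere", "prolate", "oblate"),
                        a, b = NULL) {
  shape <- match.arg(shape)
  if (a <= 0) stop("a must be positive")
  if (shape %in% c("prolate", "oblate")) {
    if (is.null(b) || b <= 0) stop("spheroids need a positive semi-minor axis b")
    if (b > a) stop("spheroids require a >= b > 0")
    if (b == a) return(a)  # sphere limit
  }
  switch(shape,
    sphere = a,
    hemisphere = 2 * a * (1 - 1 / sqrt(3)),
    prolate = sqrt(a^2 - b^2) / acosh(a / b),
    oblate = sqrt(a^2 - b^2) / acos(b / a))
}

#' Generate a random well-separated compartment configuration
#'
#' Rejection-samples `n` compartment centres inside the domain with all
#' pairwise and centre-to-boundary distances at least
#' `separation_factor * epsilon`; seeded and reproducible.
#'
#' @param seed integer seed.
#' @param n number of compartments.
#' @param domain a [domain_spec()].
#' @param epsilon small parameter.
#' @param separation_factor minimum separation in units of epsilon
#'   (default 10).
#' @param ell_range range for scaled radii (the maximum is rescaled to 1, as
#'   the definition of epsilon requires).
#' @param kappa_range,c0_range parameter ranges for reactivity and model-I
#'   boundary levels.
#' @param model compartment model tag for all compartments.
#' @param budget rejection-sampling attempt budget.
#' @export
generate_configuration <- function(seed, n, domain, epsilon,
                                   separation_factor = 10,
                                   ell_range = c(0.6, 1),
                                   kappa_range = c(0.5, 2),
                                   c0_range = c(0.5, 1.5),
                                   model = "I", budget = 5000L) {
  stopifnot(n >= 1)
  rng <- local({
    set.seed(seed)
    NULL
  })
  sep <- separation_factor * epsilon
  draw_point <- function() {
    switch(domain$kind,
      disk2d = {
        repeat {
          p <- stats::runif(2, -1, 1)
          if (sum(p^2) < 1) return(p)
        }
      },
      sphere3d = {
        repeat {
          p <- stats::runif(3, -1, 1)
          if (sum(p^2) < 1) return(p)
        }
      },
      rect2d = stats::runif(2, 0, 1) * domain$size,
      box3d = stats::runif(3, 0, 1) * domain$size)
  }
  centres <- matrix(0, 0, domain$dim)
  tries <- 0L
  while (nrow(centres) < n) {
    tries <- tries + 1L
    if (tries > budget)
      stop(sprintf("cannot place %d compartments at separation %.3g", n, sep))
    p <- draw_point()
    if (domain_boundary_distance(domain, p) < sep) next
    if (nrow(centres) &&
        min(sqrt(rowSums(sweep(centres, 2, p)^2))) < sep) next
    centres <- rbind(centres, p)
  }
  ells <- stats::runif(n, ell_range[1], ell_range[2])
  ells <- ells / max(ells)
  kappas <- stats::runif(n, kappa_range[1], kappa_range[2])
  c0s <- stats::runif(n, c0_range[1], c0_range[2])
  comps <- lapply(seq_len(n), function(j)
    compartment(centres[j, ], ell = ells[j], kappa = kappas[j],
                model = model, c0 = c0s[j]))
  compartment_configuration(domain, epsilon, comps, separation = sep)
}
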