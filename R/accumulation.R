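# Accumulation times of diffusive relaxation (gamma0 > 0 only).
#
# With Z(x,t) = 1 - u(x,t)/u(x) the accumulation time is T(x) = int_0^inf
# |Z| dt = -+ lim_{s->0} d/ds [ s u~(x,s) ] / u(x), computed in Laplace
# space where the singularly perturbed problem maps onto the steady-state
# machinery under gamma0 -> gamma0 + s, c -> c/s, plus the initial-data
# source Gamma0(x,s) = int G(x,x';s) u0(x') dx'.
#
# Sign conventions are explicit: "fill" (zero initial data, compartments
# are sources, u rises to u(x), T = -(1/u) d/ds[s u~]) and "drain"
# (bulk initial data above steady state, compartments are sinks,
# T = +(1/u) d/ds[s u~]).

#' Closed-form 1D accumulation time
#'
#' Semi-infinite interval with constant flux at the origin:
#' \eqn{T(x) = (1/2\gamma_0)(1 + \sqrt{\gamma_0/D}\,x)}.
#' @param x position(s), >= 0.
#' @param D diffusivity.
#' @param gamma0 degradation rate (> 0).
#' @export
accumulation_time_1d <- function(x, D, gamma0) {
  if (gamma0 <= 0) stop("gamma0 > 0 required")
  if (any(x < 0)) stop("x must be non-negative")
  (1 + sqrt(gamma0 / D) * x) / (2 * gamma0)
}

#' 1D accumulation time via the generic Laplace machinery
#'
#' Solves the finite-interval Laplace-space problem
#' \eqn{D\tilde u'' - (\gamma_0+s)\tilde u = 0},
#' \eqn{-D\tilde u'(0) = J_0/s}, \eqn{\tilde u'(L) = 0} and evaluates
#' \eqn{T(x) = -g'(0)/g(0)} with
#' \eqn{g(s) = \cosh(\beta_s (L-x)) / (\beta_s \sinh(\beta_s L))}
#' (analytic s-derivative).  Converges to [accumulation_time_1d()] as
#' \eqn{L \to \infty}.
#' @inheritParams accumulation_time_1d
#' @param L interval length.
#' @export
accumulation_time_1d_laplace <- function(x, D, gamma0, L) {
  if (gamma0 <= 0) stop("gamma0 > 0 required")
  beta <- sqrt(gamma0 / D)
  # d/ds log g = (1/(2 D beta)) [ (L-x) tanh(beta (L-x)) - 1/beta
  #                               - L coth(beta L) ]
  dlog <- ((L - x) * tanh(beta * (L - x)) - 1 / beta -
             L / tanh(beta * L)) / (2 * D * beta)
  -dlog
}

#' 1D accumulation time from a truncated eigenfunction sum
#'
#' Independent spectral route on `[0, L]`: Neumann cosine eigenfunctions
#' with eigenvalues \eqn{\lambda_n = \gamma_0 + n^2\pi^2 D/L^2}; the
#' expansion coefficients of the steady state are computed in closed form.
#' @inheritParams accumulation_time_1d_laplace
#' @param n_modes number of eigenmodes.
#' @export
accumulation_time_1d_eigen <- function(x, D, gamma0, L, n_modes = 4000L) {
  beta <- sqrt(gamma0 / D)
  u <- function(x) cosh(beta * (L - x)) / (D * beta * sinh(beta * L))
  # <u, phi_n> with phi_n = A_n cos(n pi (L-x)/L):
  # int_0^L cosh(beta y) cos(n pi y / L) dy
  #   = beta sinh(beta L) (-1)^n / (beta^2 + (n pi/L)^2)
  n <- 0:n_modes
  An <- ifelse(n == 0, sqrt(1 / L), sqrt(2 / L))
  lam <- gamma0 + n^2 * pi^2 * D / L^2
  inner <- beta * sinh(beta * L) * (-1)^n / (beta^2 + (n * pi / L)^2)
  cn <- -An * inner / (D * beta * sinh(beta * L))   # c_n = -<u, phi_n>
  phin_x <- An * cos(n * pi * (L - x) / L)
  -sum(cn * phin_x / lam) / u(x)
}

#' Compactly supported radial initial bump
#'
#' \eqn{u_0(x) = m\,\psi(|x-x_c|/w)/\int\psi} with the standard mollifier
#' \eqn{\psi(t) = \exp(-1/(1-t^2))} on \eqn{t < 1}; total mass `mass`.
#' @param centre bump centre.
#' @param width support radius.
#' @param mass total integral of u0.
#' @param dim spatial dimension (2 or 3).
#' @export
initial_bump <- function(centre, width, mass = 1, dim = 2) {
  raw <- function(t) ifelse(t < 1, exp(-1 / pmax(1 - t^2, 1e-300)), 0)
  # normalise by quadrature of the radial profile
  gq <- gauss_legendre(80, 0, 1)
  tot <- if (dim == 2) 2 * pi * width^2 * sum(gq$weights * gq$nodes *
                                                raw(gq$nodes))
         else 4 * pi * width^3 * sum(gq$weights * gq$nodes^2 * raw(gq$nodes))
  f <- function(x) {
    x <- rbind(x)
    t <- sqrt(rowSums(sweep(x, 2, centre)^2)) / width
    mass * raw(t) / tot
  }
  structure(list(u0 = f, centre = centre, width = width, mass = mass,
                 dim = dim),
            class = "initial_condition")
}

#' Green's-weighted integral of the initial data
#'
#' \eqn{\Gamma_0(x, s) = \int_\Omega G(x, x'; s) u_0(x')\,dx'} by polar
#' quadrature over the bump support.  The evaluation point must lie outside
#' the support (the compartments must too).
#' @param provider a Green's provider with \eqn{\gamma_0 > 0}.
#' @param u0 an [initial_bump()].
#' @param x evaluation point(s).
#' @param s Laplace rate.
#' @param n_r,n_ang quadrature resolution over the support.
#' @export
gamma0_source_field <- function(provider, u0, x, s = 0, n_r = 32,
                                n_ang = 48) {
  if (provider$domain$gamma0 <= 0) stop("gamma0 > 0 required")
  x <- rbind(x)
  if (u0$mass == 0) return(numeric(nrow(x)))
  dim <- provider$domain$dim
  gr <- gauss_legendre(n_r, 0, u0$width)
  out <- numeric(nrow(x))
  if (dim == 2) {
    th <- (seq_len(n_ang) - 0.5) * 2 * pi / n_ang
    wth <- rep(2 * pi / n_ang, n_ang)
    pts <- cbind(u0$centre[1] + outer(gr$nodes, cos(th)),
                 u0$centre[2] + outer(gr$nodes, sin(th)))
    pts <- cbind(as.vector(pts[, seq_len(n_ang)]),
                 as.vector(pts[, n_ang + seq_len(n_ang)]))
    wq <- as.vector(outer(gr$weights * gr$nodes, wth))
  } else {
    gc <- gauss_legendre(n_ang, -1, 1)
    nphi <- n_ang
    ph <- (seq_len(nphi) - 0.5) * 2 * pi / nphi
    dirs <- NULL; wd <- NULL
    for (i in seq_along(gc$nodes)) {
      ca <- gc$nodes[i]; sa <- sqrt(1 - ca^2)
      dirs <- rbind(dirs, cbind(sa * cos(ph), sa * sin(ph), rep(ca, nphi)))
      wd <- c(wd, rep(gc$weights[i] * 2 * pi / nphi, nphi))
    }
    pts <- sweep(dirs[rep(seq_len(nrow(dirs)), each = n_r), ] *
                   rep(gr$nodes, nrow(dirs)), 2, u0$centre, `+`)
    wq <- rep(wd, each = n_r) * rep(gr$weights * gr$nodes^2, nrow(dirs))
  }
  vals <- u0$u0(pts)
  for (i in seq_len(nrow(x))) {
    G <- greens_value(provider, pts, x[i, ], s)
    out[i] <- sum(wq * vals * G)
  }
  out
}

check_u0_support <- function(config, u0) {
  if (u0$mass == 0) return(invisible())
  ells <- config_field(config, "ell")
  d <- sqrt(rowSums(sweep(config$centres, 2, u0$centre)^2))
  if (any(d < u0$width + config$epsilon * ells))
    stop("initial-condition support overlaps a compartment")
  invisible()
}

# shared matrix pieces of the Laplace-space matching at s = 0
accumulation_matrices_2d <- function(config, provider) {
  D <- config$domain$D
  nu <- config$nu
  mats <- assemble_matrix_2d(config, provider, s = 0)
  N <- nrow(mats$M)
  X <- config$centres
  # M'(0): 2 pi D H entries (s-derivative of R on the diagonal)
  Mp <- matrix(0, N, N)
  for (j in seq_len(N)) {
    Hcol <- greens_s_derivative(provider, X, X[j, ])
    Mp[, j] <- 2 * pi * D * Hcol
  }
  E <- solve(diag(N) + nu * mats$M)
  Theta <- E %*% Mp %*% E
  list(M = mats$M, Mp = Mp, E = E, Theta = Theta)
}

#' 2D accumulation time for a singularly perturbed domain
#'
#' Implements the full Laplace-space expression: with
#' \eqn{A_j = \lim s\tilde A_j(s)} the steady-state coefficients,
#' \eqn{A_j' = \nu(\Theta c_0)_j + ((I+\nu M)^{-1}\Gamma_0(x_\cdot,0))_j},
#' \eqn{\Theta = (I+\nu M)^{-1} M'(0) (I+\nu M)^{-1}}, the relaxation
#' numerator is
#' \eqn{d/ds[s\tilde u] = \Gamma_0(x,0) - 2\pi\nu D\sum_k (A_k' G + A_k H)}
#' and \eqn{T = \pm\, d/ds[s\tilde u]/u(x)} (sign by `direction`).  The
#' leading-order simplification
#' \eqn{T \approx \Gamma_0 / (2\pi\nu D \sum_k G c_{k,0})} is returned for
#' comparison.
#'
#' @inheritParams solve_model1_2d
#' @param u0 an [initial_bump()] (may have mass 0 for the fill convention).
#' @param probes matrix of probe points.
#' @param direction `"drain"` (bulk initial data, compartment sinks) or
#'   `"fill"` (zero initial data, compartment sources).
#' @return object with `T`, `T_leading`, per-probe steady values, and the
#'   intermediate `A`, `Ap`, `Theta`.
#' @export
accumulation_time_2d <- function(config, provider, u0, probes,
                                 direction = c("drain", "fill")) {
  direction <- match.arg(direction)
  if (config$domain$gamma0 <= 0)
    stop("accumulation times require gamma0 > 0 (pole at s = 0 otherwise)")
  probes <- rbind(probes)
  D <- config$domain$D; nu <- config$nu
  X <- config$centres
  check_u0_support(config, u0)
  sol <- solve_model1_2d(config, provider)
  A <- sol$A
  am <- accumulation_matrices_2d(config, provider)
  G0_at_centres <- if (u0$mass > 0)
    gamma0_source_field(provider, u0, X) else numeric(nrow(X))
  Ap <- nu * as.vector(am$Theta %*% sol$c_eff) +
    as.vector(am$E %*% G0_at_centres)
  Tout <- numeric(nrow(probes)); Tlead <- numeric(nrow(probes))
  u_probe <- numeric(nrow(probes))
  for (i in seq_len(nrow(probes))) {
    xp <- probes[i, ]
    Gv <- greens_value(provider, X, xp)   # symmetric arguments
    Hv <- greens_s_derivative(provider, X, xp)
    G0x <- if (u0$mass > 0) gamma0_source_field(provider, u0, rbind(xp))
           else 0
    u_x <- -2 * pi * nu * D * sum(A * Gv)
    num <- G0x - 2 * pi * nu * D * sum(Ap * Gv + A * Hv)
    if (abs(u_x) < 1e-12 * max(abs(sol$c_eff), 1)) {
      Tout[i] <- NA_real_; Tlead[i] <- NA_real_
      warning("undefined accumulation time: steady state ~ 0 at probe")
      next
    }
    Tval <- num / u_x
    if (direction == "fill") Tval <- -Tval
    Tout[i] <- Tval
    Tlead[i] <- if (u0$mass > 0)
      G0x / (2 * pi * nu * D * sum(Gv * sol$c_eff)) else NA_real_
    u_probe[i] <- u_x
  }
  structure(list(T = Tout, T_leading = Tlead, u = u_probe, A = A, Ap = Ap,
                 Theta = am$Theta, direction = direction, probes = probes),
            class = "accumulation_result")
}

#' 3D accumulation time
#'
#' The 3D analogue: with trap strengths \eqn{\Lambda_k},
#' \eqn{d/ds[s\tilde u] = \Gamma_0(x,0) + 4\pi\epsilon D \sum_k \Lambda_k
#' \{c_{k,0} H(x,x_k) - \Gamma_0(x_k,0) G(x,x_k)\}} and the steady state
#' \eqn{u = 4\pi\epsilon D\sum_k \Lambda_k c_{k,0} G(x,x_k)} at leading
#' order.
#' @inheritParams accumulation_time_2d
#' @export
accumulation_time_3d <- function(config, provider, u0, probes,
                                 direction = c("drain", "fill")) {
  direction <- match.arg(direction)
  if (config$domain$gamma0 <= 0)
    stop("accumulation times require gamma0 > 0 (pole at s = 0 otherwise)")
  probes <- rbind(probes)
  D <- config$domain$D; eps <- config$epsilon
  X <- config$centres
  sol <- solve_model1_3d(config, provider)
  Lam <- sol$Lambda; c0 <- sol$c_eff
  G0_at_centres <- if (u0$mass > 0)
    gamma0_source_field(provider, u0, X) else numeric(nrow(X))
  Tout <- numeric(nrow(probes)); Tlead <- numeric(nrow(probes))
  for (i in seq_len(nrow(probes))) {
    xp <- probes[i, ]
    Gv <- greens_value(provider, X, xp)
    Hv <- greens_s_derivative(provider, X, xp)
    G0x <- if (u0$mass > 0) gamma0_source_field(provider, u0, rbind(xp))
           else 0
    u_x <- 4 * pi * eps * D * sum(Lam * c0 * Gv)
    num <- G0x + 4 * pi * eps * D *
      sum(Lam * (c0 * Hv - G0_at_centres * Gv))
    if (abs(u_x) < 1e-14) {
      Tout[i] <- NA_real_; Tlead[i] <- NA_real_
      warning("undefined accumulation time: steady state ~ 0 at probe")
      next
    }
    Tval <- num / u_x
    if (direction == "fill") Tval <- -Tval
    Tout[i] <- Tval
    Tlead[i] <- if (u0$mass > 0) G0x / u_x else NA_real_
  }
  structure(list(T = Tout, T_leading = Tlead, direction = direction,
                 probes = probes),
            class = "accumulation_result")
}
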