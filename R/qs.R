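# Reduction of the 2D quorum-sensing PDE-ODE model (model III with fast bulk
# diffusion D = D0/nu) to a finite ODE system for the mean bulk
# concentration ubar and the intracellular states w_j:
#   d ubar/dt = -gamma0 ubar - (2 pi D0/|Omega|) sum_j A_j(t)
#   |U_j| dw_{j,a}/dt = fhat_a(w_j) + 2 pi D0 delta_{a,0} A_j(t)
# with the quasi-static matching coefficients A_j(t) solving
#   [1 + D0/(kappa_j l_j)] A_j + 2 pi D0 nu sum_k Gcal0_jk A_k
#     = ubar(t) - w_{j,0}(t).
# For identical cells this is A = (kappa l/(kappa l + D0)) W (ubar - w_.0)
# with W = (I + nu Q)^{-1}, Q = (2 pi kappa l D0/(kappa l + D0)) Gcal0.
# (The 2 pi factor follows from the matching equation; some statements of Q
# absorb it into the Green's matrix.)  W -> I as D0 -> infinity recovers the
# well-mixed model with kappa_hat = 2 pi N kappa l / |U|.

#' Build the reduced quorum-sensing ODE system
#'
#' @param config 2D [compartment_configuration()], all compartments model
#'   III.
#' @param kinetics a [make_kinetics()] object (intensive rates).
#' @param D0 scaled bulk diffusivity (the physical diffusivity is
#'   \eqn{D_0/\nu}).
#' @return object of class `"reduced_qs"` with the coupling solve, the
#'   identical-cell `W` matrix when applicable, and the well-mixed constants
#'   `kappa_hat`, `alpha`.
#' @export
build_reduced_system <- function(config, kinetics, D0) {
  if (config$domain$dim != 2L) stop("2D configuration required")
  N <- length(config$compartments)
  nu <- config$nu
  eps <- config$epsilon
  ell <- config_field(config, "ell")
  kap <- config_field(config, "kappa")
  if (any(!is.finite(kap)))
    stop("the reduction assumes finite exchange reactivity kappa")
  # pseudo-Green's matrix evaluated with diffusivity D0
  dom0 <- domain_spec(config$domain$kind, size = config$domain$size,
                      D = D0, gamma0 = 0)
  prov0 <- make_greens_provider(dom0)
  X <- config$centres
  Gcal0 <- matrix(0, N, N)
  for (j in seq_len(N)) {
    Gcal0[j, j] <- greens_pseudo_regular(prov0, X[j, ]) -
      log(ell[j]) / (2 * pi * D0)
    if (N > 1) {
      o <- setdiff(seq_len(N), j)
      Gcal0[o, j] <- greens_pseudo(prov0, X[o, , drop = FALSE], X[j, ])
    }
  }
  live <- kap > 0   # kappa = 0 cells are sealed: A_j = 0 identically
  Mcoup <- diag(ifelse(live, 1 + D0 / (kap * ell), 1), N) +
    2 * pi * D0 * nu * Gcal0
  coup_solve <- function(rhs) {
    A <- numeric(N)
    if (any(live))
      A[live] <- solve(Mcoup[live, live, drop = FALSE], rhs[live])
    A
  }
  identical_cells <- length(unique(kap)) == 1L && length(unique(ell)) == 1L
  W <- NULL; Q <- NULL
  if (identical_cells) {
    Q <- (2 * pi * kap[1] * ell[1] * D0 / (kap[1] * ell[1] + D0)) * Gcal0
    W <- solve(diag(N) + nu * Q)
  }
  vol_cell <- pi * (eps * ell)^2
  U_tot <- sum(vol_cell)
  kappa_hat <- 2 * pi * N * kap[1] * ell[1] / U_tot
  alpha <- U_tot / (config$domain$volume - U_tot)
  structure(list(config = config, kinetics = kinetics, D0 = D0,
                 Gcal0 = Gcal0, Mcoup = Mcoup, coup_solve = coup_solve,
                 W = W, Q = Q, identical_cells = identical_cells,
                 vol_cell = vol_cell, kappa_hat = kappa_hat, alpha = alpha,
                 N = N),
            class = "reduced_qs")
}

#' Quasi-static coupling coefficients
#'
#' Solves the matching system for \eqn{A_j} given the current state.
#' @param system a [build_reduced_system()] object.
#' @param ubar mean bulk concentration.
#' @param w0 vector of exchanged-species concentrations per cell.
#' @export
qs_coupling <- function(system, ubar, w0) {
  as.vector(system$coup_solve(ubar - w0))
}

qs_rhs <- function(system, state) {
  N <- system$N; K1 <- system$kinetics$n_species
  ubar <- state[1]
  w <- matrix(state[-1], K1, N)
  A <- qs_coupling(system, ubar, w[1, ])
  dubar <- -system$config$domain$gamma0 * ubar -
    2 * pi * system$D0 / system$config$domain$volume * sum(A)
  dw <- matrix(0, K1, N)
  for (j in seq_len(N)) {
    dw[, j] <- system$kinetics$f(w[, j])
    dw[1, j] <- dw[1, j] + 2 * pi * system$D0 * A[j] / system$vol_cell[j]
  }
  c(dubar, as.vector(dw))
}

#' Simulate the reduced quorum-sensing system
#'
#' @param system a [build_reduced_system()] object.
#' @param ubar0 initial bulk mean.
#' @param w0 initial cell states (`n_species x N` matrix, or vector
#'   recycled).
#' @param horizon,n_out integration horizon and number of output times.
#' @return matrix: time, ubar, then w columns (species fastest).
#' @export
simulate_reduced <- function(system, ubar0, w0, horizon, n_out = 400) {
  K1 <- system$kinetics$n_species
  w0 <- matrix(w0, K1, system$N)
  y0 <- c(ubar0, as.vector(w0))
  f <- function(t, y, parms) {
    dy <- qs_rhs(system, y)
    if (!all(is.finite(dy))) stop("kinetics returned non-finite rates")
    list(dy)
  }
  times <- seq(0, horizon, length.out = n_out)
  out <- deSolve::lsoda(y0, times, f, NULL, rtol = 1e-10, atol = 1e-12)
  colnames(out) <- c("time", "ubar",
                     paste0("w", rep(seq_len(system$N), each = K1), "_",
                            rep(seq_len(K1) - 1L, system$N)))
  out
}

#' Simulate the non-spatial (well-mixed) quorum-sensing model
#'
#' The classical ODE limit: \eqn{dU/dt = (\alpha\hat\kappa/N)\sum_j (w_{j,0}
#' - U) - \gamma_0 U}, \eqn{dw_{j,a}/dt = f_a(w_j) - \hat\kappa
#' \delta_{a,0} (w_{j,0} - U)}.
#'
#' @param kinetics a [make_kinetics()].
#' @param kappa_hat,alpha,gamma0 exchange and decay rates.
#' @param N number of cells.
#' @inheritParams simulate_reduced
#' @export
simulate_wellmixed <- function(kinetics, kappa_hat, alpha, gamma0, N,
                               ubar0, w0, horizon, n_out = 400) {
  K1 <- kinetics$n_species
  w0 <- matrix(w0, K1, N)
  y0 <- c(ubar0, as.vector(w0))
  f <- function(t, y, parms) {
    U <- y[1]
    w <- matrix(y[-1], K1, N)
    dU <- alpha * kappa_hat / N * sum(w[1, ] - U) - gamma0 * U
    dw <- matrix(0, K1, N)
    for (j in seq_len(N)) {
      dw[, j] <- kinetics$f(w[, j])
      dw[1, j] <- dw[1, j] - kappa_hat * (w[1, j] - U)
    }
    list(c(dU, as.vector(dw)))
  }
  times <- seq(0, horizon, length.out = n_out)
  out <- deSolve::lsoda(y0, times, f, NULL, rtol = 1e-10, atol = 1e-12)
  colnames(out) <- c("time", "ubar",
                     paste0("w", rep(seq_len(N), each = K1), "_",
                            rep(seq_len(K1) - 1L, N)))
  out
}

#' Fixed point and Jacobian of the reduced system
#'
#' Newton solve for the steady state of the reduced ODEs from a start
#' state, plus the numerical Jacobian eigenvalues there.
#' @inheritParams simulate_reduced
#' @param start initial guess `c(ubar, w...)`; defaults to the kinetics
#'   fixed point with ubar matching.
#' @export
qs_fixed_point <- function(system, start = NULL) {
  K1 <- system$kinetics$n_species
  if (is.null(start)) {
    fp <- if (!is.null(system$kinetics$fixed_points))
      system$kinetics$fixed_points[1, ] else rep(1, K1)
    start <- c(fp[1], rep(fp, system$N))
  }
  res <- newton_solve(function(y) qs_rhs(system, y), start)
  n <- length(res$x)
  J <- matrix(0, n, n)
  r0 <- qs_rhs(system, res$x)
  for (i in seq_len(n)) {
    h <- 1e-6 * max(abs(res$x[i]), 1)
    xp <- res$x; xp[i] <- xp[i] + h
    J[, i] <- (qs_rhs(system, xp) - r0) / h
  }
  list(state = res$x, converged = res$converged, residual = res$resid,
       jacobian = J, eigenvalues = eigen(J, only.values = TRUE)$values)
}

#' Scan a parameter for Hopf bifurcations of the reduced system
#'
#' At each grid value the reduced-system fixed point is located and the
#' leading eigenvalue real part of its Jacobian recorded; sign changes are
#' refined by bisection.
#'
#' @param system_factory function(theta) returning a `"reduced_qs"` system.
#' @param grid parameter values (increasing).
#' @param refine bisection iterations for each crossing.
#' @return list with the per-grid report (data.frame) and refined
#'   `crossings`.
#' @export
hopf_scan <- function(system_factory, grid, refine = 20L) {
  lead_re <- function(theta) {
    sys <- system_factory(theta)
    fp <- qs_fixed_point(sys)
    if (!fp$converged) return(NA_real_)
    ev <- fp$eigenvalues
    cplx <- ev[abs(Im(ev)) > 1e-8]
    if (!length(cplx)) return(NA_real_)
    max(Re(cplx))
  }
  vals <- vapply(grid, lead_re, 0)
  report <- data.frame(theta = grid, lead_re = vals)
  crossings <- c()
  for (i in seq_len(length(grid) - 1L)) {
    if (is.na(vals[i]) || is.na(vals[i + 1])) next
    if (sign(vals[i]) * sign(vals[i + 1]) < 0) {
      lo <- grid[i]; hi <- grid[i + 1]
      flo <- vals[i]
      for (k in seq_len(refine)) {
        mid <- (lo + hi) / 2
        fm <- lead_re(mid)
        if (is.na(fm)) break
        if (sign(fm) == sign(flo)) { lo <- mid; flo <- fm } else hi <- mid
      }
      crossings <- c(crossings, (lo + hi) / 2)
    }
  }
  list(report = report, crossings = crossings)
}
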