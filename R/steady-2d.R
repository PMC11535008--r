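# 2D steady-state matched asymptotics with non-perturbative log summation.
#
# The inner solution around compartment j is U_j = Phi_j + nu A_j log(rho/l_j)
# with Phi_j = c_{j,0} + nu A_j Psi_j and Psi_j = D/(kappa_j l_j) (plus the
# interior resistance for model II).  Matching against the outer field
#   u(x) = -2 pi nu D sum_k A_k G(x, x_k)        (gamma0 > 0)
#   u(x) = u_inf - 2 pi nu D sum_k A_k G0(x,x_k) (gamma0 = 0, with sum A = 0)
# yields the linear system (I + nu M) a = -c0 (resp. its bordered analogue),
# M_ji = Psi_j delta_ij + 2 pi D Gcal_ji,
# Gcal_jj = R(x_j,x_j) - log(l_j)/(2 pi D), Gcal_ij = G(x_i,x_j).

#' Effective model-I parameters for a semi-permeable (model II) compartment
#'
#' A 2D model-II compartment behaves, in the matching condition, like a
#' model-I compartment with boundary level \eqn{c_{j,0} = \bar I_j/\bar\gamma_j}
#' and total resistance
#' \eqn{\Psi_j = D/(\kappa_j \ell_j) + D/(\bar D_j F(\bar\beta_j \ell_j))},
#' where \eqn{F(x) = x I_1(x)/I_0(x)} and
#' \eqn{\bar\beta_j = \sqrt{\bar\gamma_j/\bar D_j}}.
#'
#' @param comp a model-II [compartment()].
#' @param D bulk diffusivity.
#' @return list with `c0`, `Psi`, `betabar`.
#' @export
model2_effective_2d <- function(comp, D) {
  if (comp$model != "II") stop("not a model II compartment")
  if (comp$gbar <= 0) {
    if (comp$Ibar > 0) stop("no interior steady state: gbar = 0 with Ibar > 0")
    stop("model II effective parameters require gbar > 0")
  }
  bb <- sqrt(comp$gbar / comp$Dbar)
  Fv <- bessel_ratio_F(bb * comp$ell)
  Psi <- (if (is.finite(comp$kappa)) D / (comp$kappa * comp$ell) else 0) +
    D / (comp$Dbar * Fv)
  list(c0 = comp$Ibar / comp$gbar, Psi = Psi, betabar = bb)
}

#' The Bessel ratio F(x) = x I_1(x) / I_0(x)
#'
#' Strictly increasing, F(x) -> x^2/2 as x -> 0.  Used by the model-II
#' interior resistance.
#' @param x non-negative argument.
#' @export
bessel_ratio_F <- function(x) {
  out <- numeric(length(x))
  small <- x < 1e-4
  # series x^2/2 (1 - x^2/8 + ...) avoids 0/0 at the origin
  out[small] <- x[small]^2 / 2 * (1 - x[small]^2 / 8)
  xb <- x[!small]
  out[!small] <- xb * besselI(xb, 1, expon.scaled = TRUE) /
    besselI(xb, 0, expon.scaled = TRUE)
  out
}

# effective (c0, Psi) for the matching condition, any model
effective_parameters_2d <- function(config, c_override = NULL) {
  D <- config$domain$D
  N <- length(config$compartments)
  c0 <- numeric(N); Psi <- numeric(N)
  for (j in seq_len(N)) {
    cmp <- config$compartments[[j]]
    if (cmp$model == "II") {
      eff <- model2_effective_2d(cmp, D)
      c0[j] <- eff$c0; Psi[j] <- eff$Psi
    } else {
      c0[j] <- cmp$c0
      Psi[j] <- if (is.finite(cmp$kappa)) D / (cmp$kappa * cmp$ell) else 0
    }
  }
  if (!is.null(c_override)) c0 <- c_override
  list(c0 = c0, Psi = Psi)
}

#' Assemble the 2D interaction matrix
#'
#' Returns \eqn{M_{ji} = \Psi_j \delta_{ij} + 2\pi D \mathcal{G}_{ji}} at
#' Laplace rate `s` (the pseudo-Green's branch when \eqn{\gamma_0 + s = 0}).
#'
#' @param config a [compartment_configuration()] (2D).
#' @param provider matching [make_greens_provider()].
#' @param s Laplace rate (default 0).
#' @return list with `M`, `Gcal`, `Psi`.
#' @export
assemble_matrix_2d <- function(config, provider, s = 0) {
  if (config$domain$dim != 2L) stop("2D configuration required")
  D <- config$domain$D
  N <- length(config$compartments)
  eff <- effective_parameters_2d(config)
  g <- config$domain$gamma0 + s
  X <- config$centres
  Gcal <- matrix(0, N, N)
  for (j in seq_len(N)) {
    if (g > 0) {
      Gcal[j, j] <- greens_regular(provider, X[j, ], s) -
        log(config$compartments[[j]]$ell) / (2 * pi * D)
      if (N > 1) {
        others <- setdiff(seq_len(N), j)
        Gcal[others, j] <- greens_value(provider,
                                        X[others, , drop = FALSE], X[j, ], s)
      }
    } else {
      Gcal[j, j] <- greens_pseudo_regular(provider, X[j, ]) -
        log(config$compartments[[j]]$ell) / (2 * pi * D)
      if (N > 1) {
        others <- setdiff(seq_len(N), j)
        Gcal[others, j] <- greens_pseudo(provider,
                                         X[others, , drop = FALSE], X[j, ])
      }
    }
  }
  M <- diag(eff$Psi, N) + 2 * pi * D * Gcal
  list(M = M, Gcal = Gcal, Psi = eff$Psi)
}

#' Solve the 2D steady state (models I and II)
#'
#' Computes the matching coefficients \eqn{A_j} by the non-perturbative
#' logarithmic sum; for \eqn{\gamma_0 = 0} the far-field constant
#' \eqn{u_\infty} is determined jointly with the \eqn{A_j} through the
#' solvability constraint \eqn{\sum_j A_j = 0} (bordered linear system).
#' A uniform source \eqn{\mathcal{I}_0 > 0} (with \eqn{\gamma_0 > 0}) is
#' handled by the shift \eqn{u \to u - \mathcal{I}_0/\gamma_0}.
#'
#' @inheritParams assemble_matrix_2d
#' @param c_override optional replacement for the boundary levels (used by
#'   the model-III fixed-point iteration).
#' @return object of class `"asym2d"`: coefficients `A`, inner constants
#'   `Phi`, resistances `Psi`, far-field constant `u_inf` (zero-degradation
#'   branch only), matrix `M`, shift, and the configuration.
#' @export
solve_model1_2d <- function(config, provider, s = 0, c_override = NULL) {
  if (config$domain$dim != 2L) stop("2D configuration required")
  mats <- assemble_matrix_2d(config, provider, s)
  eff <- effective_parameters_2d(config, c_override)
  g <- config$domain$gamma0 + s
  nu <- config$nu
  N <- length(eff$c0)
  shift <- 0
  c_eff <- eff$c0
  if (config$domain$I0 > 0) {
    if (g <= 0)
      stop("uniform source with zero degradation admits no steady state")
    shift <- config$domain$I0 / g
    c_eff <- c_eff - shift
  }
  IM <- diag(N) + nu * mats$M
  if (g > 0) {
    A <- tryCatch(solve(IM, -c_eff), error = function(e)
      stop("matrix singular: compartments too close or nu too large"))
    u_inf <- NULL
  } else {
    B <- rbind(cbind(IM, -1), c(rep(1, N), 0))
    sol <- tryCatch(solve(B, c(-c_eff, 0)), error = function(e)
      stop("matrix singular: compartments too close or nu too large"))
    A <- sol[seq_len(N)]
    u_inf <- sol[N + 1L]
  }
  Phi <- eff$c0 + nu * A * eff$Psi  # physical inner constant
  structure(list(A = A, Phi = Phi, Psi = eff$Psi, u_inf = u_inf,
                 M = mats$M, Gcal = mats$Gcal, c0 = eff$c0, c_eff = c_eff,
                 shift = shift, s = s, nu = nu, config = config),
            class = "asym2d")
}

#' @export
print.asym2d <- function(x, ...) {
  cat(sprintf("<asym2d> N=%d  nu=%.4g%s\n", length(x$A), x$nu,
              if (!is.null(x$u_inf)) sprintf("  u_inf=%.6g", x$u_inf) else ""))
  print(data.frame(A = x$A, Phi = x$Phi, Psi = x$Psi))
  invisible(x)
}

#' Two-step zero-degradation solve (reference construction)
#'
#' The textbook construction: for trial \eqn{u_\infty},
#' \eqn{A_j = \sum_i (I+\nu M_0)^{-1}_{ji} (u_\infty - c_{i,0})}, with
#' \eqn{u_\infty} then fixed by \eqn{\sum_j A_j = 0}.  Must agree with the
#' bordered solve of [solve_model1_2d()]; retained as an independent route
#' for testing the better-conditioned implementation.
#' @inheritParams solve_model1_2d
#' @export
solve_model1_2d_twostep <- function(config, provider) {
  if (config$domain$gamma0 != 0) stop("two-step construction is the gamma0 = 0 branch")
  mats <- assemble_matrix_2d(config, provider)
  eff <- effective_parameters_2d(config)
  N <- length(eff$c0)
  E <- solve(diag(N) + config$nu * mats$M)
  u_inf <- sum(E %*% eff$c0) / sum(E)
  A <- as.vector(E %*% (u_inf - eff$c0))
  list(A = A, u_inf = u_inf)
}

#' Steady-state receptor number of a model-II synapse (2D)
#'
#' \eqn{\mathcal{N}_j = \pi\epsilon^2\ell_j^2 \bar I_j/\bar\gamma_j +
#' 2\pi\nu D A_j \epsilon^2/\bar\gamma_j}: the isolated-synapse balance of
#' exo/endocytosis plus the heterosynaptic correction carried by the
#' matching coefficient \eqn{A_j}.  A negative total is reported with a
#' warning (it signals parameters outside the trapping regime rather than a
#' sign convention choice).
#'
#' @param solution an `"asym2d"` from [solve_model1_2d()].
#' @param j compartment index (model II).
#' @export
receptor_number <- function(solution, j) {
  cmp <- solution$config$compartments[[j]]
  if (cmp$model != "II") stop("receptor_number requires a model II compartment")
  eps <- solution$config$epsilon
  D <- solution$config$domain$D
  Nj <- pi * eps^2 * cmp$ell^2 * cmp$Ibar / cmp$gbar +
    2 * pi * solution$nu * D * solution$A[j] * eps^2 / cmp$gbar
  if (Nj < 0)
    warning("negative receptor number: parameters outside the trapping regime")
  Nj
}

#' Model-II interior radial profile (2D)
#'
#' Returns the interior concentration \eqn{V_j(\rho)} in stretched
#' coordinates (\eqn{\rho \le \ell_j}):
#' \eqn{V_j = \bar I_j/\bar\gamma_j + \bar\Phi_j I_0(\bar\beta_j\rho)/I_0(\bar\beta_j\ell_j)}
#' with \eqn{\bar\Phi_j = \nu A_j D /(\bar D_j F(\bar\beta_j \ell_j))}.
#'
#' @inheritParams receptor_number
#' @return a function of the stretched radius rho.
#' @export
model2_interior_profile_2d <- function(solution, j) {
  cmp <- solution$config$compartments[[j]]
  if (cmp$model != "II") stop("model II compartment required")
  D <- solution$config$domain$D
  bb <- sqrt(cmp$gbar / cmp$Dbar)
  Phib <- solution$nu * solution$A[j] * D /
    (cmp$Dbar * bessel_ratio_F(bb * cmp$ell))
  base <- cmp$Ibar / cmp$gbar
  den <- besselI(bb * cmp$ell, 0)
  function(rho) base + Phib * besselI(bb * rho, 0) / den
}
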