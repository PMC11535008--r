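# Volume transmission with a randomly switching boundary.
#
# Varicosities release neurotransmitter while the source neurons fire and
# re-absorb it while quiescent.  With synchronous firing driven by the
# two-state Markov chain (quiescent) 0 <-> 1 (firing), rates beta (0 -> 1)
# and alpha (1 -> 0), the stationary conditional means
# ubar_n = E[u 1_{N=n}] satisfy a pair of coupled model-I problems:
#   step 1: ubar = ubar_0 + ubar_1 solves the zero-degradation Dirichlet
#           problem with unknown interface constants phi_j;
#   step 2: ubar_1 solves D lap u1 - (alpha+beta) u1 = -beta ubar with the
#           same Dirichlet values phi_j;
#   step 3: phi_j are fixed by the firing-state flux condition on each
#           interface, with the conditional flux weighted by the stationary
#           firing occupancy rho1 = beta/(alpha+beta).
# The convolution of the rate-s Green's function with ubar has the closed
# form (resolvent identity, using sum_k A_k = 0):
#   int G_s(x,x') ubar(x') dx'
#     = [u_inf - 2 pi D nu sum_k A_k (G0(x,x_k) - G_s(x,x_k))]/s,
# so no quadrature is needed anywhere in the nested solve.

#' Switching (volume-transmission) configuration
#'
#' @param config 2D [compartment_configuration()] on a zero-degradation
#'   domain; compartments must be Dirichlet (`kappa = Inf`).
#' @param alpha firing -> quiescent rate (> 0).
#' @param beta quiescent -> firing rate (> 0).
#' @param J per-varicosity release flux density during firing
#'   (concentration x length / time, >= 0); recycled to length N.
#' @return object of class `"switching_config"`; the Markov generator (rows
#'   summing to zero, states ordered quiescent/firing) is in `$generator`.
#' @export
switching_config <- function(config, alpha, beta, J) {
  if (config$domain$dim != 2L) stop("2D configuration required")
  if (config$domain$gamma0 != 0) stop("bulk gamma0 must be 0")
  if (alpha <= 0 || beta <= 0) stop("rates must be positive")
  if (any(J < 0)) stop("J must be non-negative")
  if (any(is.finite(config_field(config, "kappa"))))
    stop("volume transmission assumes Dirichlet interfaces (kappa = Inf)")
  J <- rep(J, length.out = length(config$compartments))
  gen <- rbind(c(-beta, beta), c(alpha, -alpha))
  dimnames(gen) <- list(c("quiescent", "firing"), c("quiescent", "firing"))
  structure(list(config = config, alpha = alpha, beta = beta, J = J,
                 generator = gen, rho_firing = beta / (alpha + beta)),
            class = "switching_config")
}

#' Steady-state conditional means for volume transmission
#'
#' Performs the two nested matched-asymptotic solves and closes the system
#' with the interface flux conditions (see module header).  Returns the
#' interface constants and evaluators for the conditional means.
#'
#' @param scfg a [switching_config()].
#' @param provider Green's provider for the (zero-degradation) domain.
#' @return object of class `"switching_solution"`: `phi`, `u_inf`, field
#'   evaluators `ubar(x)`, `ubar1(x)`, `ubar0(x)`, and the flux residuals of
#'   the imposed Neumann condition.
#' @export
solve_volume_transmission <- function(scfg, provider) {
  config <- scfg$config
  D <- config$domain$D
  nu <- config$nu
  eps <- config$epsilon
  N <- length(config$compartments)
  ell <- config_field(config, "ell")
  X <- config$centres
  s <- scfg$alpha + scfg$beta
  rho1 <- scfg$rho_firing
  # matrices: pseudo branch (step 1) and rate-s branch (step 2), Psi = 0
  mk_mat <- function(pseudo) {
    Gc <- matrix(0, N, N)
    for (j in seq_len(N)) {
      if (pseudo) {
        Gc[j, j] <- greens_pseudo_regular(provider, X[j, ]) -
          log(ell[j]) / (2 * pi * D)
        if (N > 1) {
          o <- setdiff(seq_len(N), j)
          Gc[o, j] <- greens_pseudo(provider, X[o, , drop = FALSE], X[j, ])
        }
      } else {
        Gc[j, j] <- greens_regular(provider, X[j, ], s) -
          log(ell[j]) / (2 * pi * D)
        if (N > 1) {
          o <- setdiff(seq_len(N), j)
          Gc[o, j] <- greens_value(provider, X[o, , drop = FALSE],
                                   X[j, ], s)
        }
      }
    }
    2 * pi * D * Gc
  }
  M0 <- mk_mat(TRUE)
  Ms <- mk_mat(FALSE)
  E0 <- solve(diag(N) + nu * M0)
  Es <- solve(diag(N) + nu * Ms)
  # difference kernel W_jk = G0(x_j,x_k) - G_s(x_j,x_k) (finite on diagonal)
  Wd <- matrix(0, N, N)
  for (j in seq_len(N)) {
    Wd[j, j] <- greens_pseudo_regular(provider, X[j, ]) -
      greens_regular(provider, X[j, ], s)
    if (N > 1) {
      o <- setdiff(seq_len(N), j)
      Wd[o, j] <- greens_pseudo(provider, X[o, , drop = FALSE], X[j, ]) -
        greens_value(provider, X[o, , drop = FALSE], X[j, ], s)
    }
  }
  pieces_for_phi <- function(phi) {
    u_inf <- sum(E0 %*% phi) / sum(E0)
    A <- as.vector(E0 %*% (u_inf - phi))
    GammaX <- (scfg$beta / s) *
      (u_inf - 2 * pi * D * nu * as.vector(Wd %*% A))
    B <- as.vector(Es %*% (GammaX - phi))
    list(u_inf = u_inf, A = A, B = B, GammaX = GammaX)
  }
  # affine map phi -> nu B; close with nu B_j = -eps ell_j rho1 J_j / D
  b0 <- nu * pieces_for_phi(rep(0, N))$B
  Lmap <- matrix(0, N, N)
  for (m in seq_len(N)) {
    e <- rep(0, N); e[m] <- 1
    Lmap[, m] <- nu * pieces_for_phi(e)$B - b0
  }
  target <- -eps * ell * rho1 * scfg$J / D
  phi <- tryCatch(solve(Lmap, target - b0), error = function(e)
    stop("flux-closure system singular: configuration error"))
  pc <- pieces_for_phi(phi)
  flux_resid <- nu * pc$B / (eps * ell) * D + rho1 * scfg$J
  ubar <- function(x) {
    x <- rbind(x)
    acc <- rep(pc$u_inf, nrow(x))
    for (k in seq_len(N))
      acc <- acc - 2 * pi * nu * D * pc$A[k] *
        greens_pseudo(provider, x, X[k, ])
    acc
  }
  ubar1 <- function(x) {
    x <- rbind(x)
    gs_sum <- rep(0, nrow(x))
    for (k in seq_len(N))
      gs_sum <- gs_sum + pc$A[k] * greens_value(provider, x, X[k, ], s)
    acc <- (scfg$beta / s) * (ubar(x) + 2 * pi * D * nu * gs_sum)
    for (k in seq_len(N))
      acc <- acc - 2 * pi * nu * D * pc$B[k] *
        greens_value(provider, x, X[k, ], s)
    acc
  }
  structure(list(phi = phi, u_inf = pc$u_inf, A = pc$A, B = pc$B,
                 flux_residual = flux_resid,
                 ubar = ubar, ubar1 = ubar1,
                 ubar0 = function(x) ubar(x) - ubar1(x),
                 scfg = scfg),
            class = "switching_solution")
}
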