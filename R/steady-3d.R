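# 3D steady-state asymptotics: two-term epsilon expansion.
#
# Each compartment carries the trap strength Lambda_j = kappa_j l_j^2 /
# (kappa_j l_j + D) (-> l_j in the Dirichlet limit).  The outer solution is
#   u(x) ~ 4 pi D eps sum_k Lambda_k (c_k0 - eps chi_k) G(x, x_k),
#   chi_j = 4 pi D [ Lambda_j c_j0 R_jj + sum_{k != j} Lambda_k c_k0 G_jk ],
# and the inner solution around compartment j is
#   U_j(rho) ~ (Lambda_j/rho)(c_j0 - eps chi_j).
# For gamma0 = 0 the far-field constant u_inf is fixed by solvability,
#   u_inf = sum_j Lambda_j (c_j0 - eps chi_j) / sum_j Lambda_j,
# with chi evaluated on the shifted levels c_j0 - u_inf and the pseudo
# Green's function (a scalar linear equation, solved exactly).

trap_strength <- function(kappa, ell, D) {
  ifelse(is.finite(kappa), kappa * ell^2 / (kappa * ell + D), ell)
}

# Green's matrix for the 3D matching: diag = regular part, offdiag = values
greens_matrix_3d <- function(config, provider, pseudo = FALSE, s = 0) {
  N <- length(config$compartments)
  X <- config$centres
  Gm <- matrix(0, N, N)
  for (j in seq_len(N)) {
    if (pseudo) {
      Gm[j, j] <- greens_pseudo_regular(provider, X[j, ])
      if (N > 1) {
        o <- setdiff(seq_len(N), j)
        Gm[o, j] <- greens_pseudo(provider, X[o, , drop = FALSE], X[j, ])
      }
    } else {
      Gm[j, j] <- greens_regular(provider, X[j, ], s)
      if (N > 1) {
        o <- setdiff(seq_len(N), j)
        Gm[o, j] <- greens_value(provider, X[o, , drop = FALSE], X[j, ], s)
      }
    }
  }
  Gm
}

#' Leading inner amplitude of a 3D model-II compartment
#'
#' Solves the spherically symmetric interior/exterior problem with a
#' semi-permeable interface: exterior \eqn{U = A/\rho}, interior
#' \eqn{V = \bar I/\bar\gamma + B \sinh(\bar\beta\rho)/\rho}, with flux
#' continuity \eqn{D U' = \bar D V' = \kappa (U - V)} at \eqn{\rho = \ell}.
#'
#' @param comp model-II [compartment()].
#' @param D bulk diffusivity.
#' @return list with amplitudes `A`, `B` and profile functions `U(rho)`,
#'   `V(rho)` in stretched coordinates.
#' @export
model2_inner_coefficient_3d <- function(comp, D) {
  if (comp$model != "II") stop("not a model II compartment")
  if (comp$gbar <= 0) {
    if (comp$Ibar > 0) stop("no interior steady state: gbar = 0 with Ibar > 0")
    stop("gbar > 0 required")
  }
  ell <- comp$ell
  bb <- sqrt(comp$gbar / comp$Dbar)
  Lam <- trap_strength(comp$kappa, ell, D)
  sh <- sinh(bb * ell); ch <- cosh(bb * ell)
  num <- comp$Dbar * (bb * ell * ch - sh)
  den <- D * sh / ell + comp$Dbar * (bb * ell * ch - sh) / Lam
  A <- num / den * comp$Ibar / comp$gbar
  B <- -D * A / (comp$Dbar * (bb * ell * ch - sh))
  base <- comp$Ibar / comp$gbar
  list(A = A, B = B,
       U = function(rho) A / rho,
       V = function(rho) base + B * sinh(bb * rho) / rho)
}

# effective boundary levels for the 3D matching, any model
effective_parameters_3d <- function(config, c_override = NULL) {
  D <- config$domain$D
  N <- length(config$compartments)
  c0 <- numeric(N)
  for (j in seq_len(N)) {
    cmp <- config$compartments[[j]]
    c0[j] <- if (cmp$model == "II") {
      # the interface dresses the effective source level: the exterior sees
      # U = A/rho, i.e. an effective Lambda_j c_eff = A_j
      model2_inner_coefficient_3d(cmp, D)$A /
        trap_strength(cmp$kappa, cmp$ell, D)
    } else cmp$c0
  }
  if (!is.null(c_override)) c0 <- c_override
  c0
}

#' Solve the 3D steady state (models I and II)
#'
#' @inheritParams solve_model1_2d
#' @param order `"two-term"` (default) retains the inter-compartment
#'   correction \eqn{-\epsilon\chi_k}; `"one-term"` keeps only the leading
#'   monopole sum.
#' @return object of class `"asym3d"` with `Lambda`, `chi`, effective
#'   levels `c0`, and `u_inf` on the zero-degradation branch.
#' @export
solve_model1_3d <- function(config, provider, order = c("two-term", "one-term"),
                            s = 0, c_override = NULL) {
  if (config$domain$dim != 3L) stop("3D configuration required")
  order <- match.arg(order)
  D <- config$domain$D
  eps <- config$epsilon
  g <- config$domain$gamma0 + s
  N <- length(config$compartments)
  kap <- config_field(config, "kappa")
  ell <- config_field(config, "ell")
  Lam <- trap_strength(kap, ell, D)
  c0 <- effective_parameters_3d(config, c_override)
  shift <- 0
  if (config$domain$I0 > 0) {
    if (g <= 0)
      stop("uniform source with zero degradation admits no steady state")
    shift <- config$domain$I0 / g
    c0 <- c0 - shift
  }
  if (g > 0) {
    Gm <- greens_matrix_3d(config, provider, pseudo = FALSE, s = s)
    chi <- if (order == "two-term") 4 * pi * D * as.vector(Gm %*% (Lam * c0))
           else numeric(N)
    u_inf <- NULL
  } else {
    Gm <- greens_matrix_3d(config, provider, pseudo = TRUE)
    if (order == "two-term") {
      # chi_j(u_inf) = chi_a_j - u_inf chi_b_j (linear), u_inf from
      # sum Lambda (c - u_inf - eps chi) = 0
      chi_a <- 4 * pi * D * as.vector(Gm %*% (Lam * c0))
      chi_b <- 4 * pi * D * as.vector(Gm %*% Lam)
      num <- sum(Lam * (c0 - eps * chi_a))
      den <- sum(Lam * (1 - eps * chi_b))
      u_inf <- num / den
      chi <- chi_a - u_inf * chi_b
    } else {
      chi <- numeric(N)
      u_inf <- sum(Lam * c0) / sum(Lam)
    }
  }
  structure(list(Lambda = Lam, chi = chi, c0 = c0 + shift, c_eff = c0,
                 u_inf = u_inf, order = order, shift = shift, s = s,
                 Gm = Gm, config = config),
            class = "asym3d")
}

#' @export
print.asym3d <- function(x, ...) {
  cat(sprintf("<asym3d> N=%d  order=%s%s\n", length(x$Lambda), x$order,
              if (!is.null(x$u_inf)) sprintf("  u_inf=%.6g", x$u_inf) else ""))
  print(data.frame(Lambda = x$Lambda, chi = x$chi, c0 = x$c0))
  invisible(x)
}
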