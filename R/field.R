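#' Evaluate the composite steady-state concentration field
#'
#' Uses the outer (Green's-function) representation away from all
#' compartments and switches to the matched inner solution within
#' `rho_switch` (default \eqn{5\epsilon\ell_j}) of a compartment centre.
#' Interior points (inside a compartment) return the model-II interior
#' profile where defined and `NA` otherwise (the theory does not model
#' model-I/III interiors).
#'
#' @param solution an `"asym2d"` or `"asym3d"` object.
#' @param x evaluation point(s), vector or matrix of rows.
#' @param provider the Green's provider used for the solve.
#' @param rho_switch_factor multiple of \eqn{\epsilon\ell_j} at which the
#'   composite representation switches from outer to inner (default 5).
#' @return numeric vector of concentrations.
#' @export
evaluate_field <- function(solution, provider, x, rho_switch_factor = 5) {
  x <- rbind(x)
  config <- solution$config
  if (ncol(x) != config$domain$dim) stop("point dimension mismatch")
  if (!all(domain_contains(config$domain, x, margin = -1e-12)))
    stop("point outside the domain")
  eps <- config$epsilon
  N <- length(config$compartments)
  X <- config$centres
  out <- numeric(nrow(x))
  # nearest compartment and distance
  d2 <- matrix(0, nrow(x), N)
  for (j in seq_len(N))
    d2[, j] <- rowSums(sweep(x, 2, X[j, ])^2)
  nearest <- max.col(-d2)
  dn <- sqrt(d2[cbind(seq_len(nrow(x)), nearest)])
  ells <- config_field(config, "ell")
  switch_r <- rho_switch_factor * eps * ells[nearest]
  inner_mask <- dn < switch_r
  if (any(!inner_mask)) {
    out[!inner_mask] <- field_outer(solution, provider,
                                    x[!inner_mask, , drop = FALSE])
  }
  for (i in which(inner_mask)) {
    j <- nearest[i]
    rho <- dn[i] / eps  # stretched radius
    out[i] <- field_inner(solution, j, rho)
  }
  out
}

field_outer <- function(solution, provider, x) {
  config <- solution$config
  D <- config$domain$D
  g <- config$domain$gamma0 + solution$s
  X <- config$centres
  N <- nrow(X)
  acc <- rep(solution$shift, nrow(x))
  if (!is.null(solution$u_inf)) acc <- acc + solution$u_inf
  if (inherits(solution, "asym2d")) {
    for (k in seq_len(N)) {
      Gk <- if (g > 0) greens_value(provider, x, X[k, ], solution$s)
            else greens_pseudo(provider, x, X[k, ])
      acc <- acc - 2 * pi * solution$nu * D * solution$A[k] * Gk
    }
  } else {
    eps <- config$epsilon
    amp <- solution$Lambda * (solution$c_eff -
                                (if (!is.null(solution$u_inf))
                                   solution$u_inf else 0) -
                                eps * solution$chi)
    for (k in seq_len(N)) {
      Gk <- if (g > 0) greens_value(provider, x, X[k, ], solution$s)
            else greens_pseudo(provider, x, X[k, ])
      acc <- acc + 4 * pi * D * eps * amp[k] * Gk
    }
  }
  acc
}

field_inner <- function(solution, j, rho) {
  config <- solution$config
  cmp <- config$compartments[[j]]
  if (rho < cmp$ell) {
    # interior query
    if (cmp$model == "II") {
      prof <- if (inherits(solution, "asym2d"))
        model2_interior_profile_2d(solution, j)
      else model2_inner_coefficient_3d(cmp, config$domain$D)$V
      return(prof(rho) + solution$shift)
    }
    return(NA_real_)
  }
  if (inherits(solution, "asym2d")) {
    # Phi already carries the physical (unshifted) boundary level
    solution$Phi[j] + solution$nu * solution$A[j] * log(rho / cmp$ell)
  } else {
    u_inf <- if (!is.null(solution$u_inf)) solution$u_inf else 0
    solution$shift + u_inf +
      (solution$Lambda[j] / rho) *
        (solution$c_eff[j] - u_inf - config$epsilon * solution$chi[j])
  }
}
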