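# Model III: each compartment is a well-mixed reaction network with K+1
# species; only species a = 0 is exchanged with the bulk.  At steady state
# the per-compartment kinetics balance the diffusive exchange flux:
#   2D: fhat_a(w_j*) + 2 pi D nu A_j delta_{a,0} = 0,
#       A_j from the model-I matching with c_{j,0} = w*_{j,0}
#   3D: fhat_a(w_j*) - 4 pi kappa_j l_j^2 (w*_{j,0} - U_j(l_j)) delta_{a,0} = 0,
#       U_j(l_j) from the two-term inner solution (leading order
#       fhat_0 = 4 pi D Lambda_j w*_{j,0}).
# fhat_a = |U_j| f_a is the extensive rate of the intensive kinetics f_a.

#' Define a reaction kinetics
#'
#' @param f function(w, ...) returning the intensive rate vector
#'   \eqn{f_a(w)}, one entry per species.
#' @param n_species number of species K+1 (species 1 is the exchanged one).
#' @param fixed_points optional matrix (rows) of known well-mixed fixed
#'   points of `f` alone, used to seed the multistart.
#' @param jacobian optional analytic Jacobian function(w).
#' @param name label.
#' @export
make_kinetics <- function(f, n_species, fixed_points = NULL, jacobian = NULL,
                          name = "custom") {
  structure(list(f = f, n_species = n_species, fixed_points = fixed_points,
                 jacobian = jacobian, name = name),
            class = "kinetics")
}

#' Sel'kov glycolytic oscillator kinetics
#'
#' Two species: \eqn{f_0 = \alpha_s w_1 + w_1 w_0^2 - w_0},
#' \eqn{f_1 = \epsilon_s(\mu_s - \alpha_s w_1 - w_1 w_0^2)}.  Species 0 is
#' the exchanged metabolite.  The isolated fixed point is
#' \eqn{w_0^* = \mu_s}, \eqn{w_1^* = \mu_s/(\alpha_s + \mu_s^2)} and the
#' isolated cell crosses a Hopf bifurcation where the Jacobian trace
#' \eqn{2\mu_s^2/(\alpha_s+\mu_s^2) - 1 - \epsilon_s(\alpha_s+\mu_s^2)}
#' changes sign.
#'
#' @param alpha_s,mu_s,eps_s positive kinetic parameters.
#' @export
selkov_kinetics <- function(alpha_s = 0.9, mu_s = 2, eps_s = 0.15) {
  f <- function(w) {
    if (any(w < 0)) stop("negative concentrations")
    c(alpha_s * w[2] + w[2] * w[1]^2 - w[1],
      eps_s * (mu_s - alpha_s * w[2] - w[2] * w[1]^2))
  }
  jac <- function(w) {
    rbind(c(2 * w[2] * w[1] - 1, alpha_s + w[1]^2),
          c(-2 * eps_s * w[2] * w[1], -eps_s * (alpha_s + w[1]^2)))
  }
  fp <- rbind(c(mu_s, mu_s / (alpha_s + mu_s^2)))
  k <- make_kinetics(f, 2L, fixed_points = fp, jacobian = jac,
                     name = "selkov")
  k$params <- list(alpha_s = alpha_s, mu_s = mu_s, eps_s = eps_s)
  k
}

#' Hopf threshold of the isolated Sel'kov cell
#'
#' Returns the value of \eqn{\epsilon_s} at which the isolated-cell Jacobian
#' trace vanishes (larger \eqn{\epsilon_s} is stable).
#' @inheritParams selkov_kinetics
#' @export
selkov_hopf_eps <- function(alpha_s = 0.9, mu_s = 2) {
  (2 * mu_s^2 / (alpha_s + mu_s^2) - 1) / (alpha_s + mu_s^2)
}

# damped Newton with numerical Jacobian for small systems
newton_solve <- function(resid, x0, tol = 1e-11, maxit = 60L) {
  x <- x0
  r <- resid(x)
  if (!all(is.finite(r))) return(list(x = x, converged = FALSE, resid = Inf))
  for (it in seq_len(maxit)) {
    nr <- sqrt(sum(r^2))
    if (nr < tol) return(list(x = x, converged = TRUE, resid = nr))
    n <- length(x)
    J <- matrix(0, n, n)
    for (i in seq_len(n)) {
      h <- 1e-7 * max(abs(x[i]), 1)
      xp <- x; xp[i] <- xp[i] + h
      rp <- resid(xp)
      if (!all(is.finite(rp))) return(list(x = x, converged = FALSE, resid = nr))
      J[, i] <- (rp - r) / h
    }
    step <- tryCatch(solve(J, -r), error = function(e) NULL)
    if (is.null(step)) return(list(x = x, converged = FALSE, resid = nr))
    lam <- 1
    repeat {
      xn <- x + lam * step
      rn <- tryCatch(resid(xn), error = function(e) rep(Inf, length(r)))
      if (all(is.finite(rn)) && sqrt(sum(rn^2)) < nr * (1 - 0.1 * lam) + tol)
        break
      lam <- lam / 2
      if (lam < 1e-6) break
    }
    if (lam < 1e-6) return(list(x = x, converged = FALSE,
                                resid = sqrt(sum(r^2))))
    x <- xn; r <- rn
  }
  list(x = x, converged = sqrt(sum(r^2)) < tol, resid = sqrt(sum(r^2)))
}

# residual of the coupled steady-state system, all compartments model III
model3_residual <- function(wmat, config, provider, kinetics) {
  # wmat: n_species x N
  N <- length(config$compartments)
  D <- config$domain$D
  eps <- config$epsilon
  w0 <- wmat[1, ]
  vol <- if (config$domain$dim == 2) pi * (eps * config_field(config, "ell"))^2
         else (4 / 3) * pi * (eps * config_field(config, "ell"))^3
  res <- matrix(0, nrow(wmat), N)
  for (j in seq_len(N))
    res[, j] <- vol[j] * kinetics$f(wmat[, j])
  if (config$domain$dim == 2) {
    sol <- solve_model1_2d(config, provider, c_override = w0)
    res[1, ] <- res[1, ] + 2 * pi * D * config$nu * sol$A
  } else {
    sol <- solve_model1_3d(config, provider, c_override = w0)
    u_inf <- if (is.null(sol$u_inf)) 0 else sol$u_inf
    # exchange flux out of compartment j, exact in kappa (Dirichlet limit
    # included): 4 pi D Lambda_j (w0 - u_inf - eps chi_j)
    ex <- 4 * pi * D * sol$Lambda * (w0 - u_inf - eps * sol$chi)
    res[1, ] <- res[1, ] - ex
  }
  res
}

#' Solve the model-III steady state
#'
#' Finds fixed points of the coupled compartment-bulk system by damped
#' Newton iteration from multiple start points: the well-mixed fixed points
#' of the kinetics plus a seeded Latin-hypercube-style sample.  Distinct
#' converged roots are deduplicated at relative distance 1e-6.
#'
#' @inheritParams solve_model1_2d
#' @param kinetics a [make_kinetics()] object.
#' @param starts optional list/matrix of start states (each a
#'   `n_species x N` matrix or a vector recycled across compartments).
#' @param n_random number of additional random starts (seeded).
#' @param seed RNG seed for the random starts.
#' @return list of fixed points, each with `w` (`n_species x N`),
#'   `residual`, `converged`.  Empty list (with a message) if no start
#'   converges.
#' @export
solve_model3 <- function(config, provider, kinetics, starts = NULL,
                         n_random = 4L, seed = 1L) {
  N <- length(config$compartments)
  K1 <- kinetics$n_species
  start_list <- list()
  if (!is.null(kinetics$fixed_points)) {
    for (i in seq_len(nrow(kinetics$fixed_points)))
      start_list <- c(start_list,
                      list(matrix(kinetics$fixed_points[i, ], K1, N)))
  }
  if (!is.null(starts)) {
    for (s in starts) {
      if (is.matrix(s)) start_list <- c(start_list, list(s))
      else start_list <- c(start_list, list(matrix(s, K1, N)))
    }
  }
  if (n_random > 0) {
    set.seed(seed)
    base <- if (length(start_list)) abs(start_list[[1]]) + 0.5 else
      matrix(1, K1, N)
    for (i in seq_len(n_random)) {
      start_list <- c(start_list,
                      list(base * matrix(stats::runif(K1 * N, 0.2, 2),
                                         K1, N)))
    }
  }
  roots <- list()
  for (st in start_list) {
    res_fun <- function(x) {
      as.vector(model3_residual(matrix(pmax(x, 0), K1, N), config, provider,
                                kinetics))
    }
    ans <- newton_solve(res_fun, as.vector(st))
    if (!ans$converged) next
    w <- matrix(pmax(ans$x, 0), K1, N)
    dup <- FALSE
    for (r in roots) {
      if (max(abs(r$w - w)) <= 1e-6 * max(1, max(abs(w)))) { dup <- TRUE; break }
    }
    if (!dup)
      roots <- c(roots, list(list(w = w, residual = ans$resid,
                                  converged = TRUE)))
  }
  if (!length(roots))
    message("solve_model3: no start converged; returning empty list")
  roots
}
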