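# Quorum-sensing reduction: coupling matrix structure, well-mixed limit,
# symmetry preservation, and the Hopf scan against direct simulation.

ring_config <- function(n, eps = 0.01, kappa = 1, gamma0 = 0.2, r = 0.5) {
  dom <- domain_spec("disk2d", D = 1, gamma0 = gamma0)
  comps <- lapply(seq_len(n) - 1L, function(k) {
    th <- 2 * pi * k / n
    compartment(r * c(cos(th), sin(th)), ell = 1, kappa = kappa,
                model = "III")
  })
  compartment_configuration(dom, eps, comps)
}

test_that("coupling matrix: circulant symmetry, residual, well-mixed limit", {
  kin <- selkov_kinetics()
  cfg <- ring_config(3)
  sys <- build_reduced_system(cfg, kin, D0 = 1)
  # ring of identical cells -> circulant W
  perm <- c(2, 3, 1)
  expect_lt(max(abs(sys$W - sys$W[perm, perm])), 1e-10)
  # direct substitution residual of the matching system
  set.seed(2)
  ub <- 0.7; w0 <- runif(3)
  A <- qs_coupling(sys, ub, w0)
  expect_lt(max(abs(sys$Mcoup %*% A - (ub - w0))), 1e-12)
  # identical-cell W route reproduces the general solve
  A2 <- (1 / (1 + 1)) * as.vector(sys$W %*% (ub - w0))
  expect_lt(max(abs(A - A2)), 1e-14)
  # well-mixed limit
  sysL <- build_reduced_system(cfg, kin, D0 = 1e8)
  expect_lt(max(abs(sysL$W - diag(3))), 1e-6)
})

test_that("W - I deviation scales like 1/D0", {
  kin <- selkov_kinetics()
  cfg <- ring_config(3)
  devs <- vapply(c(1e2, 1e3, 1e4), function(D0)
    max(abs(build_reduced_system(cfg, kin, D0)$W - diag(3))), 0)
  expect_lt(abs(devs[1] / devs[2] / 10 - 1), 0.2)
  expect_lt(abs(devs[2] / devs[3] / 10 - 1), 0.2)
})

test_that("sealed cells (kappa = 0) decouple: exponential bulk decay", {
  dom <- domain_spec("disk2d", D = 1, gamma0 = 0.7)
  comps <- list(compartment(c(0.4, 0), ell = 1, kappa = 0, model = "III"),
                compartment(c(-0.4, 0), ell = 1, kappa = 0, model = "III"))
  cfg <- compartment_configuration(dom, 0.01, comps)
  kin <- make_kinetics(function(w) 0 * w, 2L)
  sys <- build_reduced_system(cfg, kin, D0 = 1)
  out <- simulate_reduced(sys, 1, c(0.5, 0.3), horizon = 3, n_out = 31)
  expect_lt(max(abs(out[, "ubar"] - exp(-0.7 * out[, "time"]))), 1e-8)
  expect_lt(max(abs(out[, "w1_0"] - 0.5)), 1e-10)
  expect_lt(max(abs(out[, "w2_1"] - 0.3)), 1e-10)
})

test_that("reduced trajectories converge to the well-mixed model as D0 grows", {
  kin <- selkov_kinetics(0.9, 2, 0.2)
  cfg <- ring_config(3, eps = 0.002)
  w_init <- c(1.2, 0.4)
  gaps <- vapply(c(10, 100), function(D0) {
    s <- build_reduced_system(cfg, kin, D0)
    o1 <- simulate_reduced(s, 0.5, w_init, horizon = 10, n_out = 101)
    o2 <- simulate_wellmixed(kin, s$kappa_hat, s$alpha, 0.2, 3, 0.5,
                             w_init, 10, n_out = 101)
    max(abs(o1[, "w1_0"] - o2[, "w1_0"]))
  }, 0)
  expect_lt(abs(gaps[1] / gaps[2] / 10 - 1), 0.5)   # ~ 1/D0
})

test_that("identical cells with identical data stay synchronised", {
  kin <- selkov_kinetics(0.9, 2, 0.1)   # oscillatory regime
  cfg <- ring_config(3, eps = 0.05, kappa = 0.001)
  sys <- build_reduced_system(cfg, kin, D0 = 0.5)
  out <- simulate_reduced(sys, 0.3, c(2.2, 0.5), horizon = 50, n_out = 201)
  expect_lt(max(abs(out[, "w1_0"] - out[, "w2_0"])), 1e-9)
  expect_lt(max(abs(out[, "w1_1"] - out[, "w3_1"])), 1e-9)
})

test_that("Hopf scan: eigenvalue crossing matches the onset of oscillation", {
  dom <- domain_spec("disk2d", D = 1, gamma0 = 0.2)
  comps <- list(compartment(c(0.45, 0), ell = 1, kappa = 0.001, model = "III"),
                compartment(c(-0.45, 0), ell = 1, kappa = 0.001,
                            model = "III"))
  cfg <- compartment_configuration(dom, 0.05, comps)
  fac <- function(es) build_reduced_system(cfg, selkov_kinetics(0.9, 2, es),
                                           D0 = 0.5)
  grid <- seq(0.08, 0.18, by = 0.02)
  hs <- hopf_scan(fac, grid)
  expect_length(hs$crossings, 1L)
  # direct-simulation onset: sustained late-time amplitude above threshold
  amp <- vapply(grid, function(es) {
    out <- simulate_reduced(fac(es), 0.3, c(2.2, 0.5), horizon = 400,
                            n_out = 800)
    diff(range(out[600:800, "w1_0"]))
  }, 0)
  osc <- amp > 0.05
  expect_true(any(osc) && !all(osc))
  onset_lo <- max(grid[osc]); onset_hi <- min(grid[!osc])
  expect_gte(hs$crossings[1], onset_lo - 0.02)
  expect_lte(hs$crossings[1], onset_hi + 0.02)
  # pure decay kinetics show no crossing
  dec <- make_kinetics(function(w) -w, 2L, fixed_points = rbind(c(0, 0)))
  hs0 <- hopf_scan(function(th) build_reduced_system(cfg, dec, D0 = 0.5),
                   c(0.1, 0.2))
  expect_length(hs0$crossings, 0L)
  # symmetric two-cell system: eigenvalues split into symmetric and
  # antisymmetric blocks, so each eigenvalue appears with its block partner
  fp <- qs_fixed_point(fac(0.16))
  expect_true(fp$converged)
  expect_true(all(Re(fp$eigenvalues) < 0))
})

test_that("well-mixed equivalence is term-by-term at W = I", {
  kin <- selkov_kinetics()
  cfg <- ring_config(2, eps = 0.01)
  sys <- build_reduced_system(cfg, kin, D0 = 1e10)
  st <- c(0.6, 1.5, 0.4, 1.1, 0.8)
  r1 <- singtrap:::qs_rhs(sys, st)
  # Eq-2.12-style right-hand side with kappa_hat = 2 pi N kappa l/|U|
  U <- st[1]; w <- matrix(st[-1], 2, 2)
  kh <- sys$kappa_hat; al <- sys$alpha
  dU <- al * kh / 2 * sum(w[1, ] - U) - 0.2 * U
  dw <- vapply(1:2, function(j) {
    v <- kin$f(w[, j]); v[1] <- v[1] - kh * (w[1, j] - U); v
  }, numeric(2))
  # alpha uses |Omega| - |U| while the reduction uses |Omega|: O(eps^2) gap
  expect_lt(abs(r1[1] - dU) / max(abs(dU), 1), 1e-3)
  expect_lt(max(abs(r1[-1] - as.vector(dw))) / max(abs(dw)), 1e-3)
})
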