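# Steady-state solvers: matching systems, zero-degradation branch, exact
# radial oracles, model II conversions, and the composite field.

test_that("single-compartment 2D coefficients follow the closed matrix form", {
  dom <- disk_domain(1)
  p <- make_greens_provider(dom)
  cfg <- single_central(dom, 0.02, kappa = 2, c0 = 1)
  sol <- solve_model1_2d(cfg, p)
  M11 <- 1 / (2 * 1) + 2 * pi * greens_regular(p, c(0, 0)) - log(1)
  expect_equal(sol$A, -1 / (1 + cfg$nu * M11), tolerance = 1e-12)
  mats <- assemble_matrix_2d(cfg, p)
  expect_equal(mats$M[1, 1], M11, tolerance = 1e-12)
})

test_that("mirror-symmetric pairs give a symmetric interaction matrix", {
  dom <- disk_domain(1)
  p <- make_greens_provider(dom)
  cfg <- mirrored_pair(dom, 0.02)
  mats <- assemble_matrix_2d(cfg, p)
  expect_lt(abs(mats$M[1, 1] - mats$M[2, 2]), 1e-10)
  expect_lt(abs(mats$M[1, 2] - mats$M[2, 1]), 1e-10)
})

test_that("zero-degradation solvability: sum A = 0 and two-step equivalence", {
  dom <- disk_domain(0)
  p <- make_greens_provider(dom)
  for (n in c(2L, 5L)) {
    cfg <- generate_configuration(seed = 10 + n, n = n, dom, 0.02,
                                  c0_range = c(0.5, 2))
    sol <- solve_model1_2d(cfg, p)
    expect_lt(abs(sum(sol$A)), 1e-12)
    ts <- solve_model1_2d_twostep(cfg, p)
    expect_lt(max(abs(sol$A - ts$A)), 1e-10)
    expect_lt(abs(sol$u_inf - ts$u_inf), 1e-10)
  }
})

test_that("uniform boundary levels give the uniform steady state", {
  dom <- disk_domain(0)
  p <- make_greens_provider(dom)
  cfg <- mirrored_pair(dom, 0.02, c0 = c(2, 2), kappa = Inf)
  sol <- solve_model1_2d(cfg, p)
  expect_equal(sol$u_inf, 2, tolerance = 1e-12)
  expect_lt(max(abs(sol$A)), 1e-12)
  expect_equal(evaluate_field(sol, p, c(0, 0.5)), 2, tolerance = 1e-12)
})

test_that("2D asymptotics converge to the exact annulus solution", {
  dom <- disk_domain(1)
  p <- make_greens_provider(dom)
  errs <- vapply(c(0.04, 0.02, 0.01), function(eps) {
    cfg <- single_central(dom, eps, kappa = Inf, c0 = 1)
    sol <- solve_model1_2d(cfg, p)
    ex <- exact_annulus_2d(1, eps, Inf, 1, 1, 1)
    abs(evaluate_field(sol, p, c(0.5, 0)) / ex$u(0.5) - 1)
  }, 0)
  expect_lt(errs[3], 0.02)
  expect_true(all(diff(errs) < 0))
})

test_that("3D two-term error shrinks at third order when eps halves", {
  dom <- sphere_domain(1)
  p <- make_greens_provider(dom)
  errs <- vapply(c(0.04, 0.02), function(eps) {
    cfg <- single_central(dom, eps, kappa = Inf, c0 = 1)
    sol <- solve_model1_3d(cfg, p)
    ex <- exact_shell_3d(1, eps, Inf, 1, 1, 1)
    abs(evaluate_field(sol, p, c(0.5, 0, 0)) - ex$u(0.5))
  }, 0)
  expect_gt(errs[1] / errs[2], 4)
  # one-term is less accurate than two-term
  cfg <- single_central(dom, 0.04, kappa = Inf, c0 = 1)
  s1 <- solve_model1_3d(cfg, p, order = "one-term")
  ex <- exact_shell_3d(1, 0.04, Inf, 1, 1, 1)
  expect_gt(abs(evaluate_field(s1, p, c(0.5, 0, 0)) - ex$u(0.5)), errs[1])
})

test_that("Dirichlet limit: kappa = 1e8 agrees with kappa = Inf", {
  dom <- disk_domain(1)
  p <- make_greens_provider(dom)
  c1 <- single_central(dom, 0.02, kappa = 1e8, c0 = 1)
  c2 <- single_central(dom, 0.02, kappa = Inf, c0 = 1)
  s1 <- solve_model1_2d(c1, p); s2 <- solve_model1_2d(c2, p)
  expect_lt(abs(s1$A - s2$A), 1e-6)
  dom3 <- sphere_domain(1)
  p3 <- make_greens_provider(dom3)
  s31 <- solve_model1_3d(single_central(dom3, 0.02, kappa = 1e8), p3)
  s32 <- solve_model1_3d(single_central(dom3, 0.02, kappa = Inf), p3)
  expect_lt(abs(s31$Lambda - s32$Lambda), 1e-6)
})

test_that("O(nu) Taylor expansion reproduces the leading-order constants", {
  dom <- disk_domain(0)
  p <- make_greens_provider(dom)
  cfg <- mirrored_pair(dom, 1e-4, c0 = c(2, 1), kappa = 3)
  sol <- solve_model1_2d(cfg, p)
  cbar <- mean(sol$c0)
  # A_j ~ u_inf - c_j0 and u_inf ~ mean(c0), with O(nu) corrections
  expect_lt(abs(sol$u_inf - cbar), 5 * cfg$nu)
  expect_lt(max(abs(sol$A - (sol$u_inf - sol$c0))), 5 * cfg$nu)
})

test_that("model II effective parameters and Bessel ratio", {
  # F cross-check: base besselI route vs direct power series
  Fseries <- function(x) {
    k <- 0:30
    I0 <- sum((x / 2)^(2 * k) / factorial(k)^2)
    I1 <- sum((x / 2)^(2 * k + 1) / (factorial(k) * factorial(k + 1)))
    x * I1 / I0
  }
  expect_lt(abs(bessel_ratio_F(1) - Fseries(1)), 1e-12)
  # small-argument limit: Psi ~ D/(kappa l) + 2 D/(gbar l^2)
  cmp <- compartment(c(0, 0), ell = 1, kappa = 1, model = "II",
                     Dbar = 1e8 / 1e-8, gbar = 1, Ibar = 0.5)
  cmp$Dbar <- 1 / 1e-8^2   # bbar * ell = 1e-8... set via gbar/Dbar
  cmp$gbar <- 1
  eff <- model2_effective_2d(cmp, D = 1)
  expect_lt(abs(eff$betabar * cmp$ell - 1e-8), 1e-12)
  expect_lt(abs(eff$Psi - (1 / (1 * 1) + 2 * 1 / (1 * 1^2))) /
              abs(eff$Psi), 1e-6)
  expect_equal(eff$c0, 0.5)
  # no interior source -> zero effective boundary level
  cmp0 <- compartment(c(0, 0), ell = 0.8, kappa = 2, model = "II",
                      Dbar = 3, gbar = 2, Ibar = 0)
  expect_equal(model2_effective_2d(cmp0, 1)$c0, 0)
  expect_error(compartment(c(0, 0), model = "II", Dbar = 1, gbar = 0,
                           Ibar = 1), "no interior steady state")
})

test_that("receptor numbers: quadrature identity and symmetry", {
  dom <- disk_domain(1)
  p <- make_greens_provider(dom)
  eps <- 0.03
  mk <- function(ctr) compartment(ctr, ell = 1, kappa = 1.5, model = "II",
                                  Dbar = 2, gbar = 1.2, Ibar = 0.8)
  cfg <- compartment_configuration(dom, eps, list(mk(c(0.4, 0)),
                                                  mk(c(-0.4, 0))))
  sol <- solve_model1_2d(cfg, p)
  N1 <- receptor_number(sol, 1)
  expect_equal(N1, receptor_number(sol, 2), tolerance = 1e-12)
  # direct quadrature of the interior profile V_j over the compartment
  prof <- model2_interior_profile_2d(sol, 1)
  gq <- gauss_legendre(80, 0, 1)          # stretched radius rho in (0, ell)
  quad <- 2 * pi * eps^2 * sum(gq$weights * gq$nodes * prof(gq$nodes))
  expect_lt(abs(N1 - quad), 1e-8)
})

test_that("3D model II interface: flux continuity and limits", {
  cmp <- compartment(c(0, 0, 0), ell = 0.8, kappa = 1.5, model = "II",
                     Dbar = 2, gbar = 3, Ibar = 1)
  mc <- model2_inner_coefficient_3d(cmp, D = 1)
  ell <- 0.8; bb <- sqrt(3 / 2)
  dU <- -mc$A / ell^2
  dV <- mc$B * (bb * cosh(bb * ell) / ell - sinh(bb * ell) / ell^2)
  expect_lt(abs(1 * dU - 2 * dV), 1e-10)
  expect_lt(abs(1 * dU - 1.5 * (mc$U(ell) - mc$V(ell))), 1e-10)
  # no interior source -> empty compartment
  cmp0 <- compartment(c(0, 0, 0), ell = 0.8, kappa = 1.5, model = "II",
                      Dbar = 2, gbar = 3, Ibar = 0)
  mc0 <- model2_inner_coefficient_3d(cmp0, 1)
  expect_equal(mc0$A, 0)
  expect_equal(mc0$V(0.5), 0)
  # reaction-dominated regime: A -> Lambda * Ibar/gbar when the interior
  # resistance D sinh/(l Dbar beta l cosh) is negligible (D << Dbar beta l)
  cmpR <- compartment(c(0, 0, 0), ell = 1, kappa = 5, model = "II",
                      Dbar = 1, gbar = 400, Ibar = 400)
  mcR <- model2_inner_coefficient_3d(cmpR, D = 0.1)
  Lam <- 5 / (5 + 0.1)
  expect_lt(abs(mcR$A / (Lam * 1) - 1), 0.01)
})

test_that("composite field: boundary flux, switch continuity, average", {
  dom <- disk_domain(1)
  p <- make_greens_provider(dom)
  cfg <- mirrored_pair(dom, 0.02, c0 = c(1.5, 0.8))
  sol <- solve_model1_2d(cfg, p)
  # no-flux at the outer boundary
  u <- c(cos(1.1), sin(1.1)); h <- 1e-4
  f <- evaluate_field(sol, p, rbind(u, u * (1 - h), u * (1 - 2 * h)))
  expect_lt(abs((3 * f[1] - 4 * f[2] + f[3]) / (2 * h)), 1e-4)
  # inner/outer mismatch at the switch radius shrinks with eps
  mism <- vapply(c(0.04, 0.02, 0.01), function(eps) {
    cfge <- mirrored_pair(dom, eps, c0 = c(1.5, 0.8))
    se <- solve_model1_2d(cfge, p)
    xsw <- c(0.4 + 5 * eps, 0)
    inner <- se$Phi[1] + se$nu * se$A[1] * log(5)
    outer <- evaluate_field(se, p, xsw, rho_switch_factor = 4.99)
    abs(inner - outer)
  }, 0)
  expect_true(all(diff(mism) < 0))
  # interior of a model I compartment is undefined
  expect_true(is.na(evaluate_field(sol, p, c(0.4, 0))))
  # zero-degradation: spatial average equals u_inf
  dom0 <- disk_domain(0)
  p0 <- make_greens_provider(dom0)
  cfg0 <- mirrored_pair(dom0, 0.02, c0 = c(2, 1), kappa = 3)
  s0 <- solve_model1_2d(cfg0, p0)
  gq <- gauss_legendre(40, 0, 1)
  th <- (seq_len(80) - 0.5) * 2 * pi / 80
  pts <- cbind(as.vector(outer(gq$nodes, cos(th))),
               as.vector(outer(gq$nodes, sin(th))))
  w <- rep(gq$weights * gq$nodes, 80) * (2 * pi / 80)
  keep <- sqrt((pts[, 1] - 0.4)^2 + pts[, 2]^2) > 0.05 &
    sqrt((pts[, 1] + 0.4)^2 + pts[, 2]^2) > 0.05
  avg <- sum(w[keep] * evaluate_field(s0, p0, pts[keep, ])) / sum(w[keep])
  expect_lt(abs(avg - s0$u_inf), 0.02)
})

test_that("configuration validation enforces the asymptotic assumptions", {
  dom <- disk_domain(1)
  expect_error(compartment_configuration(dom, 0.02, list(
    compartment(c(0, 0), ell = 0.5))), "ell_j must equal 1")
  expect_error(compartment_configuration(dom, 0.02, list(
    compartment(c(0.1, 0), ell = 1), compartment(c(-0.05, 0), ell = 1))),
    "too close")
  expect_error(compartment_configuration(dom, 0.02, list(
    compartment(c(0.95, 0), ell = 1))), "boundary")
  expect_error(compartment_configuration(dom, 1.2, list(
    compartment(c(0, 0), ell = 1))), "epsilon")
})
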