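# Accumulation times: 1D closed form vs the Laplace machinery and the
# eigenfunction sum; 2D Laplace-space identities and scaling.

test_that("1D closed form: values, affine structure, domain errors", {
  expect_equal(accumulation_time_1d(0, 1, 2), 0.25)
  x <- seq(0, 4, by = 0.5)
  Tx <- accumulation_time_1d(x, D = 2, gamma0 = 0.5)
  slopes <- diff(Tx) / diff(x)
  expect_lt(diff(range(slopes)), 1e-14)
  expect_equal(slopes[1], sqrt(0.5 / 2) / (2 * 0.5), tolerance = 1e-12)
  expect_error(accumulation_time_1d(1, 1, 0), "gamma0")
  expect_error(accumulation_time_1d(-1, 1, 1), "non-negative")
})

test_that("Laplace machinery reproduces the closed form as L grows", {
  xs <- seq(0, 5, length.out = 11)   # xi = 1 when D = gamma0 = 1
  errs <- vapply(c(10, 20, 40), function(L)
    max(abs(accumulation_time_1d_laplace(xs, 1, 1, L) -
              accumulation_time_1d(xs, 1, 1))), 0)
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[3], 1e-4)
})

test_that("eigenfunction-sum oracle converges to the closed form", {
  errs <- vapply(c(10, 20, 40), function(L)
    abs(accumulation_time_1d_eigen(2, 1, 1, L) -
          accumulation_time_1d(2, 1, 1)), 0)
  expect_lt(errs[1], 1e-5)
  expect_lt(errs[3], 1e-8)
})

test_that("Gamma0: zero data, delta limit, and Green's normalisation", {
  dom <- rect_domain(9, size = c(1, 1))   # larger rate keeps image sums light
  p <- make_greens_provider(dom)
  u0z <- initial_bump(c(0.3, 0.7), 0.08, mass = 0)
  expect_equal(gamma0_source_field(p, u0z, rbind(c(0.7, 0.3))), 0)
  # shrinking bump converges to mass * G(x, x_c)
  x <- c(0.7, 0.3)
  gref <- 2.5 * greens_value(p, rbind(x), c(0.3, 0.7))
  errs <- vapply(c(0.1, 0.05), function(w)
    abs(gamma0_source_field(p, initial_bump(c(0.3, 0.7), w, mass = 2.5), rbind(x)) -
          gref), 0)
  expect_lt(errs[2], abs(gref) * 0.01)
  expect_lt(errs[2], errs[1])
  # int_Omega Gamma0 dx = (1/gamma0) int u0 via a polar quadrature around x0
  u0 <- initial_bump(c(0.5, 0.5), 0.1, mass = 1.7)
  gq <- gauss_legendre(12, 0, 1)
  nth <- 16
  th <- (seq_len(nth) - 0.5) * 2 * pi / nth
  tot <- 0
  for (t in th) {
    u <- c(cos(t), sin(t))
    rmax <- min(ifelse(u > 0, (1 - 0.5) / u, (0 - 0.5) / u))
    r <- gq$nodes * rmax
    pts <- cbind(0.5 + r * u[1], 0.5 + r * u[2])
    vals <- gamma0_source_field(p, u0, pts, n_r = 16, n_ang = 24)
    tot <- tot + (2 * pi / nth) * rmax * sum(gq$weights * r * vals)
  }
  # tolerance set by the coarse outer quadrature, not the field itself
  expect_lt(abs(tot - 1.7 / 9) / (1.7 / 9), 2e-2)
})

test_that("matrix-derivative identity and steady-state limit hold", {
  dom <- rect_domain(1, size = c(1, 1))
  p <- make_greens_provider(dom)
  cfg <- compartment_configuration(dom, 0.02, list(
    compartment(c(0.35, 0.4), ell = 1, kappa = 3, model = "I", c0 = 1),
    compartment(c(0.7, 0.65), ell = 0.8, kappa = 2, model = "I", c0 = 0.7)))
  am <- singtrap:::accumulation_matrices_2d(cfg, p)
  # M'(0) from the analytic s-derivative equals the FD derivative of M
  h <- 1e-4
  Mp_fd <- (assemble_matrix_2d(cfg, p, h)$M -
              assemble_matrix_2d(cfg, p, -h)$M) / (2 * h)
  expect_lt(max(abs(am$Mp - Mp_fd)), 1e-6)
  # T T^-1 derivative identity: d/ds [T T^-1] = 0 with T = I + nu M(s)
  nu <- cfg$nu
  T0 <- diag(2) + nu * assemble_matrix_2d(cfg, p, 0)$M
  Tp <- nu * am$Mp
  Einv_p <- -am$E %*% Tp %*% am$E          # d/ds T^{-1}
  resid <- Tp %*% am$E + T0 %*% Einv_p
  expect_lt(max(abs(resid)), 1e-10)
  # lim s Atilde(s) equals the steady-state coefficients
  sol <- solve_model1_2d(cfg, p)
  s <- 1e-6
  Ms <- assemble_matrix_2d(cfg, p, s)$M
  Atilde <- -solve(diag(2) + nu * Ms, sol$c_eff / s)
  expect_lt(max(abs(s * Atilde - sol$A)), 1e-5)
})

test_that("2D accumulation time: fill is O(1), drain leading term is 1/nu", {
  dom <- rect_domain(1, size = c(1, 1))
  p <- make_greens_provider(dom)
  probe <- c(0.75, 0.3)
  u0 <- initial_bump(c(0.25, 0.75), 0.1, mass = 2)
  u00 <- initial_bump(c(0.25, 0.75), 0.1, mass = 0)
  lead <- c(); fills <- c()
  for (eps in c(0.04, 0.02, 0.01)) {
    cfg <- single_central(rect_domain(1, size = c(1, 1)), eps,
                          kappa = Inf, c0 = 1)
    ar <- accumulation_time_2d(cfg, p, u0, probe, "drain")
    lead <- c(lead, ar$T_leading)
    arf <- accumulation_time_2d(cfg, p, u00, probe, "fill")
    fills <- c(fills, arf$T)
    expect_gt(ar$T, 0); expect_gt(arf$T, 0)
  }
  nus <- -1 / log(c(0.04, 0.02, 0.01))
  expect_lt(diff(range(lead * nus)) / mean(lead * nus), 1e-10)
  # fill times stay O(1) as nu -> 0
  expect_lt(diff(range(fills)) / mean(fills), 0.5)
})

test_that("3D accumulation time: finite, increasing with distance (fill)", {
  dom <- sphere_domain(1)
  p <- make_greens_provider(dom)
  cfg <- single_central(dom, 0.02, kappa = Inf, c0 = 1)
  u00 <- initial_bump(c(0.5, 0, 0), 0.1, mass = 0, dim = 3)
  ar <- accumulation_time_3d(cfg, p, u00,
                             rbind(c(-0.3, 0, 0), c(-0.6, 0, 0)), "fill")
  expect_true(all(is.finite(ar$T)) && all(ar$T > 0))
  expect_gt(ar$T[2], ar$T[1])
  # drain leading term scales like 1/eps
  u0 <- initial_bump(c(0.5, 0, 0), 0.1, mass = 1, dim = 3)
  leads <- vapply(c(0.04, 0.02), function(eps) {
    cfge <- single_central(dom, eps, kappa = Inf, c0 = 1)
    accumulation_time_3d(cfge, p, u0, rbind(c(-0.5, 0, 0)),
                         "drain")$T_leading
  }, 0)
  expect_lt(abs(leads[2] / leads[1] - 2), 1e-8)
})

test_that("zero-degradation accumulation times are refused", {
  dom <- rect_domain(0, size = c(1, 1))
  p <- make_greens_provider(dom)
  cfg <- single_central(dom, 0.02, kappa = Inf, c0 = 1)
  u0 <- initial_bump(c(0.25, 0.75), 0.1, mass = 1)
  expect_error(accumulation_time_2d(cfg, p, u0, c(0.75, 0.3)),
               "gamma0 > 0")
})
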