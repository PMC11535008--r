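# Validation harness: exact radial oracles, finite-difference order of
# accuracy, trap capacitances, and the seeded configuration generator.

test_that("exact annulus: Robin residual and outer no-flux by construction", {
  ex <- exact_annulus_2d(1, 0.05, 2.5, 1.3, 1, 1.5)
  expect_lt(abs(ex$robin_residual), 1e-12)
  expect_lt(abs(ex$du(1)), 1e-12)
  exd <- exact_annulus_2d(0.8, 0.04, Inf, 2, 1.5, 0.7)
  expect_lt(abs(exd$u(0.04 * 0.8) - 2), 1e-12)
})

test_that("exact shell: Robin residual, no-flux, harmonic limit", {
  ex <- exact_shell_3d(1, 0.05, 3, 1, 1, 2)
  expect_lt(abs(ex$robin_residual), 1e-12)
  expect_lt(abs(ex$du(1)), 1e-12)
  # gamma0 -> 0: pure reflection forces the uniform state
  ex0 <- exact_shell_3d(1, 0.05, 2, 1.4, 1, 0)
  expect_equal(ex0$u(0.5), 1.4)
  exs <- exact_shell_3d(1, 0.05, 2, 1.4, 1, 1e-8)
  expect_lt(abs(exs$u(0.5) - 1.4), 1e-4)
})

test_that("radial FD schemes are second order (Richardson triple)", {
  ex <- exact_annulus_2d(1, 0.05, 2, 1, 1, 1.5)
  errs <- vapply(c(100, 200, 400), function(n)
    abs(fd_solve_radial(1, 0.05, 2, 1, 1, 1.5, n = n)$interp(0.5) -
          ex$u(0.5)), 0)
  p1 <- log2(errs[1] / errs[2]); p2 <- log2(errs[2] / errs[3])
  expect_gt(min(p1, p2), 1.7); expect_lt(max(p1, p2), 2.3)
  ex3 <- exact_shell_3d(1, 0.05, 3, 1, 1, 2)
  errs3 <- vapply(c(100, 200, 400), function(n)
    abs(fd_solve_radial(1, 0.05, 3, 1, 1, 2, n = n, dim = 3)$interp(0.5) -
          ex3$u(0.5)), 0)
  p1 <- log2(errs3[1] / errs3[2]); p2 <- log2(errs3[2] / errs3[3])
  expect_gt(min(p1, p2), 1.7); expect_lt(max(p1, p2), 2.3)
})

test_that("embedded-boundary solver: uniform state and refinement", {
  dom0 <- rect_domain(0, size = c(1, 1))
  cfg <- compartment_configuration(dom0, 0.05, list(
    compartment(c(0.35, 0.5), ell = 1, kappa = Inf, model = "I", c0 = 1.3),
    compartment(c(0.68, 0.5), ell = 1, kappa = Inf, model = "I", c0 = 1.3)),
    separation = 0.25)
  fd <- fd_solve_2d(cfg, h = 0.0125)
  expect_lt(max(abs(fd$u - 1.3)), 1e-10)
  # self-convergence at a probe under grid refinement
  dom <- rect_domain(1, size = c(1, 1))
  cfg1 <- compartment_configuration(dom, 0.05, list(
    compartment(c(0.4, 0.45), ell = 1, kappa = Inf, model = "I", c0 = 1)),
    separation = 0.3)
  vals <- vapply(c(1 / 80, 1 / 160, 1 / 320), function(h)
    fd_solve_2d(cfg1, h)$interp(rbind(c(0.8, 0.8))), 0)
  expect_lt(abs(vals[3] - vals[2]), abs(vals[2] - vals[1]))
  # unresolved compartments are refused
  expect_error(fd_solve_2d(cfg1, h = 1 / 40), "unresolved")
})

test_that("capacitances match the electrostatic formulas", {
  expect_equal(capacitance("sphere", 1), 1)
  expect_equal(capacitance("hemisphere", 1), 2 * (1 - 1 / sqrt(3)))
  expect_equal(capacitance("prolate", 2, 1), sqrt(3) / acosh(2))
  expect_equal(capacitance("oblate", 2, 1), sqrt(3) / acos(0.5))
  # sphere limit of the prolate spheroid
  expect_lt(abs(capacitance("prolate", 1, 1 - 1e-9) - 1), 1e-6)
  expect_lt(abs(capacitance("oblate", 1, 1 - 1e-9) - 1), 1e-6)
  expect_error(capacitance("prolate", 1, 2), "a >= b")
})

test_that("capacitance substitution perturbs the 3D solution consistently", {
  # a hemispherical trap of radius a acts like a sphere of radius C < a
  dom <- sphere_domain(1)
  p <- make_greens_provider(dom)
  Ch <- capacitance("hemisphere", 1)
  cfg_eq <- single_central(dom, 0.03 * Ch, kappa = Inf, c0 = 1)
  cfg <- single_central(dom, 0.03, kappa = Inf, c0 = 1)
  s_eq <- solve_model1_3d(cfg_eq, p)
  s <- solve_model1_3d(cfg, p)
  # the equivalent-capacitance trap absorbs less than the full sphere
  u_eq <- evaluate_field(s_eq, p, c(0.5, 0, 0))
  u <- evaluate_field(s, p, c(0.5, 0, 0))
  expect_lt(u_eq, u)
  expect_lt(abs(u_eq / u - Ch), 0.1)   # leading order scales with C
})

test_that("configuration generator is seeded, separated, and fails cleanly", {
  dom <- disk_domain(1)
  c1 <- generate_configuration(1, 4, dom, 0.02)
  c2 <- generate_configuration(1, 4, dom, 0.02)
  expect_identical(c1$centres, c2$centres)
  expect_identical(config_field <- vapply(c1$compartments, `[[`, 0, "ell"),
                   vapply(c2$compartments, `[[`, 0, "ell"))
  dd <- as.matrix(stats::dist(c1$centres)); diag(dd) <- Inf
  expect_gte(min(dd), 10 * 0.02)
  expect_equal(max(vapply(c1$compartments, `[[`, 0, "ell")), 1)
  expect_error(generate_configuration(1, 500, dom, 0.05, budget = 200L),
               "cannot place")
})
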