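# Ostwald ripening: Gibbs-Thomson law, rate identities, conservation,
# extinction handling, and a fixed-step oracle for the extinction time.

test_that("Gibbs-Thomson law: limits and monotonicity", {
  pr <- ripening_params(0.1, 1, l_c = 0.5, dimension = 3)
  expect_equal(gibbs_thomson(1e12, pr), 0.1, tolerance = 1e-10)
  expect_equal(gibbs_thomson(0.5, pr), 0.2)
  r <- c(2, 1.5, 1, 0.7, 0.3)
  expect_true(all(diff(gibbs_thomson(r, pr)) > 0))  # smaller r, higher c
  expect_error(gibbs_thomson(-1, pr), "positive")
})

test_that("rate identities: fixed point, signs, exact mass conservation", {
  pr2 <- ripening_params(0.1, 1, dimension = 2, eps = 0.02)
  pr3 <- ripening_params(0.1, 1, l_c = 1, dimension = 3)
  expect_equal(ripening_rhs_2d(c(1, 1, 1), pr2), rep(0, 3))
  expect_equal(ripening_rhs_3d(c(2, 2), pr3), rep(0, 2))
  rts <- ripening_rhs_2d(c(1, 2), pr2)
  expect_lt(rts[1], 0); expect_gt(rts[2], 0)
  r3 <- ripening_rhs_3d(c(1, 2, 3), pr3)
  expect_lt(r3[1], 0); expect_gt(r3[3], 0)
  set.seed(4)
  for (k in 1:5) {
    rr <- runif(6, 0.3, 2)
    expect_lt(abs(sum(rr * ripening_rhs_2d(rr, pr2))), 1e-14)
    expect_lt(abs(sum(rr^2 * ripening_rhs_3d(rr, pr3))), 1e-14)
  }
  expect_error(ripening_rhs_2d(c(1, -0.1), pr2), "positive")
})

test_that("a single droplet is stationary", {
  pr <- ripening_params(0.1, 1, dimension = 2, eps = 0.02)
  tr <- integrate_ripening(0.8, pr, horizon = 10)
  expect_true(all(tr$radii[, 1] == 0.8))
})

test_that("3D coarsening ends in a single droplet carrying all the mass", {
  pr <- ripening_params(0.1, 1, l_c = 1, dimension = 3)
  set.seed(7)
  r0 <- runif(5, 0.5, 1.5)
  tr <- integrate_ripening(r0, pr, horizon = 200)
  alive_end <- tr$alive[nrow(tr$alive), ]
  expect_equal(sum(alive_end), 1L)
  surv <- tr$radii[nrow(tr$radii), alive_end]
  expect_lt(abs(surv / sum(r0^3)^(1 / 3) - 1), 1e-3)
  # conserved mass between events
  expect_lt((max(tr$mass) - min(tr$mass)) / tr$mass[1], 1e-6)
  # droplet count non-increasing; min alive radius below the mean shrinks
  counts <- rowSums(tr$alive)
  expect_true(all(diff(counts) <= 0))
})

test_that("critical radius grows across extinction events", {
  pr <- ripening_params(0.1, 1, l_c = 1, dimension = 3)
  set.seed(9)
  tr <- integrate_ripening(runif(4, 0.5, 1.5), pr, horizon = 300)
  # sample the alive-mean just after each extinction and at the ends
  ev <- sort(stats::na.omit(tr$extinction_times))
  rows <- c(1L, vapply(ev, function(tt) which(tr$time > tt)[1], 1L),
            nrow(tr$radii))
  means <- vapply(rows, function(i) {
    r <- tr$radii[i, ]; mean(r[!is.na(r)])
  }, 0)
  expect_true(all(diff(means) > -1e-8))
})

test_that("equal radii are an unstable fixed point", {
  pr <- ripening_params(0.1, 1, dimension = 2, eps = 0.02)
  r0 <- c(1, 1, 1) + c(1e-6, 0, 0)
  tr <- integrate_ripening(r0, pr, horizon = 200, n_out = 200)
  dev <- abs(tr$radii[, 1] - tr$radii[, 2])
  expect_true(all(diff(dev[dev < 0.1]) > 0))   # monotone divergence early on
  expect_gt(dev[length(dev)], 2e-5)  # ~20-fold amplification
})

test_that("2D extinction time matches a fixed-step RK4 oracle", {
  pr <- ripening_params(0.5, 1, dimension = 2, eps = 0.02)
  r0 <- c(0.9, 1.1)
  thr <- pr$extinction_threshold * mean(r0)
  tr <- integrate_ripening(r0, pr, horizon = 50)
  t_ext <- tr$extinction_times[1]
  expect_false(is.na(t_ext))
  # brute-force fixed-step RK4 at dt = 1e-5 until the threshold crossing
  dt <- 1e-5
  y <- r0; t <- 0
  f <- function(y) ripening_rhs_2d(pmax(y, thr / 10), pr)
  repeat {
    k1 <- f(y); k2 <- f(y + dt / 2 * k1); k3 <- f(y + dt / 2 * k2)
    k4 <- f(y + dt * k3)
    ynew <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    t <- t + dt
    if (min(ynew) < thr) {
      # linear interpolation to the crossing
      fr <- (min(y) - thr) / (min(y) - min(ynew))
      t <- t - dt + fr * dt
      break
    }
    y <- ynew
    if (t > 50) break
  }
  expect_lt(abs(t_ext / t - 1), 1e-3)
})
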