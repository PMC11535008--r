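# Green's function providers: symmetry, singular structure, normalisation,
# truncation robustness, s-derivative, and the finite-difference PDE oracle.

test_that("Green's functions are symmetric in their arguments", {
  cases <- list(
    list(dom = disk_domain(1), x = c(0.35, -0.2), y = c(-0.4, 0.3)),
    list(dom = rect_domain(2, size = c(1.4, 1)), x = c(0.4, 0.3),
         y = c(1.1, 0.7)),
    list(dom = sphere_domain(1.5), x = c(0.3, 0.1, -0.2),
         y = c(-0.3, 0.4, 0.25)),
    list(dom = box_domain(2), x = c(0.5, 0.3, 0.6), y = c(0.8, 0.7, 0.3)))
  for (cs in cases) {
    p <- make_greens_provider(cs$dom)
    g1 <- greens_value(p, rbind(cs$y), cs$x)
    g2 <- greens_value(p, rbind(cs$x), cs$y)
    expect_lt(abs(g1 - g2), 1e-9)
    g1 <- greens_pseudo(p, rbind(cs$y), cs$x)
    g2 <- greens_pseudo(p, rbind(cs$x), cs$y)
    expect_lt(abs(g1 - g2), 1e-9)
  }
})

test_that("small-separation behaviour approaches the free-space singularity", {
  p2 <- make_greens_provider(disk_domain(1))
  x0 <- c(0.3, 0.2)
  ratios <- vapply(c(1e-4, 1e-8, 1e-12), function(d)
    greens_value(p2, rbind(x0 + c(d, 0)), x0) / (-log(d) / (2 * pi)), 0)
  # the log singularity dominates progressively (the regular part is O(1))
  expect_true(all(diff(abs(ratios - 1)) < 0))
  expect_lt(abs(ratios[3] - 1), 0.06)
  p3 <- make_greens_provider(sphere_domain(1))
  y0 <- c(0.2, -0.1, 0.3)
  r3 <- greens_value(p3, rbind(y0 + c(1e-7, 0, 0)), y0) * (4 * pi * 1e-7)
  expect_lt(abs(r3 - 1), 1e-5)
})

test_that("normalisation identities hold on disk and rectangle", {
  p <- make_greens_provider(disk_domain(1))
  nr <- greens_normalization(p, c(0.3, 0.2))
  expect_lt(abs(nr$residual) * 1, 1e-6)
  n0 <- greens_normalization(p, c(0.3, 0.2), pseudo = TRUE)
  expect_lt(abs(n0$residual), 1e-6)
  pr <- make_greens_provider(rect_domain(2, size = c(1, 1)))
  nr <- greens_normalization(pr, c(0.4, 0.6))
  expect_lt(abs(nr$residual) * 2, 1e-6)  # relative to 1/gamma0
  n0 <- greens_normalization(pr, c(0.4, 0.6), pseudo = TRUE)
  expect_lt(abs(n0$residual), 1e-6)
})

test_that("regular parts agree with Richardson-extrapolated limits", {
  for (dom in list(disk_domain(1.3), rect_domain(0.7, size = c(1.2, 1)))) {
    p <- make_greens_provider(dom)
    x0 <- if (dom$kind == "disk2d") c(0.25, -0.3) else c(0.5, 0.45)
    R <- greens_regular(p, x0)
    f <- function(d) greens_value(p, rbind(x0 + c(d, 0)), x0) +
      log(d) / (2 * pi * dom$D)
    # values approach R linearly in d; Richardson-extrapolate the sequence
    v1 <- f(1e-3); v2 <- f(5e-4)
    expect_lt(abs((2 * v2 - v1) - R), 1e-6)
  }
  pb <- make_greens_provider(box_domain(1.5))
  x0 <- c(0.45, 0.55, 0.5)
  R <- greens_regular(pb, x0)
  f <- function(d) greens_value(pb, rbind(x0 + c(d, 0, 0)), x0) -
    1 / (4 * pi * pb$domain$D * d)
  v1 <- f(2e-3); v2 <- f(1e-3)
  expect_lt(abs((2 * v2 - v1) - R), 1e-6)
})

test_that("rotational symmetry of the disk regular part at the centre", {
  p <- make_greens_provider(disk_domain(2))
  # R at a fixed radius is independent of the angular position
  vals <- vapply(c(0, pi / 3, 1.2, 2.5), function(th)
    greens_regular(p, 0.4 * c(cos(th), sin(th))), 0)
  expect_lt(diff(range(vals)), 1e-10)
})

test_that("truncation self-consistency: tighter tolerance changes G marginally", {
  dom <- rect_domain(1.5, size = c(1, 1))
  p1 <- make_greens_provider(dom, tol = 1e-8)
  p2 <- make_greens_provider(dom, tol = 1e-14)
  g1 <- greens_value(p1, rbind(c(0.7, 0.6)), c(0.3, 0.2))
  g2 <- greens_value(p2, rbind(c(0.7, 0.6)), c(0.3, 0.2))
  expect_lt(abs(g1 - g2), 1e-8)
  d1 <- make_greens_provider(disk_domain(1), tol = 1e-8)
  d2 <- make_greens_provider(disk_domain(1), tol = 1e-14)
  expect_lt(abs(greens_regular(d1, c(0.4, 0.1)) -
                  greens_regular(d2, c(0.4, 0.1))), 1e-8)
})

test_that("s-derivative: analytic image sums match finite differences", {
  p <- make_greens_provider(rect_domain(1, size = c(1, 1)))
  x0 <- c(0.35, 0.55); x1 <- c(0.8, 0.25)
  H <- greens_s_derivative(p, rbind(x1), x0)
  h <- 1e-4
  Hfd <- (greens_value(p, rbind(x1), x0, h) -
            greens_value(p, rbind(x1), x0, -h)) / (2 * h)
  expect_lt(abs(H - Hfd), 1e-6)
  # symmetry inherited from G
  expect_lt(abs(H - greens_s_derivative(p, rbind(x0), x1)), 1e-10)
  # screened kernels decrease with rate: dG/ds < 0
  expect_lt(H, 0)
  pb <- make_greens_provider(box_domain(1.5))
  Hb <- greens_s_derivative(pb, rbind(c(0.7, 0.4, 0.6)), c(0.3, 0.5, 0.4))
  Hbfd <- (greens_value(pb, rbind(c(0.7, 0.4, 0.6)), c(0.3, 0.5, 0.4), h) -
             greens_value(pb, rbind(c(0.7, 0.4, 0.6)), c(0.3, 0.5, 0.4),
                          -h)) / (2 * h)
  expect_lt(abs(Hb - Hbfd), 1e-6)
  expect_lt(Hb, 0)
})

test_that("disk Green's function matches a dense finite-difference solve", {
  p <- make_greens_provider(disk_domain(1))
  x0 <- c(0.3, 0.2)
  fdg <- fd_solve_disk_greens(x0, D = 1, gamma0 = 1, n_r = 300, n_th = 256)
  pts <- rbind(c(-0.4, 0.3), c(0.1, -0.5), c(0.7, 0.1))
  rel <- abs(fdg$interp(pts) / greens_value(p, pts, x0) - 1)
  expect_lt(max(rel), 1e-3)
})

test_that("boundary Neumann condition holds along the outer normal", {
  p <- make_greens_provider(disk_domain(1))
  x0 <- c(0.3, 0.2)
  u <- c(cos(0.8), sin(0.8))
  h <- 1e-4
  g <- greens_value(p, rbind(u, u * (1 - h), u * (1 - 2 * h)), x0)
  expect_lt(abs((3 * g[1] - 4 * g[2] + g[3]) / (2 * h)), 1e-5)
})

test_that("provider contracts: errors for unsupported input", {
  expect_error(domain_spec("hexagon"), "arg")
  p <- make_greens_provider(disk_domain(1))
  expect_error(greens_value(p, rbind(c(0.3, 0.2)), c(0.3, 0.2)),
               "coincident")
  p0 <- make_greens_provider(disk_domain(0))
  expect_error(greens_value(p0, rbind(c(0.5, 0)), c(0, 0)), "pseudo")
  expect_error(greens_regular(p, c(0.999, 0)), "boundary")
  expect_error(greens_s_derivative(p0, rbind(c(0.5, 0)), c(0, 0)),
               "pole at s=0")
  expect_error(greens_value(p, rbind(c(2, 0)), c(0, 0)), "outside")
})
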