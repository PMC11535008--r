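# Monte-Carlo finite-difference oracle for volume transmission.
#
# Direct simulation of the switching PDE on a cell-centred rectangular grid:
# in the firing state each varicosity injects flux J_j spread over its cut
# cells (total influx 2 pi eps ell_j J_j exact); in the quiescent state the
# interface is absorbing (Shortley-Weller Dirichlet 0).  Backward-Euler
# stepping with both operators factorised once makes the stepper
# unconditionally stable, so no CFL restriction applies.  Conditional means
# at the probes are time-averaged over a late window and across independent
# replicates; standard errors come from the replicate spread.

# operators for the two boundary states on a shared active-cell set
fd_operator_switching <- function(config, h, J) {
  # Dirichlet-0 operator (quiescent): reuse the embedded Dirichlet build
  cfg0 <- config
  cfg0$compartments <- lapply(config$compartments, function(cmp) {
    cmp$c0 <- 0; cmp
  })
  opd <- fd_operator_2d(cfg0, h)
  dom <- config$domain
  nx <- opd$nx; ny <- opd$ny
  eps <- config$epsilon
  radii <- eps * config_field(config, "ell")
  X <- config$centres
  # flux operator: plain 5-point Laplacian on active cells with reflecting
  # interface; couplings only between mutually active cells
  active <- opd$active; amap <- opd$amap
  na <- length(active)
  ix <- ((active - 1L) %% nx) + 1L
  iy <- ((active - 1L) %/% nx) + 1L
  ii <- integer(0); jj <- integer(0); vv <- numeric(0)
  diagv <- numeric(na)
  for (o in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
    nxi <- ix + o[1]; nyi <- iy + o[2]
    inb <- nxi >= 1 & nxi <= nx & nyi >= 1 & nyi <= ny
    nidx <- (pmax(nyi, 1L) - 1L) * nx + pmax(nxi, 1L)
    ok <- inb & amap[nidx] > 0
    sel <- which(ok)
    ii <- c(ii, sel); jj <- c(jj, amap[nidx[sel]])
    vv <- c(vv, rep(1 / h^2, length(sel)))
    diagv[sel] <- diagv[sel] - 1 / h^2
  }
  ii <- c(ii, seq_len(na)); jj <- c(jj, seq_len(na)); vv <- c(vv, diagv)
  Lf <- Matrix::sparseMatrix(i = ii, j = jj, x = vv, dims = c(na, na))
  # firing source: total release 2 pi r_j J_j split over the cut cells
  src <- numeric(na)
  px <- opd$xc[ix]; py <- opd$yc[iy]
  for (j in seq_len(nrow(X))) {
    d <- sqrt((px - X[j, 1])^2 + (py - X[j, 2])^2)
    cut <- which(d >= radii[j] & d < radii[j] + 1.5 * h)
    if (!length(cut)) stop("unresolved compartment in switching oracle")
    src[cut] <- src[cut] + 2 * pi * radii[j] * J[j] / (length(cut) * h^2)
  }
  list(op_dirichlet = opd, L_flux = Lf, src_firing = src, active = active,
       nx = nx, ny = ny, h = h, xc = opd$xc, yc = opd$yc)
}

#' Monte-Carlo conditional means for the switching problem
#'
#' @param scfg a [switching_config()] on a `rect2d` domain.
#' @param h grid spacing.
#' @param horizon per-replicate simulated time.
#' @param burnin initial fraction of the horizon discarded.
#' @param reps number of independent replicates.
#' @param dt backward-Euler step.
#' @param probes matrix of probe points.
#' @param seed RNG seed.
#' @return list with conditional means `ubar0`, `ubar1` (and their standard
#'   errors), the empirical firing occupancy, and metadata.
#' @export
simulate_switching_fd <- function(scfg, h, horizon, reps, probes,
                                  burnin = 0.5, dt = 0.02, seed = 1L) {
  config <- scfg$config
  if (config$domain$kind != "rect2d")
    stop("the switching oracle runs on rect2d domains")
  probes <- rbind(probes)
  ops <- fd_operator_switching(config, h, scfg$J)
  D <- config$domain$D
  na <- length(ops$active)
  I <- Matrix::Diagonal(na)
  lu_f <- Matrix::lu(I - dt * D * ops$L_flux)
  Ld <- D * ops$op_dirichlet$L
  lu_d <- Matrix::lu(I - dt * Ld)
  # probe extraction weights (bilinear on active cells)
  probe_of <- function(u) fd_interp_2d(ops$op_dirichlet, u)(probes)
  set.seed(seed)
  nsteps <- ceiling(horizon / dt)
  nburn <- ceiling(burnin * nsteps)
  m0 <- matrix(0, reps, nrow(probes)); m1 <- matrix(0, reps, nrow(probes))
  occ <- numeric(reps)
  for (r in seq_len(reps)) {
    u <- numeric(na)
    state <- as.integer(stats::runif(1) < scfg$rho_firing)  # 1 = firing
    steps_left <- 0L
    acc0 <- numeric(nrow(probes)); acc1 <- numeric(nrow(probes))
    n0 <- 0L; n1 <- 0L
    for (k in seq_len(nsteps)) {
      if (steps_left <= 0L) {
        rate <- if (state == 1L) scfg$alpha else scfg$beta
        steps_left <- max(1L, round(stats::rexp(1, rate) / dt))
      }
      if (state == 1L) {
        u <- as.vector(Matrix::solve(lu_f, u + dt * D * 0 + dt * ops$src_firing))
      } else {
        u <- as.vector(Matrix::solve(lu_d, u))
      }
      steps_left <- steps_left - 1L
      if (k > nburn) {
        pv <- probe_of(u)
        if (state == 1L) { acc1 <- acc1 + pv; n1 <- n1 + 1L }
        else { acc0 <- acc0 + pv; n0 <- n0 + 1L }
      }
      if (steps_left == 0L) state <- 1L - state
    }
    ntot <- n0 + n1
    m0[r, ] <- acc0 / ntot   # E[u 1_{quiescent}]
    m1[r, ] <- acc1 / ntot   # E[u 1_{firing}]
    occ[r] <- n1 / ntot
  }
  list(ubar0 = colMeans(m0), ubar1 = colMeans(m1),
       se0 = apply(m0, 2, stats::sd) / sqrt(reps),
       se1 = apply(m1, 2, stats::sd) / sqrt(reps),
       occupancy_firing = mean(occ),
       occupancy_se = stats::sd(occ) / sqrt(reps),
       reps = reps, dt = dt, h = h)
}
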