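# Finite-difference oracles.
#
# Three independent discretisations back-stop the asymptotics:
#  * fd_solve_radial: boundary-fitted 1D radial scheme for the concentric
#    annulus/shell, second order, certifying the Robin implementation;
#  * fd_solve_disk_greens: finite-volume polar scheme on the unit disk with a
#    mollified point source, oracle for the disk Green's function;
#  * fd_solve_2d: cell-centred Cartesian scheme on a rectangle with embedded
#    circular Dirichlet compartments (Shortley-Weller corrections, globally
#    second order), plus Crank-Nicolson time stepping for relaxation studies.

#' Radial finite-difference solve (annulus 2D / shell 3D)
#'
#' @inheritParams exact_annulus_2d
#' @param n number of radial intervals.
#' @param dim 2 (annulus) or 3 (shell).
#' @return list with `r`, `u` and the interpolating function.
#' @export
fd_solve_radial <- function(ell, eps, kappa, c0, D, gamma0, n = 400,
                            dim = 2) {
  a <- eps * ell
  h <- (1 - a) / n
  r <- a + h * (0:n)
  m <- n + 1L
  # tridiagonal system with ghost-node boundary treatment
  lower <- numeric(m); main <- numeric(m); upper <- numeric(m)
  rhs <- numeric(m)
  dcoef <- (dim - 1)
  for (i in 2:(m - 1)) {
    ri <- r[i]
    lower[i] <- D * (1 / h^2 - dcoef / (2 * ri * h))
    main[i] <- -2 * D / h^2 - gamma0
    upper[i] <- D * (1 / h^2 + dcoef / (2 * ri * h))
  }
  k_eff <- kappa / eps
  if (is.finite(kappa)) {
    # ghost point at a - h: interior equation + Robin D u'(a) = k_eff (u - c0)
    # u' ~ (u_2 - u_0)/(2h)  =>  u_0 = u_2 - (2h k_eff/D)(u_1 - c0)
    main[1] <- -2 * D / h^2 - gamma0 -
      (D / h^2 - D * dcoef / (2 * r[1] * h)) * (2 * h * k_eff / D)
    upper[1] <- 2 * D / h^2
    rhs[1] <- -(D / h^2 - D * dcoef / (2 * r[1] * h)) *
      (2 * h * k_eff / D) * c0
  } else {
    main[1] <- 1; upper[1] <- 0; rhs[1] <- c0
  }
  # Neumann at r = 1 (ghost at 1 + h equal to u_{m-1})
  lower[m] <- 2 * D / h^2
  main[m] <- -2 * D / h^2 - gamma0
  rhs[m] <- 0
  A <- Matrix::bandSparse(m, m, k = c(-1, 0, 1),
                          diagonals = list(lower[-1], main, upper[-m]))
  u <- as.vector(Matrix::solve(A, rhs))
  list(r = r, u = u, interp = stats::approxfun(r, u))
}

#' Finite-volume polar solve of the Green's PDE on the unit disk
#'
#' Solves \eqn{D\nabla^2 G - \gamma_0 G = -\delta_w(x - x_0)} with a
#' mollified source of total mass 1 and reflecting outer boundary, on a
#' cell-centred polar grid (the zero-radius face carries no flux, so the
#' origin needs no special casing).
#'
#' @param x0 source location.
#' @param D,gamma0 coefficients (`gamma0 > 0`).
#' @param n_r,n_th grid resolution.
#' @param width mollifier radius (default 6 radial cells).
#' @return list with grid vectors, the solution matrix `G[r, theta]` and a
#'   bilinear interpolator `interp(x)`.
#' @export
fd_solve_disk_greens <- function(x0, D = 1, gamma0 = 1, n_r = 300,
                                 n_th = 256, width = NULL) {
  h_r <- 1 / n_r
  h_t <- 2 * pi / n_th
  if (is.null(width)) width <- 6 * h_r
  r_c <- (seq_len(n_r) - 0.5) * h_r
  th_c <- (seq_len(n_th) - 0.5) * h_t
  idx <- function(i, j) (j - 1L) * n_r + i     # i radial, j angular
  nn <- n_r * n_th
  ii <- integer(0); jj <- integer(0); vv <- numeric(0)
  push <- function(a, b, v) {
    ii <<- c(ii, a); jj <<- c(jj, b); vv <<- c(vv, v)
  }
  # assemble vectorised by bands
  i_all <- rep(seq_len(n_r), n_th)
  j_all <- rep(seq_len(n_th), each = n_r)
  r_all <- r_c[i_all]
  area <- r_all * h_r * h_t
  # radial faces
  rp <- r_all + h_r / 2; rm <- r_all - h_r / 2
  cp <- D * rp * h_t / h_r   # coupling to i+1 (zero at i = n_r: Neumann)
  cm <- D * rm * h_t / h_r   # coupling to i-1 (rm = 0 at i = 1: no flux)
  cp[i_all == n_r] <- 0
  ct <- D * h_r / (r_all * h_t)  # angular couplings (periodic)
  diagv <- -(cp + cm + 2 * ct) - gamma0 * area
  k <- idx(i_all, j_all)
  push(k, k, diagv)
  sel <- i_all < n_r
  push(k[sel], idx(i_all[sel] + 1L, j_all[sel]), cp[sel])
  sel <- i_all > 1
  push(k[sel], idx(i_all[sel] - 1L, j_all[sel]), cm[sel])
  jp <- ifelse(j_all == n_th, 1L, j_all + 1L)
  jm <- ifelse(j_all == 1L, n_th, j_all - 1L)
  push(k, idx(i_all, jp), ct)
  push(k, idx(i_all, jm), ct)
  A <- Matrix::sparseMatrix(i = ii, j = jj, x = vv, dims = c(nn, nn))
  # mollified source, normalised to unit discrete mass
  xx <- r_all * cos(th_c[j_all]); yy <- r_all * sin(th_c[j_all])
  t2 <- ((xx - x0[1])^2 + (yy - x0[2])^2) / width^2
  src <- ifelse(t2 < 1, exp(-1 / pmax(1 - t2, 1e-300)), 0)
  src <- src / sum(src * area)
  b <- -src * area
  G <- as.vector(Matrix::solve(A, b))
  Gm <- matrix(G, n_r, n_th)
  interp <- function(x) {
    x <- rbind(x)
    r <- sqrt(rowSums(x^2))
    th <- atan2(x[, 2], x[, 1]) %% (2 * pi)
    fi <- pmin(pmax(r / h_r + 0.5, 1), n_r)
    fj <- th / h_t + 0.5
    i0 <- pmin(pmax(floor(fi), 1), n_r - 1); wi <- fi - i0
    j0 <- floor(fj); wj <- fj - j0
    j0w <- ((j0 - 1) %% n_th) + 1; j1w <- (j0 %% n_th) + 1
    Gm[cbind(i0, j0w)] * (1 - wi) * (1 - wj) +
      Gm[cbind(i0 + 1, j0w)] * wi * (1 - wj) +
      Gm[cbind(i0, j1w)] * (1 - wi) * wj +
      Gm[cbind(i0 + 1, j1w)] * wi * wj
  }
  list(r = r_c, theta = th_c, G = Gm, interp = interp, width = width)
}

# ---- rectangle with embedded circular Dirichlet compartments ---------------

# Shortley-Weller crossing fraction along an axis from active point p to
# neighbour q (q inside circle(centre, a)); returns theta in (0, 1]
sw_theta <- function(p, q, centre, a) {
  d <- q - p
  f <- p - centre
  A <- sum(d^2); B <- 2 * sum(f * d); C <- sum(f^2) - a^2
  disc <- sqrt(max(B^2 - 4 * A * C, 0))
  t <- (-B - disc) / (2 * A)
  if (t <= 0 || t > 1) t <- (-B + disc) / (2 * A)
  min(max(t, 1e-6), 1)
}

#' Build the embedded-boundary FD operator on a rectangle
#'
#' Cell-centred grid; reflecting outer faces; circular compartments imposed
#' as Dirichlet data through Shortley-Weller corrected stencils.  Used for
#' both steady solves and Crank-Nicolson relaxation.
#'
#' @param config a 2D [compartment_configuration()] on a `rect2d` domain
#'   (compartments must be Dirichlet, `kappa = Inf`).
#' @param h grid spacing (must resolve every compartment with >= 8 cells
#'   across its diameter).
#' @return list with operator pieces (`L`, `b_dirichlet`), the active-cell
#'   index map and grid metadata.
#' @export
fd_operator_2d <- function(config, h) {
  dom <- config$domain
  if (dom$kind != "rect2d") stop("fd_operator_2d expects a rect2d domain")
  for (cmp in config$compartments) {
    if (!is.finite(cmp$kappa))
      next
    stop("embedded compartments must be Dirichlet (kappa = Inf); finite ",
         "kappa is certified by the boundary-fitted radial solver")
  }
  eps <- config$epsilon
  radii <- eps * config_field(config, "ell")
  if (any(2 * radii / h < 8))
    stop("unresolved compartments: fewer than 8 cells across a diameter")
  nx <- round(dom$size[1] / h); ny <- round(dom$size[2] / h)
  xc <- (seq_len(nx) - 0.5) * h; yc <- (seq_len(ny) - 0.5) * h
  X <- config$centres
  # classify cells
  gx <- rep(xc, ny); gy <- rep(yc, each = nx)
  inside <- rep(FALSE, nx * ny)
  for (j in seq_len(nrow(X)))
    inside <- inside | ((gx - X[j, 1])^2 + (gy - X[j, 2])^2 < radii[j]^2)
  active <- which(!inside)
  amap <- integer(nx * ny); amap[active] <- seq_along(active)
  na <- length(active)
  ii <- integer(0); jj <- integer(0); vv <- numeric(0)
  bd <- numeric(na)       # Dirichlet contribution (per unit boundary value,
                          # scaled by compartment c0 set below)
  bwhich <- integer(na)   # which compartment the correction came from
  c0s <- config_field(config, "c0")
  add <- function(a, b, v) {
    ii <<- c(ii, a); jj <<- c(jj, b); vv <<- c(vv, v)
  }
  offs <- list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))
  ix_all <- ((active - 1L) %% nx) + 1L
  iy_all <- ((active - 1L) %/% nx) + 1L
  px <- xc[ix_all]; py <- yc[iy_all]
  diagv <- numeric(na)
  for (o in offs) {
    nxi <- ix_all + o[1]; nyi <- iy_all + o[2]
    inb <- nxi >= 1 & nxi <= nx & nyi >= 1 & nyi <= ny
    nidx <- ifelse(inb, (pmax(nyi, 1) - 1L) * nx + pmax(nxi, 1), NA_integer_)
    nact <- inb & !is.na(nidx) & amap[ifelse(is.na(nidx), 1L, nidx)] > 0 &
      !inside[ifelse(is.na(nidx), 1L, nidx)]
    # outer boundary: reflecting -> no coupling, no diagonal contribution
    # (zero-flux face), handled by simply skipping out-of-range neighbours
    for (kcase in c("active", "cut")) {
      if (kcase == "active") {
        sel <- which(nact)
        if (length(sel)) {
          add(sel, amap[nidx[sel]], rep(1 / h^2, length(sel)))
          diagv[sel] <- diagv[sel] - 1 / h^2
        }
      } else {
        sel <- which(inb & !nact)
        for (s in sel) {
          p <- c(px[s], py[s]); q <- p + c(o[1], o[2]) * h
          # find the compartment cutting this segment
          jc <- which((q[1] - X[, 1])^2 + (q[2] - X[, 2])^2 < radii^2)[1]
          th <- sw_theta(p, q, X[jc, ], radii[jc])
          # u'' ~ 2 [ g/(th(th+1)) + u_opp/(th+1) - u_P/th ] / h^2 ; the
          # u_opp part is the regular neighbour on the other side, already
          # added with weight 1/h^2 -- adjust to 2/((1+th) h^2) by a
          # correction below; here add the boundary and centre terms.
          diagv[s] <- diagv[s] - 2 / (th * h^2) + 1 / h^2
          bd[s] <- bd[s] + 2 * c0s[jc] / (th * (th + 1) * h^2)
          bwhich[s] <- jc
          # correction for the opposite neighbour weight
          oo <- -o
          qx <- ix_all[s] + oo[1]; qy <- iy_all[s] + oo[2]
          if (qx >= 1 && qx <= nx && qy >= 1 && qy <= ny) {
            qidx <- (qy - 1L) * nx + qx
            if (amap[qidx] > 0) {
              add(s, amap[qidx], 2 / ((1 + th) * h^2) - 1 / h^2)
            }
          }
        }
      }
    }
  }
  add(seq_len(na), seq_len(na), diagv)
  L <- Matrix::sparseMatrix(i = ii, j = jj, x = vv, dims = c(na, na))
  list(L = L, b = bd, active = active, amap = amap, nx = nx, ny = ny,
       h = h, xc = xc, yc = yc, inside = inside, config = config)
}

#' Steady embedded-boundary solve on a rectangle
#'
#' Solves \eqn{D\nabla^2 u - \gamma_0 u + \mathcal{I}_0 = 0} with reflecting
#' outer walls and Dirichlet compartments.
#' @inheritParams fd_operator_2d
#' @return list with the operator info, solution vector `u` (active cells)
#'   and an interpolator `interp(x)` (NA inside compartments).
#' @export
fd_solve_2d <- function(config, h) {
  op <- fd_operator_2d(config, h)
  dom <- config$domain
  A <- dom$D * op$L - Matrix::Diagonal(length(op$active), dom$gamma0)
  rhs <- -dom$D * op$b - rep(dom$I0, length(op$active))
  u <- as.vector(Matrix::solve(A, rhs))
  list(op = op, u = u, interp = fd_interp_2d(op, u))
}

# bilinear interpolation over active cells (falls back to nearest active)
fd_interp_2d <- function(op, u) {
  full <- rep(NA_real_, op$nx * op$ny)
  full[op$active] <- u
  Gm <- matrix(full, op$nx, op$ny)
  function(x) {
    x <- rbind(x)
    fi <- pmin(pmax(x[, 1] / op$h + 0.5, 1), op$nx)
    fj <- pmin(pmax(x[, 2] / op$h + 0.5, 1), op$ny)
    i0 <- pmin(pmax(floor(fi), 1), op$nx - 1); wi <- fi - i0
    j0 <- pmin(pmax(floor(fj), 1), op$ny - 1); wj <- fj - j0
    Gm[cbind(i0, j0)] * (1 - wi) * (1 - wj) +
      Gm[cbind(i0 + 1, j0)] * wi * (1 - wj) +
      Gm[cbind(i0, j0 + 1)] * (1 - wi) * wj +
      Gm[cbind(i0 + 1, j0 + 1)] * wi * wj
  }
}

#' Time-dependent embedded-boundary solve (Crank-Nicolson)
#'
#' Integrates \eqn{\partial_t u = D\nabla^2 u - \gamma_0 u} from `u0_fun`
#' with Dirichlet compartments, recording the solution at the probe points
#' at every step.  The implicit matrix is factorised once.
#'
#' @inheritParams fd_operator_2d
#' @param u0_fun initial condition, function of a point matrix.
#' @param horizon final time.
#' @param dt time step.
#' @param probes matrix of probe points.
#' @return list with `times`, `u_probe` (times x probes matrix) and the
#'   final-state interpolator.
#' @export
fd_transient_2d <- function(config, h, u0_fun, horizon, dt, probes) {
  op <- fd_operator_2d(config, h)
  dom <- config$domain
  probes <- rbind(probes)
  na <- length(op$active)
  Lop <- dom$D * op$L - Matrix::Diagonal(na, dom$gamma0)
  bvec <- dom$D * op$b + rep(dom$I0, na)
  I <- Matrix::Diagonal(na)
  Aimp <- I - (dt / 2) * Lop
  Aexp <- I + (dt / 2) * Lop
  lu <- Matrix::lu(Aimp)
  gx <- op$xc[((op$active - 1L) %% op$nx) + 1L]
  gy <- op$yc[((op$active - 1L) %/% op$nx) + 1L]
  u <- u0_fun(cbind(gx, gy))
  nt <- ceiling(horizon / dt)
  up <- matrix(0, nt + 1L, nrow(probes))
  itp <- fd_interp_2d(op, u)
  up[1, ] <- itp(probes)
  for (k in seq_len(nt)) {
    rhs <- Aexp %*% u + dt * bvec
    u <- as.vector(Matrix::solve(lu, rhs))
    itp <- fd_interp_2d(op, u)
    up[k + 1L, ] <- itp(probes)
  }
  list(times = dt * (0:nt), u_probe = up, interp = itp, op = op, u = u)
}
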