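#' Bulk domain specification
#'
#' Describes the bounded bulk domain \eqn{\Omega} in which particles diffuse:
#' its geometry (unit disk or rectangle in 2D, unit sphere or box in 3D),
#' the bulk diffusivity \eqn{D}, the degradation rate \eqn{\gamma_0 \ge 0}
#' and a spatially uniform source \eqn{\mathcal{I}_0}.  Lengths are
#' non-dimensionalised so that the smallest inscribed dimension is 1.
#'
#' @param kind one of `"disk2d"`, `"rect2d"`, `"sphere3d"`, `"box3d"`.
#' @param size for `rect2d` a length-2 vector of side lengths, for `box3d` a
#'   length-3 vector; ignored (fixed unit radius) for `disk2d`/`sphere3d`.
#' @param D bulk diffusivity (length^2/time), strictly positive.
#' @param gamma0 degradation rate (1/time), non-negative.  `gamma0 = 0`
#'   selects the pseudo-Green's function machinery in downstream solvers.
#' @param I0 uniform volumetric source (concentration/time), default 0.
#'
#' @return an object of class `"domain_spec"` with fields `kind`, `size`,
#'   `dim`, `D`, `gamma0`, `I0` and `volume` (area in 2D).
#' @export
domain_spec <- function(kind = c("disk2d", "rect2d", "sphere3d", "box3d"),
                        size = NULL, D = 1, gamma0 = 1, I0 = 0) {
  kind <- match.arg(kind)
  if (!is.numeric(D) || length(D) != 1L || D <= 0)
    stop("D must be a single positive number")
  if (!is.numeric(gamma0) || length(gamma0) != 1L || gamma0 < 0)
    stop("gamma0 must be a single non-negative number")
  if (!is.numeric(I0) || length(I0) != 1L || I0 < 0)
    stop("I0 must be a single non-negative number")
  dim <- if (kind %in% c("disk2d", "rect2d")) 2L else 3L
  size <- switch(kind,
    disk2d = 1,
    sphere3d = 1,
    rect2d = {
      if (is.null(size)) size <- c(1, 1)
      if (length(size) != 2L || any(size <= 0))
        stop("rect2d needs two positive side lengths")
      if (min(size) != 1)
        stop("sizes are normalised so the smallest inscribed dimension is 1; ",
             "min(size) must equal 1")
      size
    },
    box3d = {
      if (is.null(size)) size <- c(1, 1, 1)
      if (length(size) != 3L || any(size <= 0))
        stop("box3d needs three positive side lengths")
      if (min(size) != 1)
        stop("sizes are normalised so the smallest inscribed dimension is 1; ",
             "min(size) must equal 1")
      size
    })
  volume <- switch(kind,
    disk2d = pi,
    rect2d = prod(size),
    sphere3d = 4 * pi / 3,
    box3d = prod(size))
  structure(list(kind = kind, size = size, dim = dim, D = D,
                 gamma0 = gamma0, I0 = I0, volume = volume),
            class = "domain_spec")
}

#' @export
print.domain_spec <- function(x, ...) {
  cat(sprintf("<domain_spec> %s  size=(%s)  D=%g  gamma0=%g  I0=%g\n",
              x$kind, paste(signif(x$size, 6), collapse = ", "),
              x$D, x$gamma0, x$I0))
  invisible(x)
}

# is a point (row of a matrix or plain vector) strictly inside the domain?
domain_contains <- function(domain, x, margin = 0) {
  x <- rbind(x)
  switch(domain$kind,
    disk2d   = sqrt(rowSums(x^2)) < 1 - margin,
    sphere3d = sqrt(rowSums(x^2)) < 1 - margin,
    rect2d   = x[, 1] > margin & x[, 1] < domain$size[1] - margin &
               x[, 2] > margin & x[, 2] < domain$size[2] - margin,
    box3d    = x[, 1] > margin & x[, 1] < domain$size[1] - margin &
               x[, 2] > margin & x[, 2] < domain$size[2] - margin &
               x[, 3] > margin & x[, 3] < domain$size[3] - margin)
}

# distance of interior point x to the outer boundary
domain_boundary_distance <- function(domain, x) {
  x <- rbind(x)
  switch(domain$kind,
    disk2d   = 1 - sqrt(rowSums(x^2)),
    sphere3d = 1 - sqrt(rowSums(x^2)),
    rect2d   = pmin(x[, 1], domain$size[1] - x[, 1],
                    x[, 2], domain$size[2] - x[, 2]),
    box3d    = pmin(x[, 1], domain$size[1] - x[, 1],
                    x[, 2], domain$size[2] - x[, 2],
                    x[, 3], domain$size[3] - x[, 3]))
}

# distance from point x along unit direction u to the outer boundary
# (used by the polar/spherical quadrature rules); x interior.
domain_ray_length <- function(domain, x, u) {
  switch(domain$kind,
    disk2d = , sphere3d = {
      # |x + t u| = 1  =>  t^2 + 2 t (x.u) + |x|^2 - 1 = 0
      b <- sum(x * u); c0 <- sum(x^2) - 1
      -b + sqrt(b * b - c0)
    },
    rect2d = , box3d = {
      t <- Inf
      for (i in seq_along(x)) {
        if (u[i] > 1e-300) t <- min(t, (domain$size[i] - x[i]) / u[i])
        if (u[i] < -1e-300) t <- min(t, (0 - x[i]) / u[i])
      }
      t
    })
}
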