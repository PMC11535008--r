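#' Define a small interior compartment
#'
#' A compartment is a disk (2D) or ball (3D) of physical radius
#' \eqn{\epsilon \ell_j} centred at \eqn{x_j}, carrying a Robin exchange
#' reactivity \eqn{\kappa_j} (post-rescaling, O(1); `Inf` means a Dirichlet
#' boundary) and a model-specific payload:
#' \describe{
#'   \item{model I}{a prescribed boundary concentration `c0`.}
#'   \item{model II}{interior diffusivity `Dbar`, degradation `gbar` and
#'     source `Ibar` (post-rescaling, O(1)), giving a semi-permeable
#'     spatially resolved interior.}
#'   \item{model III}{a well-mixed reaction compartment; the exchanged
#'     species concentration plays the role of the boundary value and is
#'     determined self-consistently by [solve_model3()].}
#' }
#'
#' @param centre numeric vector (length 2 or 3).
#' @param ell scaled radius \eqn{\ell_j \in (0, 1]}; the configuration
#'   requires \eqn{\max_j \ell_j = 1} (that is the definition of
#'   \eqn{\epsilon}).
#' @param kappa reactivity (length/time), `Inf` allowed.
#' @param model `"I"`, `"II"` or `"III"`.
#' @param c0 model-I boundary concentration.
#' @param Dbar,gbar,Ibar model-II interior parameters.
#' @export
compartment <- function(centre, ell = 1, kappa = Inf,
                        model = c("I", "II", "III"),
                        c0 = 0, Dbar = NULL, gbar = NULL, Ibar = NULL) {
  model <- match.arg(model)
  if (ell <= 0 || ell > 1) stop("ell must lie in (0, 1]")
  if (kappa < 0) stop("kappa must be non-negative")
  if (model == "II") {
    if (is.null(Dbar) || is.null(gbar) || is.null(Ibar))
      stop("model II requires Dbar, gbar, Ibar")
    if (Dbar <= 0) stop("Dbar must be positive")
    if (gbar <= 0 && Ibar > 0)
      stop("no interior steady state: gbar = 0 with Ibar > 0")
  }
  structure(list(centre = as.numeric(centre), ell = ell, kappa = kappa,
                 model = model, c0 = c0, Dbar = Dbar, gbar = gbar,
                 Ibar = Ibar),
            class = "compartment")
}

#' Assemble a validated compartment configuration
#'
#' Checks the well-separation assumptions of the asymptotics: all pairwise
#' centre distances and all centre-to-boundary distances must be at least
#' `separation` (default \eqn{10\epsilon}).
#'
#' @param domain a [domain_spec()].
#' @param epsilon the small parameter (max compartment radius over domain
#'   scale), in (0, 1).
#' @param compartments list of [compartment()] objects.
#' @param separation minimum allowed centre separation; default
#'   `10 * epsilon`.
#' @return object of class `"compartment_config"` with derived
#'   \eqn{\nu = -1/\log\epsilon}.
#' @export
compartment_configuration <- function(domain, epsilon, compartments,
                                      separation = 10 * epsilon) {
  if (!inherits(domain, "domain_spec")) stop("domain must be a domain_spec")
  if (!is.numeric(epsilon) || epsilon <= 0 || epsilon >= 1)
    stop("epsilon must be in (0,1)")
  if (!length(compartments)) stop("at least one compartment required")
  if (inherits(compartments, "compartment"))
    compartments <- list(compartments)
  for (cmp in compartments) {
    if (!inherits(cmp, "compartment")) stop("compartments must be a list of compartment objects")
    if (length(cmp$centre) != domain$dim)
      stop("compartment centre dimension does not match the domain")
  }
  ells <- vapply(compartments, `[[`, 0, "ell")
  if (abs(max(ells) - 1) > 1e-12)
    stop("max_j ell_j must equal 1 (this defines epsilon)")
  X <- t(vapply(compartments, `[[`, numeric(domain$dim), "centre"))
  if (!all(domain_contains(domain, X)))
    stop("compartment centres must be interior points")
  if (nrow(X) > 1) {
    dd <- as.matrix(stats::dist(X))
    diag(dd) <- Inf
    if (min(dd) < separation)
      stop(sprintf("compartments too close: min centre distance %.4g < %.4g",
                   min(dd), separation))
  }
  bd <- domain_boundary_distance(domain, X)
  if (min(bd) < separation)
    stop(sprintf("compartment too close to the boundary: %.4g < %.4g",
                 min(bd), separation))
  structure(list(domain = domain, epsilon = epsilon, nu = -1 / log(epsilon),
                 compartments = compartments, centres = X,
                 separation = separation),
            class = "compartment_config")
}

#' @export
print.compartment_config <- function(x, ...) {
  cat(sprintf("<compartment_config> %s, N=%d, epsilon=%g (nu=%.4g)\n",
              x$domain$kind, length(x$compartments), x$epsilon, x$nu))
  invisible(x)
}

config_field <- function(config, name, default = NA_real_) {
  vapply(config$compartments, function(cmp) {
    v <- cmp[[name]]
    if (is.null(v)) default else v
  }, 0)
}
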