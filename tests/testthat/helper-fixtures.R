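# Shared fixtures: light-weight providers and configurations built in code.

disk_domain <- function(gamma0 = 1, D = 1, I0 = 0)
  domain_spec("disk2d", D = D, gamma0 = gamma0, I0 = I0)

rect_domain <- function(gamma0 = 1, D = 1, size = c(1, 1), I0 = 0)
  domain_spec("rect2d", size = size, D = D, gamma0 = gamma0, I0 = I0)

sphere_domain <- function(gamma0 = 1, D = 1)
  domain_spec("sphere3d", D = D, gamma0 = gamma0)

box_domain <- function(gamma0 = 1, D = 1, size = c(1, 1, 1))
  domain_spec("box3d", size = size, D = D, gamma0 = gamma0)

single_central <- function(domain, eps, kappa = Inf, c0 = 1, ell = 1) {
  ctr <- if (domain$kind %in% c("disk2d", "sphere3d"))
    rep(0, domain$dim) else domain$size / 2
  compartment_configuration(domain, eps,
                            list(compartment(ctr, ell = ell, kappa = kappa,
                                             model = "I", c0 = c0)))
}

mirrored_pair <- function(domain, eps, d = 0.4, kappa = 2, c0 = c(1, 1),
                          ell = c(1, 1)) {
  stopifnot(domain$kind %in% c("disk2d", "sphere3d"))
  ctr1 <- c(d, rep(0, domain$dim - 1))
  ctr2 <- c(-d, rep(0, domain$dim - 1))
  compartment_configuration(domain, eps, list(
    compartment(ctr1, ell = ell[1], kappa = kappa, model = "I", c0 = c0[1]),
    compartment(ctr2, ell = ell[2], kappa = kappa, model = "I", c0 = c0[2])))
}
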