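# Configuration parsing and columnar output.
#
# The single configuration dialect is YAML with two required blocks:
#   domain:       kind, size, D, gamma0, I0
#   epsilon:      the small parameter
#   compartments: list of {centre, ell, kappa, model, c0, Dbar, gbar, Ibar}
# plus an optional `solver:` block (tolerance, order, rho_switch, seed,
# separation).  Unknown keys are rejected rather than ignored.

.domain_keys <- c("kind", "size", "D", "gamma0", "I0")
.comp_keys <- c("centre", "ell", "kappa", "model", "c0", "Dbar", "gbar",
                "Ibar")
.solver_keys <- c("tolerance", "order", "rho_switch", "seed", "separation")

#' Parse a run configuration file
#'
#' @param path YAML file with `domain`, `epsilon` and `compartments` blocks.
#' @return list with the validated [domain_spec()],
#'   [compartment_configuration()] and materialised solver options.
#' @export
parse_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  allowed_top <- c("domain", "epsilon", "compartments", "solver")
  extra <- setdiff(names(raw), allowed_top)
  if (length(extra))
    stop("unknown configuration key(s): ", paste(extra, collapse = ", "),
         " (expected ", paste(allowed_top, collapse = ", "), ")")
  if (is.null(raw$domain)) stop("missing `domain:` block")
  extra <- setdiff(names(raw$domain), .domain_keys)
  if (length(extra))
    stop("unknown domain key(s): ", paste(extra, collapse = ", "))
  dom <- domain_spec(kind = raw$domain$kind %||% "disk2d",
                     size = unlist(raw$domain$size),
                     D = raw$domain$D %||% 1,
                     gamma0 = raw$domain$gamma0 %||% 0,
                     I0 = raw$domain$I0 %||% 0)
  epsv <- raw$epsilon
  if (is.null(epsv) || !is.numeric(epsv) || epsv <= 0 || epsv >= 1)
    stop("epsilon must be in (0,1)")
  if (is.null(raw$compartments) || !length(raw$compartments))
    stop("missing `compartments:` block")
  comps <- lapply(raw$compartments, function(cc) {
    extra <- setdiff(names(cc), .comp_keys)
    if (length(extra))
      stop("unknown compartment key(s): ", paste(extra, collapse = ", "))
    kap <- cc$kappa %||% Inf
    if (identical(kap, "Inf") || identical(kap, ".inf")) kap <- Inf
    compartment(centre = unlist(cc$centre), ell = cc$ell %||% 1,
                kappa = kap, model = cc$model %||% "I",
                c0 = cc$c0 %||% 0, Dbar = cc$Dbar, gbar = cc$gbar,
                Ibar = cc$Ibar)
  })
  solver <- raw$solver %||% list()
  extra <- setdiff(names(solver), .solver_keys)
  if (length(extra))
    stop("unknown solver key(s): ", paste(extra, collapse = ", "))
  solver <- list(tolerance = solver$tolerance %||% 1e-10,
                 order = solver$order %||% "two-term",
                 rho_switch = solver$rho_switch %||% 5,
                 seed = solver$seed %||% 1L,
                 separation = solver$separation %||% (10 * epsv))
  config <- compartment_configuration(dom, epsv, comps,
                                      separation = solver$separation)
  list(domain = dom, config = config, solver = solver)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Serialise a parsed configuration back to YAML
#'
#' Round-trips with [parse_config()].
#' @param parsed result of [parse_config()].
#' @param path output file.
#' @export
write_config <- function(parsed, path) {
  dom <- parsed$domain
  comps <- lapply(parsed$config$compartments, function(cmp) {
    out <- list(centre = as.list(cmp$centre), ell = cmp$ell,
                kappa = if (is.finite(cmp$kappa)) cmp$kappa else "Inf",
                model = cmp$model, c0 = cmp$c0)
    if (!is.null(cmp$Dbar)) out <- c(out, list(Dbar = cmp$Dbar,
                                               gbar = cmp$gbar,
                                               Ibar = cmp$Ibar))
    out
  })
  yaml::write_yaml(list(domain = list(kind = dom$kind,
                                      size = as.list(dom$size),
                                      D = dom$D, gamma0 = dom$gamma0,
                                      I0 = dom$I0),
                        epsilon = parsed$config$epsilon,
                        compartments = comps,
                        solver = parsed$solver),
                   path)
  invisible(path)
}

#' Write records as full-precision columnar text
#'
#' Comma-separated with header; doubles serialised with 17 significant
#' digits so a read-back reproduces them bit-for-bit.
#' @param records a data.frame (possibly zero rows).
#' @param path output path.
#' @export
write_table <- function(records, path) {
  if (!is.data.frame(records)) stop("records must be a data.frame")
  fmt <- records
  for (nm in names(fmt)) {
    if (is.double(fmt[[nm]]))
      fmt[[nm]] <- trimws(formatC(fmt[[nm]], digits = 17, format = "g"))
  }
  utils::write.table(fmt, path, sep = ",", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, eol = "\n")
  invisible(path)
}

#' Read a table written by [write_table()]
#' @param path input path.
#' @export
read_table_ <- function(path) {
  utils::read.table(path, header = TRUE, sep = ",",
                    stringsAsFactors = FALSE)
}
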