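#' Environment specifications for the replicator models
#'
#' `mass_environment()` describes the mass-regulated setting: the resource
#' concentration `r` is held constant and strands leave the system at a
#' dynamically adjusted per-capita rate (the normalized production), tuned so
#' that the total replicator concentration relaxes logistically to the target
#' concentration `m`.
#'
#' `chemostat_environment()` describes the resource-explicit chemostat:
#' dilution happens at a fixed rate `phi` and the resource, flowing in at
#' concentration `rho`, is tracked dynamically.
#'
#' @param m target replicator concentration (\code{> 0}); the equilibrium
#'   total concentration of the mass-regulated system.
#' @param r fixed resource concentration (\code{>= 0}).
#' @return an object of class \code{"mass_environment"} or
#'   \code{"chemostat_environment"}.
#' @examples
#' mass_environment(m = 2, r = 1)
#' chemostat_environment(rho = 2, phi = 0.5)
#' @export
mass_environment <- function(m, r) {
  stopifnot(is.numeric(m), length(m) == 1L, is.finite(m), m > 0,
            is.numeric(r), length(r) == 1L, is.finite(r), r >= 0)
  structure(list(m = m, r = r), class = "mass_environment")
}

#' @rdname mass_environment
#' @param rho inflowing resource concentration (\code{> 0}).
#' @param phi constant dilution rate (time^-1, \code{> 0}).
#' @export
chemostat_environment <- function(rho, phi) {
  stopifnot(is.numeric(rho), length(rho) == 1L, is.finite(rho), rho > 0,
            is.numeric(phi), length(phi) == 1L, is.finite(phi), phi > 0)
  structure(list(rho = as.numeric(rho), phi = as.numeric(phi)),
            class = "chemostat_environment")
}

#' @export
print.mass_environment <- function(x, ...) {
  cat("Mass-regulated environment: m =", x$m, ", r =", x$r, "\n")
  invisible(x)
}

#' @export
print.chemostat_environment <- function(x, ...) {
  cat("Chemostat environment: rho =", x$rho, ", phi =", x$phi, "\n")
  invisible(x)
}

#' Phenomenological power-law species
#'
#' Species for the single-equation growth model
#' \eqn{dz/dt = k z^{p} - \phi z}: a rate constant `k` and a growth exponent
#' `p`, with \eqn{0 < p < 1} for a sub-exponential (S-) species and
#' \eqn{p = 1} for an exponential (E-) species.
#'
#' @param k numeric vector of rate constants (\code{> 0}).
#' @param p numeric vector of growth exponents in \code{(0, 1]}.
#' @param label optional identifiers.
#' @return data frame of class \code{"phenomenological_pool"}.
#' @export
phenomenological_pool <- function(k, p, label = NULL) {
  n <- max(length(k), length(p))
  k <- rep_len(as.numeric(k), n)
  p <- rep_len(as.numeric(p), n)
  if (any(!is.finite(k)) || any(k <= 0)) stop("'k' must be finite and > 0")
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1))
    stop("growth exponents 'p' must lie in (0, 1]")
  if (is.null(label)) label <- paste0("sp", seq_len(n))
  out <- data.frame(label = rep_len(as.character(label), n), k = k, p = p,
                    stringsAsFactors = FALSE)
  class(out) <- unique(c("phenomenological_pool", class(out)))
  out
}
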