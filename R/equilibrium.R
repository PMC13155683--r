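#' Single-strand concentration at which a species' growth rate equals phi
#'
#' Inverts the density-dependent fitness of an S-species: the unique
#' single-strand concentration \eqn{\hat x} with
#' \eqn{\Lambda(\hat x) = \phi}, obtained in closed form from the defining
#' quadratic:
#' \deqn{\hat x = \frac{b c r - (b + c r)\phi - \phi^2}{2 a \phi}.}
#' Defined for \eqn{0 < \phi < \lambda}; at \eqn{\phi = \lambda} the
#' numerator vanishes and \eqn{\hat x = 0}; for \eqn{\phi > \lambda} no
#' non-negative solution exists (the species is excluded).
#'
#' @param kin single species: a one-row \code{\link{species_pool}} or a list
#'   with \code{a > 0}, \code{b}, \code{c}.
#' @param r resource concentration (\code{> 0}).
#' @param phi target growth rate (\code{0 < phi <= lambda}).
#' @return the equilibrium single-strand concentration \eqn{\hat x \ge 0}.
#' @export
invert_growth_rate <- function(kin, r, phi) {
  kin <- as_pool_df(kin)
  if (nrow(kin) != 1L) stop("'kin' must be a single species")
  if (kin$a <= 0) stop("growth-rate inversion requires an S-species (a > 0)")
  if (!is.finite(phi) || phi <= 0) stop("'phi' must be positive")
  lam <- intrinsic_growth_rate(kin, r)
  if (phi > lam * (1 + 1e-12))
    stop("phi (", phi, ") exceeds the intrinsic growth rate (", lam,
         "); no non-negative solution — species excluded")
  x <- (kin$b * kin$c * r - (kin$b + kin$c * r) * phi - phi^2) /
    (2 * kin$a * phi)
  max(x, 0)
}

#' Equilibrium total concentration of one S-species at a given production
#'
#' The total concentration \eqn{\hat\mu = r c \hat x / \phi} a single
#' S-species settles at when the community-wide normalized production is
#' \eqn{\phi}. Returns 0 (rather than an error) when \eqn{\phi \ge \lambda},
#' so the function is continuous across exclusion boundaries and can be
#' summed inside a root-finder.
#'
#' @inheritParams invert_growth_rate
#' @return \eqn{\hat\mu \ge 0}; strictly decreasing in \code{phi} on
#'   \eqn{(0, \lambda)}, 0 beyond.
#' @export
species_equilibrium_mass <- function(kin, r, phi) {
  kin <- as_pool_df(kin)
  if (nrow(kin) != 1L) stop("'kin' must be a single species")
  if (!is.finite(phi) || phi <= 0) stop("'phi' must be positive")
  lam <- intrinsic_growth_rate(kin, r)
  if (phi >= lam) return(0)
  r * kin$c * invert_growth_rate(kin, r, phi) / phi
}

# Vectorized over a pool; E-species (a == 0) contribute 0 here — their mass
# is not pinned by phi and is handled by the residual rule.
pool_equilibrium_mass <- function(pool, r, phi) {
  s <- 2 * pool$a * 0 + pool$b + pool$c * r
  lam <- 2 * pool$b * pool$c * r / (s + sqrt(s * s + 4 * pool$b * pool$c * r))
  x <- (pool$b * pool$c * r - (pool$b + pool$c * r) * phi - phi^2) /
    (2 * pool$a * phi)
  mu <- r * pool$c * x / phi
  mu[phi >= lam | pool$a == 0] <- 0
  pmax(mu, 0)
}

#' Analytic equilibrium of a mass-regulated replicator community
#'
#' Solves for the equilibrium normalized production \eqn{\hat\phi}, the set
#' of surviving species, and every survivor's equilibrium concentrations.
#'
#' With only S-species, \eqn{\hat\phi} is the unique root of
#' \eqn{\sum_i \hat\mu_i(\phi) = m} on \eqn{(0, \max_i \lambda_i)}: each
#' species' equilibrium mass is a continuous, decreasing function of
#' \eqn{\phi} (diverging as \eqn{\phi \to 0^+}, zero at its own
#' \eqn{\lambda}), so the bracketed root exists and is unique for every
#' \eqn{m > 0}. Survivors are the species with \eqn{\lambda_i > \hat\phi}.
#'
#' If E-species are present, only the one with the largest intrinsic growth
#' rate \eqn{\lambda_0} can persist, and it pins the production at
#' \eqn{\hat\phi = \lambda_0}, absorbing the residual mass
#' \eqn{m - \sum_S \hat\mu_i(\lambda_0)}. If that residual is not positive
#' the E-species is excluded and the pure-S branch applies. Ties between
#' E-species at the maximal \eqn{\lambda} are rejected as degenerate (two
#' E-species cannot coexist and no tie-breaking rule exists).
#'
#' @param pool a \code{\link{species_pool}}.
#' @param env a \code{\link{mass_environment}} with \code{r > 0}.
#' @param fill_state if \code{TRUE} (default) also compute per-species
#'   \eqn{\hat x_i}, \eqn{\hat y_i}.
#' @param marginal_tol relative width of the band around \eqn{\hat\phi}
#'   within which a species' \eqn{\lambda} is flagged "marginal" rather than
#'   confidently classified.
#' @return An object of class \code{"replicator_equilibrium"}: a list with
#'   \code{phi_hat}, \code{survivors} (labels), \code{resident_E} (label or
#'   \code{NA}), \code{marginal} (labels), and \code{table}, a data frame
#'   with per-species \code{lambda}, \code{x_hat}, \code{y_hat},
#'   \code{mu_hat}, \code{survivor}.
#' @examples
#' eq <- equilibrium_state(table1_pool(), mass_environment(m = 2, r = 1))
#' eq$phi_hat
#' sum(eq$table$mu_hat)  # == m
#' @export
equilibrium_state <- function(pool, env, fill_state = TRUE,
                              marginal_tol = 1e-9) {
  pool <- as_pool_df(pool)
  if (!inherits(env, "mass_environment"))
    stop("'env' must be a mass_environment")
  if (env$r <= 0)
    stop("r = 0: no production, no equilibrium with positive mass")
  m <- env$m; r <- env$r
  lam <- intrinsic_growth_rate(pool, r)
  isE <- pool$a == 0

  phi_hat <- NA_real_
  resident_E <- NA_character_
  if (any(isE)) {
    lam0 <- max(lam[isE])
    if (sum(lam[isE] == lam0) > 1L)
      stop("degenerate input: several E-species share the maximal intrinsic ",
           "growth rate; two E-species cannot coexist and there is no ",
           "tie-breaking rule")
    residual <- m - sum(pool_equilibrium_mass(pool, r, lam0))
    if (residual > 1e-12) {
      phi_hat <- lam0
      resident_E <- pool$label[isE & lam == lam0]
    }
  }
  if (is.na(phi_hat)) {
    # pure-S branch (also reached when every E-species is excluded)
    if (all(isE)) {
      # single viable E-species takes all mass only via the residual rule;
      # if we are here, no E-species can persist at positive mass => the
      # largest-lambda E still holds all mass in the limit: residual rule
      # with no S-species always yields residual = m > 0, so this branch is
      # unreachable for pure-E pools.
      stop("internal error: pure-E pool should resolve via the E-branch")
    }
    lam_max <- max(lam[!isE])
    f <- function(phi) sum(pool_equilibrium_mass(pool, r, phi)) - m
    eps <- 1e-12 * lam_max
    lo <- eps
    while (f(lo) < 0) lo <- lo / 8  # guard: mass diverges as phi -> 0+
    phi_hat <- stats::uniroot(f, c(lo, lam_max * (1 - 1e-15)),
                              tol = 1e-14 * lam_max)$root
  }

  mu_hat <- pool_equilibrium_mass(pool, r, phi_hat)
  if (!is.na(resident_E)) {
    iE <- match(resident_E, pool$label)
    mu_hat[iE] <- m - sum(mu_hat)
  }
  band <- marginal_tol * phi_hat
  marginal <- pool$label[!isE & abs(lam - phi_hat) <= band]
  survivor <- mu_hat > 0
  survivors <- pool$label[survivor]

  tab <- data.frame(label = pool$label, a = pool$a, b = pool$b, c = pool$c,
                    lambda = lam, mu_hat = mu_hat,
                    x_hat = NA_real_, y_hat = NA_real_,
                    survivor = survivor, stringsAsFactors = FALSE)
  if (fill_state) {
    # survivors sit on Eq. (6): x/mu = phi/(r c); Eq. (7): y/x = (cr-phi)/(2 phi)
    x_hat <- ifelse(survivor, mu_hat * phi_hat / (r * pool$c), 0)
    y_hat <- ifelse(survivor, x_hat * (pool$c * r - phi_hat) / (2 * phi_hat), 0)
    tab$x_hat <- x_hat
    tab$y_hat <- y_hat
  }
  structure(list(phi_hat = phi_hat, survivors = survivors,
                 resident_E = resident_E, marginal = marginal,
                 table = tab, env = env),
            class = "replicator_equilibrium")
}

#' @rdname equilibrium_state
#' @export
equilibrium_phi <- function(pool, env, marginal_tol = 1e-9) {
  equilibrium_state(pool, env, fill_state = FALSE,
                    marginal_tol = marginal_tol)
}

#' @export
print.replicator_equilibrium <- function(x, ...) {
  cat("Replicator community equilibrium (m = ", x$env$m, ", r = ", x$env$r,
      ")\n", sep = "")
  cat("phi_hat =", format(x$phi_hat, digits = 10), "\n")
  if (!is.na(x$resident_E)) cat("Resident E-species:", x$resident_E,
                                "(pins phi_hat at its lambda)\n")
  cat("Survivors:", if (length(x$survivors)) paste(x$survivors, collapse = ", ")
      else "(none)", "\n")
  if (length(x$marginal))
    cat("Marginal (lambda within tolerance of phi_hat):",
        paste(x$marginal, collapse = ", "), "\n")
  print(x$table, digits = 6)
  invisible(x)
}

#' Critical target concentration at which the first extinction occurs
#'
#' In a pure-S community the equilibrium production \eqn{\hat\phi(m)} is
#' decreasing in \eqn{m}; as \eqn{m} shrinks, \eqn{\hat\phi} rises and the
#' species with the smallest intrinsic growth rate \eqn{\lambda_{\min}} is
#' the first to be excluded. The threshold solves
#' \eqn{\hat\phi(m^*) = \lambda_{\min}}; since the exiting species carries
#' zero mass exactly at the boundary,
#' \deqn{m^* = \sum_{i \ne \mathrm{argmin}} \hat\mu_i(\lambda_{\min}).}
#'
#' @param pool a pure-S \code{\link{species_pool}} with at least two species
#'   of distinct intrinsic growth rate.
#' @param r resource concentration (\code{> 0}).
#' @return list with \code{m_star}, \code{lambda_min}, and \code{exiting}
#'   (label of the species lost first).
#' @export
critical_target_concentration <- function(pool, r) {
  pool <- as_pool_df(pool)
  if (any(pool$a == 0))
    stop("critical m is defined for pure-S communities")
  if (nrow(pool) < 2L)
    stop("a single-species community has no first-extinction threshold")
  lam <- intrinsic_growth_rate(pool, r)
  lam_min <- min(lam)
  if (sum(lam == lam_min) > 1L)
    stop("degenerate community: several species share the minimal intrinsic ",
         "growth rate, so there is no single first-extinction threshold")
  keep <- lam > lam_min
  m_star <- sum(pool_equilibrium_mass(pool[keep, , drop = FALSE], r, lam_min))
  list(m_star = m_star, lambda_min = lam_min,
       exiting = pool$label[lam == lam_min])
}
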