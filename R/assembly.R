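#' Invasion criterion for a rare species entering a resident community
#'
#' A rare invader grows as if unpaired, at its intrinsic growth rate
#' \eqn{\lambda'}, while being washed out at the resident community's
#' normalized production \eqn{\hat\phi_{res}}. It invades iff
#' \eqn{\lambda' > \hat\phi_{res}} (strict). Because \eqn{\lambda'} does not
#' depend on the association rate, neither does invasion success.
#'
#' @param invader a single-species \code{\link{species_pool}} row.
#' @param phi_res the resident equilibrium normalized production.
#' @param r resource concentration.
#' @return logical.
#' @export
can_invade <- function(invader, phi_res, r) {
  invader <- as_pool_df(invader)
  if (nrow(invader) != 1L) stop("'invader' must be a single species")
  stopifnot(is.finite(phi_res), phi_res >= 0)
  intrinsic_growth_rate(invader, r) > phi_res
}

#' Equilibrium-to-equilibrium invasion of a resident community
#'
#' Resolves the resident community to its equilibrium, tests the invasion
#' criterion, and — if the invader can enter — recomputes the equilibrium of
#' residents plus invader. Species that survived before but not after are
#' reported extinct; their intrinsic growth rates fall inside the zone of
#' exclusion \eqn{(\hat\phi_{res}, \hat\phi_{new}]}. Both characterizations
#' (zero equilibrium mass, and \eqn{\lambda} in the zone, plus a displaced
#' E-species) are computed and cross-checked on every call.
#'
#' This works at the level of equilibria (adiabatic assembly). For a
#' dynamical cross-check, introduce the invader at low concentration in
#' \code{\link{integrate_dynamics}} instead.
#'
#' @param residents a \code{\link{species_pool}}.
#' @param invader a single-species pool row; its label must not collide.
#' @param env a \code{\link{mass_environment}}.
#' @return An object of class \code{"invasion_outcome"}: list with
#'   \code{invader}, \code{lambda_invader}, \code{phi_res}, \code{phi_new},
#'   \code{can_invade}, \code{extinct} (labels), \code{survivors},
#'   \code{equilibrium} (the post-invasion \code{"replicator_equilibrium"};
#'   pre-invasion one if the invasion fails).
#' @export
invade <- function(residents, invader, env) {
  residents <- as_pool_df(residents)
  invader <- as_pool_df(invader)
  if (nrow(invader) != 1L) stop("'invader' must be a single species")
  if (invader$label %in% residents$label)
    stop("invader label collides with a resident")
  eq_res <- equilibrium_state(residents, env)
  lam_inv <- intrinsic_growth_rate(invader, env$r)
  ok <- can_invade(invader, eq_res$phi_hat, env$r)
  if (!ok) {
    return(structure(list(invader = invader$label, lambda_invader = lam_inv,
                          phi_res = eq_res$phi_hat, phi_new = eq_res$phi_hat,
                          can_invade = FALSE, extinct = character(0),
                          survivors = eq_res$survivors,
                          equilibrium = eq_res),
                     class = "invasion_outcome"))
  }
  joint <- validate_species_pool(rbind(as.data.frame(residents),
                                       as.data.frame(invader)))
  eq_new <- equilibrium_state(joint, env)
  extinct <- setdiff(eq_res$survivors, eq_new$survivors)
  # cross-check: extinct residents are exactly the former survivors whose
  # lambda lies in (phi_res, phi_new], plus a displaced resident E-species
  lam_res <- intrinsic_growth_rate(residents, env$r)
  names(lam_res) <- residents$label
  in_zone <- residents$label[lam_res > eq_res$phi_hat &
                               lam_res <= eq_new$phi_hat]
  expected <- intersect(eq_res$survivors, in_zone)
  if (!is.na(eq_res$resident_E) && !(eq_res$resident_E %in% eq_new$survivors))
    expected <- union(expected, eq_res$resident_E)
  if (!setequal(extinct, expected))
    warning("zone-of-exclusion classification disagrees with zero-mass ",
            "classification (extinct: ", paste(extinct, collapse = ","),
            "; in zone: ", paste(expected, collapse = ","), ")")
  structure(list(invader = invader$label, lambda_invader = lam_inv,
                 phi_res = eq_res$phi_hat, phi_new = eq_new$phi_hat,
                 can_invade = TRUE, extinct = extinct,
                 survivors = eq_new$survivors, equilibrium = eq_new),
            class = "invasion_outcome")
}

#' @export
print.invasion_outcome <- function(x, ...) {
  cat("Invasion of '", x$invader, "' (lambda' = ",
      format(x$lambda_invader, digits = 6), ") into phi_res = ",
      format(x$phi_res, digits = 6), ": ",
      if (x$can_invade) "SUCCEEDS" else "fails", "\n", sep = "")
  if (x$can_invade) {
    cat("phi_new =", format(x$phi_new, digits = 6), "\n")
    cat("Extinct:", if (length(x$extinct)) paste(x$extinct, collapse = ", ")
        else "(none)", "\n")
  }
  invisible(x)
}

#' Zone of exclusion of a successful invasion
#'
#' The half-open interval \eqn{(\hat\phi_{res}, \hat\phi_{new}]}: resident
#' species whose intrinsic growth rate falls inside are extirpated. Its
#' width is the invader's competitiveness.
#'
#' @param outcome an \code{"invasion_outcome"} from \code{\link{invade}}.
#' @return list with \code{lower}, \code{upper}, \code{width},
#'   \code{extinct}.
#' @export
exclusion_zone <- function(outcome) {
  if (!inherits(outcome, "invasion_outcome"))
    stop("'outcome' must come from invade()")
  if (!outcome$can_invade)
    return(list(lower = outcome$phi_res, upper = outcome$phi_res,
                width = 0, extinct = character(0)))
  list(lower = outcome$phi_res, upper = outcome$phi_new,
       width = outcome$phi_new - outcome$phi_res,
       extinct = outcome$extinct)
}

#' Assemble the maximal coexisting community from a species pool
#'
#' Introduces pool members one at a time (in the given order) into the
#' growing community via \code{\link{invade}} until no remaining member can
#' enter. Because the normalized production never decreases along the way, a
#' rejected species stays rejected, and the final survivor set and
#' \eqn{\hat\phi} are independent of the order — identical to solving the
#' equilibrium of the full pool at once (\code{order = "all-at-once"}),
#' where excluded species simply come out with zero mass.
#'
#' @param pool a \code{\link{species_pool}}.
#' @param env a \code{\link{mass_environment}}.
#' @param order integer permutation of \code{seq_len(nrow(pool))}, a
#'   character permutation of the labels, or \code{"all-at-once"} (default).
#' @return list with \code{survivors} (labels), \code{phi_hat},
#'   \code{equilibrium} (a \code{"replicator_equilibrium"} over the final
#'   community), and \code{rejected} (pool members absent from the final
#'   community).
#' @examples
#' asm <- assemble(table1_pool(), mass_environment(m = 2, r = 1))
#' asm$survivors
#' @export
assemble <- function(pool, env, order = "all-at-once") {
  pool <- as_pool_df(pool)
  if (identical(order, "all-at-once")) {
    eq <- equilibrium_state(pool, env)
    return(list(survivors = eq$survivors, phi_hat = eq$phi_hat,
                equilibrium = eq,
                rejected = setdiff(pool$label, eq$survivors)))
  }
  if (is.character(order)) order <- match(order, pool$label)
  if (!setequal(order, seq_len(nrow(pool))))
    stop("'order' must be a permutation of the pool")
  idx <- order[1]
  community <- pool[idx, , drop = FALSE]
  for (i in order[-1]) {
    eq <- equilibrium_state(community, env)
    if (can_invade(pool[i, , drop = FALSE], eq$phi_hat, env$r)) {
      community <- validate_species_pool(
        rbind(as.data.frame(community), as.data.frame(pool[i, , drop = FALSE])))
      eq <- equilibrium_state(community, env)
      community <- community[community$label %in% eq$survivors, , drop = FALSE]
      community <- validate_species_pool(community)
    }
  }
  eq <- equilibrium_state(community, env)
  list(survivors = eq$survivors, phi_hat = eq$phi_hat, equilibrium = eq,
       rejected = setdiff(pool$label, eq$survivors))
}

#' Trajectory-based invasion cross-check
#'
#' Introduces the invader at low concentration (\code{x = 1e-5},
#' \code{y = 0}) on top of the resolved resident equilibrium and integrates
#' the full dynamics, classifying the invasion by whether the invader's
#' total concentration ends above the extinction threshold. Slower than the
#' equilibrium-to-equilibrium \code{\link{invade}}, and intended to
#' cross-validate it.
#'
#' @inheritParams invade
#' @param intro_x introduction concentration.
#' @param t_end integration horizon.
#' @param threshold extinction threshold on the final \eqn{\mu}.
#' @return list with \code{established} (logical), \code{mu_invader},
#'   \code{trajectory}.
#' @export
invade_dynamic <- function(residents, invader, env, intro_x = 1e-5,
                           t_end = 1e6, threshold = 1e-7) {
  residents <- as_pool_df(residents)
  invader <- as_pool_df(invader)
  eq <- equilibrium_state(residents, env)
  joint <- validate_species_pool(rbind(as.data.frame(residents),
                                       as.data.frame(invader)))
  st0 <- community_state(c(eq$table$x_hat, intro_x),
                         c(eq$table$y_hat, 0))
  tr <- integrate_dynamics(joint, env, state0 = st0, t_end = t_end)
  lab <- invader$label
  mu_inv <- tr[[paste0("mu_", lab)]][nrow(tr)]
  list(established = mu_inv > threshold, mu_invader = mu_inv,
       trajectory = tr)
}
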