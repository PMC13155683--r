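#' Community state: strand concentrations for N species
#'
#' Bundles the single-strand concentrations \code{x}, the double-strand
#' (duplex) concentrations \code{y}, and — for the chemostat model only — the
#' current resource concentration \code{rvar}.
#'
#' @param x numeric vector of single-strand concentrations (\code{>= 0}).
#' @param y numeric vector of duplex concentrations (\code{>= 0}), same length.
#' @param rvar optional current resource concentration (chemostat model).
#' @return list of class \code{"community_state"}.
#' @export
community_state <- function(x, y = rep(0, length(x)), rvar = NULL) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("'x' and 'y' must have the same length")
  if (any(!is.finite(x)) || any(!is.finite(y)) || any(x < 0) || any(y < 0))
    stop("concentrations must be finite and non-negative")
  if (!is.null(rvar)) {
    stopifnot(length(rvar) == 1L, is.finite(rvar), rvar >= 0)
    rvar <- as.numeric(rvar)
  }
  structure(list(x = x, y = y, rvar = rvar), class = "community_state")
}

#' Total (strand-equivalent) concentrations
#'
#' Each duplex carries two strands, so the total concentration of species i
#' is \eqn{\mu_i = x_i + 2 y_i} and the community total is
#' \eqn{\mu = \sum_i \mu_i}.
#'
#' @param state a \code{\link{community_state}} (or list with \code{x}, \code{y}).
#' @return list with components \code{mu} (per-species vector) and
#'   \code{total} (scalar).
#' @export
total_concentrations <- function(state) {
  mu <- state$x + 2 * state$y
  list(mu = mu, total = sum(mu))
}

#' Normalized production of a mass-regulated community
#'
#' The total strand production per unit time, \eqn{r \sum_j c_j x_j},
#' divided by the target concentration \code{m}:
#' \deqn{\phi = \frac{r}{m} \sum_j c_j x_j.}
#' It is the per-capita outflow rate that regulates the total concentration
#' towards \code{m}.
#'
#' @param x single-strand concentration vector (one entry per species).
#' @param pool the \code{\link{species_pool}}.
#' @param env a \code{\link{mass_environment}}.
#' @return the normalized production (scalar, \code{>= 0}).
#' @export
normalized_production <- function(x, pool, env) {
  pool <- as_pool_df(pool)
  if (length(x) != nrow(pool))
    stop("length of 'x' (", length(x), ") does not match pool size (",
         nrow(pool), ")")
  (env$r / env$m) * sum(pool$c * x)
}

## Right-hand sides ---------------------------------------------------------

#' Time derivatives of the mass-regulated replicator community
#'
#' For each species, single strands are lost to pairing (rate \eqn{2 a x^2}),
#' to templated copying (\eqn{c r x}, which leaves the new copy bound to its
#' template) and to outflow, and regained by duplex dissociation
#' (\eqn{2 b y}):
#' \deqn{dx_i/dt = -2 a_i x_i^2 + 2 b_i y_i - c_i r x_i - \phi x_i,}
#' \deqn{dy_i/dt = a_i x_i^2 - b_i y_i + c_i r x_i - \phi y_i,}
#' with \eqn{\phi} the \code{\link{normalized_production}}. The per-species
#' totals obey \eqn{d\mu_i/dt = r c_i x_i - \phi \mu_i}, so the community
#' total follows the logistic identity \eqn{d\mu/dt = \phi (m - \mu)}.
#'
#' @param state a \code{\link{community_state}}.
#' @param pool the \code{\link{species_pool}}.
#' @param env a \code{\link{mass_environment}}.
#' @return list with components \code{dx}, \code{dy}, and the current
#'   \code{phi}.
#' @export
mass_regulated_rhs <- function(state, pool, env) {
  pool <- as_pool_df(pool)
  x <- state$x; y <- state$y
  if (any(x < 0) || any(y < 0)) stop("negative concentrations in state")
  phi <- normalized_production(x, pool, env)
  ax2 <- pool$a * x * x
  crx <- pool$c * env$r * x
  list(dx = -2 * ax2 + 2 * pool$b * y - crx - phi * x,
       dy = ax2 - pool$b * y + crx - phi * y,
       phi = phi)
}

#' Time derivatives of the resource-explicit chemostat community
#'
#' Same strand kinetics as \code{\link{mass_regulated_rhs}}, but the outflow
#' is a fixed dilution rate \eqn{\phi} and the resource is dynamic:
#' \deqn{dr/dt = -r \sum_i c_i x_i + (\rho - r)\,\phi.}
#' At equilibrium \eqn{\rho - \hat r} equals the total replicator
#' concentration \eqn{\hat\mu}.
#'
#' @param state a \code{\link{community_state}} carrying \code{rvar}.
#' @param pool the \code{\link{species_pool}}.
#' @param env a \code{\link{chemostat_environment}}.
#' @return list with \code{dx}, \code{dy}, \code{dr}, and \code{phi}.
#' @export
chemostat_rhs <- function(state, pool, env) {
  pool <- as_pool_df(pool)
  if (is.null(state$rvar)) stop("chemostat state must carry 'rvar'")
  x <- state$x; y <- state$y; r <- state$rvar
  if (any(x < 0) || any(y < 0) || r < 0) stop("negative concentrations in state")
  phi <- env$phi
  ax2 <- pool$a * x * x
  crx <- pool$c * r * x
  list(dx = -2 * ax2 + 2 * pool$b * y - crx - phi * x,
       dy = ax2 - pool$b * y + crx - phi * y,
       dr = -sum(crx) + (env$rho - r) * phi,
       phi = phi)
}

#' Time derivatives of the phenomenological power-law model
#'
#' The single-equation approximation that ignores the single/double-strand
#' distinction: \eqn{dz_i/dt = k_i z_i^{p_i} - \phi z_i} with
#' \eqn{\phi = (\sum_j k_j z_j^{p_j})/m}. For \eqn{p < 1} the per-capita
#' growth rate \eqn{k z^{p-1}} diverges as \eqn{z \to 0^+}, the artifact
#' that makes every sub-exponential species invade unconditionally.
#'
#' @param z concentration vector (\code{>= 0}).
#' @param pool a \code{\link{phenomenological_pool}}.
#' @param m target replicator concentration.
#' @return list with \code{dz} and \code{phi}.
#' @export
phenomenological_rhs <- function(z, pool, m) {
  if (!inherits(pool, "phenomenological_pool"))
    pool <- phenomenological_pool(pool$k, pool$p, pool$label)
  if (length(z) != nrow(pool)) stop("length mismatch between 'z' and pool")
  if (any(z < 0)) stop("negative concentrations in state")
  prod <- pool$k * z^pool$p
  phi <- sum(prod) / m
  list(dz = prod - phi * z, phi = phi)
}

## Integration --------------------------------------------------------------

#' Integrate a replicator community through time
#'
#' Wraps a stiff, adaptive-step BDF integrator (\pkg{deSolve}) around the
#' three model right-hand sides. Integration proceeds in chunks up to
#' \code{t_end} and stops early once the community is numerically at steady
#' state: \eqn{\max_i |d\mu_i/dt| / \max(\mu, 10^{-12})} below
#' \code{steady_tol}. The default threshold is deliberately far below the
#' accuracy sought in the state itself: near an exclusion boundary the
#' slowest mode decays at a rate \eqn{|\lambda_i - \hat\phi|} that can be
#' tiny, and the derivative criterion underestimates the remaining distance
#' to equilibrium by exactly that factor.
#'
#' Concentration coordinates that undershoot zero by less than \code{atol}
#' (an unavoidable consequence of finite solver tolerances when species
#' decay towards extinction) are clipped to zero; more negative values abort
#' with an error, as they indicate solver misconfiguration rather than
#' round-off.
#'
#' @param pool a \code{\link{species_pool}} (or
#'   \code{\link{phenomenological_pool}} for \code{model = "phenomenological"}).
#' @param env a \code{\link{mass_environment}} or
#'   \code{\link{chemostat_environment}}; for the phenomenological model a
#'   \code{\link{mass_environment}} whose \code{r} is ignored, or a plain
#'   number \code{m}.
#' @param state0 initial \code{\link{community_state}} (or, for the
#'   phenomenological model, a numeric vector \code{z}). Default: every
#'   species at \eqn{x_i = 10^{-3}}, \eqn{y_i = 0} (resource at \code{rho}
#'   for the chemostat).
#' @param model one of \code{"mass"}, \code{"chemostat"},
#'   \code{"phenomenological"}.
#' @param t_end integration horizon (default \code{1e6} time units).
#' @param times optional explicit output times; when given, early stopping is
#'   disabled and the trajectory is reported exactly at \code{times}.
#' @param rtol,atol relative/absolute solver tolerances. The defaults are
#'   tight because extinction decisions hinge on concentrations several
#'   orders of magnitude below the community total.
#' @param steady_tol steady-state detection threshold.
#' @param forcing optional list with functions \code{a(t)} and/or \code{r(t)}
#'   overriding the (common) association rate and resource concentration
#'   through time (mass-regulated model only).
#' @param method \pkg{deSolve} method; default \code{"bdf"}.
#' @return A \code{"replicator_trajectory"}: a data frame with column
#'   \code{time}, per-species \code{x_<label>}/\code{y_<label>} (or
#'   \code{z_<label>}), \code{r} for the chemostat, per-species
#'   \code{mu_<label>}, \code{mu_total}, and \code{phi}; attributes
#'   \code{converged} (steady state reached before \code{t_end}),
#'   \code{model}, and \code{labels}.
#' @examples
#' pool <- table1_pool()
#' tr <- integrate_dynamics(pool, mass_environment(m = 2, r = 1), t_end = 1e3)
#' tail(tr$mu_total, 1)
#' @export
integrate_dynamics <- function(pool, env, state0 = NULL,
                               model = c("mass", "chemostat",
                                         "phenomenological"),
                               t_end = 1e6, times = NULL,
                               rtol = 1e-10, atol = 1e-12,
                               steady_tol = 1e-12, forcing = NULL,
                               method = "bdf") {
  model <- match.arg(model)
  if (model == "phenomenological") {
    return(integrate_phenomenological(pool, env, state0, t_end, times,
                                      rtol, atol, steady_tol, method))
  }
  pool <- as_pool_df(pool)
  n <- nrow(pool)
  if (is.null(state0)) {
    state0 <- community_state(rep(1e-3, n), rep(0, n),
                              rvar = if (model == "chemostat") env$rho)
  }
  if (length(state0$x) != n) stop("state dimension does not match pool")
  if (model == "chemostat" && is.null(state0$rvar))
    stop("chemostat initial state must carry 'rvar'")
  if (!is.null(forcing) && model != "mass")
    stop("time-varying forcing is only supported for the mass-regulated model")
  stopifnot(t_end > 0)

  a0 <- pool$a; c0 <- pool$c; b0 <- pool$b
  afun <- if (!is.null(forcing$a)) forcing$a else NULL
  rfun <- if (!is.null(forcing$r)) forcing$r else NULL

  ix <- seq_len(n); iy <- n + ix
  if (model == "mass") {
    m <- env$m; renv <- env$r
    rhs <- function(t, s, parms) {
      x <- pmax(s[ix], 0); y <- pmax(s[iy], 0)
      a <- if (is.null(afun)) a0 else rep_len(afun(t), n)
      r <- if (is.null(rfun)) renv else rfun(t)
      phi <- (r / m) * sum(c0 * x)
      ax2 <- a * x * x
      crx <- c0 * r * x
      list(c(-2 * ax2 + 2 * b0 * y - crx - phi * x,
             ax2 - b0 * y + crx - phi * y))
    }
    y0 <- c(state0$x, state0$y)
  } else {
    rho <- env$rho; phi <- env$phi
    rhs <- function(t, s, parms) {
      x <- pmax(s[ix], 0); y <- pmax(s[iy], 0); r <- max(s[2 * n + 1], 0)
      ax2 <- a0 * x * x
      crx <- c0 * r * x
      list(c(-2 * ax2 + 2 * b0 * y - crx - phi * x,
             ax2 - b0 * y + crx - phi * y,
             -sum(crx) + (rho - r) * phi))
    }
    y0 <- c(state0$x, state0$y, state0$rvar)
  }

  run <- run_chunked(rhs, y0, t_end, times, rtol, atol, method,
                     steady_check = function(s) {
                       dm <- mu_derivative(s, rhs, n)
                       mu <- sum(s[ix] + 2 * s[iy])
                       max(abs(dm)) / max(mu, 1e-12) < steady_tol
                     })
  build_trajectory(run, pool, env, model)
}

# d(mu_i)/dt at a state, from one RHS evaluation
mu_derivative <- function(s, rhs, n) {
  d <- rhs(attr(s, "time") %||% 0, s, NULL)[[1]]
  d[seq_len(n)] + 2 * d[n + seq_len(n)]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Chunked integration with optional early stopping. Chunk boundaries are
# log-spaced so transients are resolved and long tails are cheap.
run_chunked <- function(rhs, y0, t_end, times, rtol, atol, method,
                        steady_check) {
  clip_guard <- function(s) {
    bad <- s < -sqrt(atol)
    if (any(bad))
      stop("integration produced strongly negative concentrations (min ",
           format(min(s)), "); solver misconfigured")
    pmax(s, 0)
  }
  if (!is.null(times)) {
    out <- deSolve::ode(y = y0, times = times, func = rhs, parms = NULL,
                        method = method, rtol = rtol, atol = atol,
                        maxsteps = 5e5)
    check_solver(out, times)
    states <- out[, -1, drop = FALSE]
    states[] <- t(apply(states, 1, clip_guard))
    return(list(times = out[, 1], states = states, converged = NA))
  }
  bounds <- unique(c(0, 10^seq(0, log10(t_end), length.out = 25)))
  bounds[length(bounds)] <- t_end
  all_t <- 0
  all_s <- matrix(y0, nrow = 1)
  cur <- y0
  converged <- FALSE
  for (k in seq_len(length(bounds) - 1)) {
    seg <- c(bounds[k], bounds[k + 1])
    out <- deSolve::ode(y = cur, times = seg, func = rhs, parms = NULL,
                        method = method, rtol = rtol, atol = atol,
                        maxsteps = 5e5)
    check_solver(out, seg)
    cur <- clip_guard(out[nrow(out), -1])
    attr(cur, "time") <- seg[2]
    all_t <- c(all_t, seg[2])
    all_s <- rbind(all_s, cur)
    if (steady_check(cur)) { converged <- TRUE; break }
  }
  list(times = all_t, states = all_s, converged = converged)
}

check_solver <- function(out, times) {
  if (nrow(out) < length(times) || any(!is.finite(out[nrow(out), -1])))
    stop("ODE solver failed before reaching t = ", max(times),
         "; diagnostics: ", paste(utils::capture.output(
           deSolve::diagnostics(out)), collapse = " "))
  invisible(out)
}

build_trajectory <- function(run, pool, env, model) {
  n <- nrow(pool)
  lab <- pool$label
  st <- run$states
  x <- st[, seq_len(n), drop = FALSE]
  y <- st[, n + seq_len(n), drop = FALSE]
  mu <- x + 2 * y
  if (model == "mass") {
    phi <- (env$r / env$m) * as.vector(x %*% pool$c)
    rcol <- NULL
  } else {
    rcol <- st[, 2 * n + 1]
    phi <- rep(env$phi, length(run$times))
  }
  df <- data.frame(time = run$times)
  for (j in seq_len(n)) df[[paste0("x_", lab[j])]] <- x[, j]
  for (j in seq_len(n)) df[[paste0("y_", lab[j])]] <- y[, j]
  if (!is.null(rcol)) df$r <- rcol
  for (j in seq_len(n)) df[[paste0("mu_", lab[j])]] <- mu[, j]
  df$mu_total <- rowSums(mu)
  df$phi <- phi
  structure(df, class = c("replicator_trajectory", "data.frame"),
            converged = run$converged, model = model, labels = lab)
}

integrate_phenomenological <- function(pool, env, state0, t_end, times,
                                       rtol, atol, steady_tol, method) {
  if (!inherits(pool, "phenomenological_pool"))
    pool <- phenomenological_pool(pool$k, pool$p, pool$label)
  m <- if (inherits(env, "mass_environment")) env$m else as.numeric(env)
  stopifnot(is.finite(m), m > 0)
  n <- nrow(pool)
  if (is.null(state0)) state0 <- rep(1e-3, n)
  z0 <- if (is.list(state0)) state0$x else as.numeric(state0)
  if (length(z0) != n) stop("state dimension does not match pool")
  k <- pool$k; p <- pool$p
  rhs <- function(t, z, parms) {
    z <- pmax(z, 0)
    prod <- k * z^p
    phi <- sum(prod) / m
    list(prod - phi * z)
  }
  run <- run_chunked(rhs, z0, t_end, times, rtol, atol, method,
                     steady_check = function(s) {
                       d <- rhs(0, s, NULL)[[1]]
                       max(abs(d)) / max(sum(s), 1e-12) < steady_tol
                     })
  lab <- pool$label
  df <- data.frame(time = run$times)
  for (j in seq_len(n)) df[[paste0("z_", lab[j])]] <- run$states[, j]
  df$mu_total <- rowSums(run$states)
  df$phi <- as.vector(run$states^matrix(p, nrow(run$states), n,
                                        byrow = TRUE) %*% k) / m
  structure(df, class = c("replicator_trajectory", "data.frame"),
            converged = run$converged, model = "phenomenological",
            labels = lab)
}

#' @export
print.replicator_trajectory <- function(x, ...) {
  cat("Replicator trajectory (", attr(x, "model"), " model): ",
      length(attr(x, "labels")), " species, ", nrow(x), " time points, t in [",
      min(x$time), ", ", max(x$time), "]\n", sep = "")
  conv <- attr(x, "converged")
  if (isTRUE(conv)) cat("Steady state reached before the horizon.\n")
  cat("Final mu_total = ", x$mu_total[nrow(x)],
      ", phi = ", x$phi[nrow(x)], "\n", sep = "")
  invisible(x)
}

#' Final state of a trajectory as a community_state
#'
#' @param traj a \code{"replicator_trajectory"} from a strand-resolved model.
#' @return a \code{\link{community_state}}.
#' @export
final_state <- function(traj) {
  lab <- attr(traj, "labels")
  i <- nrow(traj)
  community_state(as.numeric(traj[i, paste0("x_", lab)]),
                  as.numeric(traj[i, paste0("y_", lab)]),
                  rvar = if ("r" %in% names(traj)) traj$r[i])
}
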