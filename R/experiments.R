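#' Count species present in a trajectory's final state
#'
#' A species is counted as surviving when its total concentration
#' \eqn{\mu_i} exceeds \code{threshold}. The default \code{1e-7} marks
#' numerical extinction in long deterministic runs; the
#' fluctuating-environment protocol uses its own establishment threshold
#' (\code{3e-5}) instead.
#'
#' @param traj a \code{"replicator_trajectory"}.
#' @param threshold extinction threshold on \eqn{\mu_i}.
#' @return integer count.
#' @export
count_survivors <- function(traj, threshold = 1e-7) {
  lab <- attr(traj, "labels")
  mu <- as.numeric(traj[nrow(traj), paste0("mu_", lab)])
  sum(mu >= threshold)
}

#' Equilibrium sweeps over the external parameters
#'
#' Computes the analytic community equilibrium over a grid of target
#' replicator concentrations \code{m} (`sweep_m`), resource concentrations
#' \code{r} (`sweep_r`), or their full factorial (`sweep_grid`). The default
#' grids are log-spaced: \code{m} over \eqn{10^{[-2, 2]}} and \code{r} over
#' \eqn{10^{[-1, 1.5]}}, 81 points each.
#'
#' @param pool a \code{\link{species_pool}}.
#' @param r,m the fixed parameter for the 1-D sweeps.
#' @param m_grid,r_grid positive numeric grids.
#' @return An object of class \code{"sweep_result"}: list with
#'   \code{summary} (one row per grid cell: the grid coordinates,
#'   \code{phi_hat}, \code{n_survivors}) and \code{detail} (one row per cell
#'   per species: \code{lambda}, \code{mu_hat}, \code{x_hat}, \code{y_hat},
#'   \code{survivor}).
#' @examples
#' sw <- sweep_m(table1_pool(), r = 1, m_grid = 10^seq(-1, 1, length.out = 9))
#' sw$summary
#' @export
sweep_m <- function(pool, r = 1, m_grid = 10^seq(-2, 2, length.out = 81)) {
  stopifnot(all(m_grid > 0))
  do_sweep(pool, expand.grid(m = m_grid, r = r))
}

#' @rdname sweep_m
#' @export
sweep_r <- function(pool, m = 2, r_grid = 10^seq(-1, 1.5, length.out = 81)) {
  stopifnot(all(r_grid > 0))
  do_sweep(pool, expand.grid(m = m, r = r_grid))
}

#' @rdname sweep_m
#' @export
sweep_grid <- function(pool, m_grid = 10^seq(-2, 2, length.out = 81),
                       r_grid = 10^seq(-1, 1.5, length.out = 81)) {
  stopifnot(all(m_grid > 0), all(r_grid > 0))
  do_sweep(pool, expand.grid(m = m_grid, r = r_grid))
}

do_sweep <- function(pool, cells) {
  pool <- as_pool_df(pool)
  res <- lapply(seq_len(nrow(cells)), function(i) {
    env <- mass_environment(cells$m[i], cells$r[i])
    eq <- equilibrium_state(pool, env)
    det <- eq$table
    det$m <- cells$m[i]; det$r <- cells$r[i]
    list(summary = data.frame(m = cells$m[i], r = cells$r[i],
                              phi_hat = eq$phi_hat,
                              n_survivors = length(eq$survivors),
                              resident_E = eq$resident_E),
         detail = det)
  })
  out <- list(summary = do.call(rbind, lapply(res, `[[`, "summary")),
              detail = do.call(rbind, lapply(res, `[[`, "detail")),
              pool = pool)
  class(out) <- "sweep_result"
  out
}

#' @export
print.sweep_result <- function(x, ...) {
  cat("Equilibrium sweep over", nrow(x$summary), "grid cells,",
      nrow(x$pool), "species\n")
  print(utils::head(x$summary, 10))
  if (nrow(x$summary) > 10) cat("...\n")
  invisible(x)
}

#' Configuration of the fluctuating-environment experiment
#'
#' Defines the protocol of the variable-environment run: all species share a
#' common, slowly oscillating association rate \eqn{a(t)} (emulating
#' temperature cycles), the resource concentration \eqn{r(t)} oscillates ten
#' times faster, and a new candidate species — its \code{b} and \code{c}
#' drawn uniformly from the kinetic grids — enters every
#' \code{mutant_interval} time units at \eqn{x = 10^{-5}}, \eqn{y = 0}.
#' At each introduction, species whose total concentration is below the
#' establishment threshold \eqn{3\times10^{-5}} are removed (by default all
#' such species, standing in for stochastic extinction at low numbers; set
#' \code{removal = "newest"} to cull only the latest entrant).
#'
#' Default waveforms: \eqn{a(t) = 75 + 25\sin(2\pi t/10^4)} (spanning the
#' grid range 50–100) and \eqn{\log r(t) = \log(4)\sin(2\pi t/10^3)}
#' (spanning 0.25–4).
#'
#' @param a_wave,r_wave functions of time returning the current common
#'   association rate / resource concentration.
#' @param mutant_interval time between introductions.
#' @param intro_x introduction single-strand concentration.
#' @param establish_threshold concentration below which a species is removed
#'   at the next introduction.
#' @param m fixed target replicator concentration.
#' @param b_set,c_set sets the entrant's rates are drawn from.
#' @param t_end run length. The default covers six slow association-rate
#'   periods: the community assembles from empty during the first half, and
#'   waveform/diversity associations are measured on the saturated second
#'   half (see \code{\link{fluctuation_association}}).
#' @param removal \code{"all"} or \code{"newest"}.
#' @param seed RNG seed for the entrant draws.
#' @param rtol,atol solver tolerances for the piecewise integrations.
#' @return list of class \code{"fluctuation_config"}.
#' @export
fluctuation_config <- function(
    a_wave = function(t) 75 + 25 * sin(2 * pi * t / 1e4),
    r_wave = function(t) exp(log(4) * sin(2 * pi * t / 1e3)),
    mutant_interval = 100, intro_x = 1e-5, establish_threshold = 3e-5,
    m = 2, b_set = seq(5, 10, by = 0.25), c_set = seq(1, 5, by = 0.2),
    t_end = 6e4, removal = c("all", "newest"), seed = 1,
    rtol = 1e-8, atol = 1e-10) {
  stopifnot(mutant_interval > 0, intro_x > 0, establish_threshold > 0,
            m > 0, t_end > 0)
  structure(list(a_wave = a_wave, r_wave = r_wave,
                 mutant_interval = mutant_interval, intro_x = intro_x,
                 establish_threshold = establish_threshold, m = m,
                 b_set = b_set, c_set = c_set, t_end = t_end,
                 removal = match.arg(removal), seed = seed,
                 rtol = rtol, atol = atol),
            class = "fluctuation_config")
}

#' Run the fluctuating-environment protocol
#'
#' Integrates the mass-regulated dynamics piecewise between species
#' introductions, with the time-varying common association rate and resource
#' concentration of the configuration. See \code{\link{fluctuation_config}}
#' for the protocol.
#'
#' @param cfg a \code{\link{fluctuation_config}}.
#' @return list of class \code{"fluctuation_run"} with \code{series} (data
#'   frame: \code{time}, \code{a}, \code{r}, \code{n_species} — species at or
#'   above the establishment threshold — and \code{mu_total}), \code{events}
#'   (data frame of introductions and removals), and \code{final}
#'   (\code{label}, \code{b}, \code{c}, \code{mu} of the species present at
#'   the end).
#' @export
fluctuating_run <- function(cfg = fluctuation_config()) {
  stopifnot(inherits(cfg, "fluctuation_config"))
  set.seed(cfg$seed)
  env <- mass_environment(cfg$m, r = 1)  # r is overridden by the waveform
  forcing <- list(a = cfg$a_wave, r = cfg$r_wave)
  n_steps <- floor(cfg$t_end / cfg$mutant_interval)
  pool <- NULL; x <- numeric(0); y <- numeric(0)
  sp_id <- 0L
  series <- vector("list", n_steps + 1L)
  events <- list()
  record <- function(t) {
    mu <- x + 2 * y
    data.frame(time = t, a = cfg$a_wave(t), r = cfg$r_wave(t),
               n_species = sum(mu >= cfg$establish_threshold),
               mu_total = sum(mu))
  }
  t <- 0
  for (k in seq_len(n_steps)) {
    series[[k]] <- record(t)
    # removals (stochastic-extinction proxy), then the new entrant
    if (length(x)) {
      mu <- x + 2 * y
      below <- mu < cfg$establish_threshold
      if (cfg$removal == "newest") {
        drop <- below & seq_along(x) == length(x)
      } else drop <- below
      if (any(drop)) {
        events[[length(events) + 1L]] <-
          data.frame(time = t, event = "removal", label = pool$label[drop],
                     b = pool$b[drop], c = pool$c[drop])
        pool <- pool[!drop, , drop = FALSE]
        x <- x[!drop]; y <- y[!drop]
      }
    }
    sp_id <- sp_id + 1L
    newb <- sample(cfg$b_set, 1L)
    newc <- sample(cfg$c_set, 1L)
    lab <- paste0("m", sp_id)
    newrow <- data.frame(label = lab, a = cfg$a_wave(t), b = newb, c = newc)
    pool <- if (is.null(pool)) newrow else rbind(pool, newrow)
    x <- c(x, cfg$intro_x); y <- c(y, 0)
    events[[length(events) + 1L]] <-
      data.frame(time = t, event = "introduction", label = lab,
                 b = newb, c = newc)
    # the `a` column is a placeholder; integration uses a(t) for everyone
    p <- validate_species_pool(transform(pool, a = pmax(pool$a, 1e-9)))
    tr <- integrate_dynamics(p, env,
                             state0 = community_state(x, y),
                             model = "mass",
                             times = c(t, t + cfg$mutant_interval),
                             rtol = cfg$rtol, atol = cfg$atol,
                             forcing = forcing)
    st <- final_state(tr)
    x <- st$x; y <- st$y
    t <- t + cfg$mutant_interval
  }
  series[[n_steps + 1L]] <- record(t)
  mu <- x + 2 * y
  structure(list(series = do.call(rbind, series),
                 events = do.call(rbind, events),
                 final = data.frame(label = pool$label, b = pool$b,
                                    c = pool$c, mu = mu),
                 config = cfg),
            class = "fluctuation_run")
}

#' @export
print.fluctuation_run <- function(x, ...) {
  cat("Fluctuating-environment run to t =", max(x$series$time), "\n")
  cat("Introductions:", sum(x$events$event == "introduction"),
      "; removals:", sum(x$events$event == "removal"), "\n")
  cat("Final established species:",
      sum(x$final$mu >= x$config$establish_threshold), "\n")
  invisible(x)
}

#' Contrast the three modeling frameworks
#'
#' Produces the two qualitative comparisons between the strand-resolved
#' mass-regulated model and its alternatives.
#'
#' \strong{Phenomenological artifact}: in the power-law model the per-capita
#' growth rate of a sub-exponential species diverges at low density, so any
#' S-species invades any resident community — even one held by an E-species.
#' The mechanistic model gates invasion on \eqn{\lambda' > \hat\phi_{res}}
#' instead. The report pits a sub-exponential invader (introduced at
#' \eqn{z = 10^{-8}}) against an exponential resident in both frameworks.
#'
#' \strong{Chemostat correspondence}: in the resource-explicit chemostat the
#' inflow concentration \eqn{\rho} plays the role of the target
#' concentration \eqn{m} (more inflow, more coexistence) and the dilution
#' rate that of the resource level. The report sweeps \eqn{\rho} at fixed
#' dilution and counts surviving species by ODE integration.
#'
#' @param pool mechanistic \code{\link{species_pool}} used for both
#'   contrasts; default the reference ten-species community with species 3
#'   exponential.
#' @param env \code{\link{mass_environment}} for the mechanistic invasion
#'   contrast.
#' @param invader_mech a single S-species whose \eqn{\lambda'} falls below
#'   the resident production (so the mechanistic invasion fails).
#' @param phen_resident,phen_invader \code{\link{phenomenological_pool}}
#'   rows: the exponential resident (\eqn{p = 1}) and sub-exponential
#'   invader.
#' @param rho_grid inflow concentrations for the chemostat sweep.
#' @param dilution fixed chemostat dilution rate.
#' @param t_end integration horizon for the trajectory-based checks.
#' @return list of class \code{"model_comparison"} with elements
#'   \code{phenomenological} (invader persists: logical, plus its final
#'   concentration), \code{mechanistic} (\code{can_invade} and the gate
#'   values), and \code{chemostat} (data frame \code{rho},
#'   \code{n_survivors}, \code{r_hat}, \code{mu_hat}).
#' @export
model_comparison <- function(pool = table1_pool(exponential_species_3 = TRUE),
                             env = mass_environment(m = 2, r = 1),
                             invader_mech = species_pool(72.5, 5, 2,
                                                         label = "inv"),
                             phen_resident = phenomenological_pool(
                               k = 2, p = 1, label = "E"),
                             phen_invader = phenomenological_pool(
                               k = 0.5, p = 0.5, label = "S"),
                             rho_grid = c(1, 2, 4, 8, 16),
                             dilution = 1, t_end = 1e5) {
  pool <- as_pool_df(pool)
  ## (i) phenomenological: S invades the E-resident from z = 1e-8
  ppool <- rbind(as.data.frame(phen_resident), as.data.frame(phen_invader))
  ppool <- phenomenological_pool(ppool$k, ppool$p, ppool$label)
  z0 <- c(env$m, 1e-8)  # resident at its single-species equilibrium z = m
  tr <- integrate_dynamics(ppool, env, state0 = z0,
                           model = "phenomenological", t_end = t_end)
  z_inv <- tr[[paste0("z_", phen_invader$label[1])]][nrow(tr)]
  phen <- list(invader_final = z_inv, invades = z_inv > 1e-4)

  ## mechanistic counterpart: invasion gated by lambda' > phi_hat
  eq <- equilibrium_phi(pool, env)
  mech <- list(phi_res = eq$phi_hat,
               lambda_invader = intrinsic_growth_rate(invader_mech, env$r),
               can_invade = can_invade(invader_mech, eq$phi_hat, env$r))

  ## (ii) chemostat rho-sweep at fixed dilution
  spool <- pool[pool$a > 0, , drop = FALSE]
  chem <- do.call(rbind, lapply(rho_grid, function(rho) {
    cenv <- chemostat_environment(rho = rho, phi = dilution)
    tr <- integrate_dynamics(spool, cenv, model = "chemostat",
                             t_end = t_end, rtol = 1e-8, atol = 1e-10)
    st <- final_state(tr)
    data.frame(rho = rho, n_survivors = count_survivors(tr),
               r_hat = st$rvar, mu_hat = sum(st$x + 2 * st$y))
  }))
  structure(list(phenomenological = phen, mechanistic = mech,
                 chemostat = chem),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("Phenomenological model: sub-exponential invader from z = 1e-8 ",
      if (x$phenomenological$invades) "ESTABLISHES" else "fails",
      " (final z = ", format(x$phenomenological$invader_final, digits = 4),
      ")\n", sep = "")
  cat("Mechanistic model: lambda' = ",
      format(x$mechanistic$lambda_invader, digits = 4), " vs phi_res = ",
      format(x$mechanistic$phi_res, digits = 4), " -> invasion ",
      if (x$mechanistic$can_invade) "succeeds" else "FAILS", "\n", sep = "")
  cat("Chemostat rho-sweep (dilution fixed):\n")
  print(x$chemostat, digits = 4)
  invisible(x)
}

#' Diversity-waveform association of a fluctuating run
#'
#' Quantifies how the number of established species tracks the two
#' environmental waveforms, after discarding the assembly transient
#' (\code{burn_in}; default the first half of the run, by which time the
#' community has saturated under the default protocol).
#'
#' Three summaries are produced. (1) Window means of the species count
#' around each association-rate maximum and minimum in the measured part of
#' the run. (2) The correlation between the count — detrended with a
#' centered rolling mean one slow period wide, to remove any residual
#' accumulation — and \eqn{a(t)}. (3) The fast-time-scale phase profile:
#' the count detrended with a rolling mean one fast period wide, averaged
#' by phase of the resource cycle, together with the phases at which that
#' profile is maximal/minimal and the phases at which \eqn{r(t)} itself is
#' minimal/maximal.
#'
#' @param run a \code{"fluctuation_run"}.
#' @param slow_period,fast_period periods of \eqn{a(t)} and \eqn{r(t)} in
#'   time units (defaults match \code{\link{fluctuation_config}}).
#' @param burn_in time discarded before measuring.
#' @param window half-width of the extremum windows.
#' @return list with \code{a_max_mean}, \code{a_min_mean} (average count
#'   over the a-extremum windows), \code{cor_a} (detrended correlation with
#'   \eqn{a(t)}), \code{phase_profile} (data frame \code{phase},
#'   \code{count}), \code{peak_phase}, \code{trough_phase},
#'   \code{r_min_phase}, \code{r_max_phase}.
#' @export
fluctuation_association <- function(run, slow_period = 1e4,
                                    fast_period = 1e3,
                                    burn_in = max(run$series$time) / 2,
                                    window = 1000) {
  stopifnot(inherits(run, "fluctuation_run"))
  s <- run$series[run$series$time >= burn_in, ]
  dt <- diff(s$time[1:2])
  roll <- function(v, width) {
    k <- max(3L, 2L * floor(width / dt / 2) + 1L)  # odd window
    as.numeric(stats::filter(v, rep(1 / k, k), sides = 2))
  }
  # (1) counts around a-extrema
  tt <- s$time
  a_max_times <- tt[which(diff(sign(diff(s$a))) < 0) + 1L]
  a_min_times <- tt[which(diff(sign(diff(s$a))) > 0) + 1L]
  wmean <- function(t0) mean(s$n_species[abs(tt - t0) <= window])
  a_max_mean <- mean(vapply(a_max_times, wmean, 0))
  a_min_mean <- mean(vapply(a_min_times, wmean, 0))
  # (2) slow-detrended correlation with a(t)
  d_slow <- s$n_species - roll(s$n_species, slow_period)
  ok <- !is.na(d_slow)
  cor_a <- stats::cor(d_slow[ok], s$a[ok])
  # (3) fast phase profile vs the resource cycle
  d_fast <- s$n_species - roll(s$n_species, fast_period)
  phase <- tt %% fast_period
  ok <- !is.na(d_fast)
  prof <- tapply(d_fast[ok], phase[ok], mean)
  profile <- data.frame(phase = as.numeric(names(prof)),
                        count = as.numeric(prof))
  rphase <- tapply(s$r[ok], phase[ok], mean)
  list(a_max_mean = a_max_mean, a_min_mean = a_min_mean, cor_a = cor_a,
       phase_profile = profile,
       peak_phase = profile$phase[which.max(profile$count)],
       trough_phase = profile$phase[which.min(profile$count)],
       r_min_phase = profile$phase[which.min(rphase)],
       r_max_phase = profile$phase[which.max(rphase)])
}
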