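#' Load a run configuration
#'
#' Reads a YAML (or JSON) configuration describing a model run. Recognized
#' keys:
#' \itemize{
#'   \item \code{model}: \code{"mass"} (default), \code{"chemostat"} or
#'     \code{"phenomenological"}.
#'   \item exactly one species source: \code{species} (list of
#'     \code{{label, a, b, c}}, or \code{{label, k, p}} for the
#'     phenomenological model), \code{table1} (logical or
#'     \code{{exponential_species_3: true}}), or \code{grid_sample}
#'     (\code{{n, seed}}).
#'   \item \code{environment}: \code{{m, r}}, or \code{chemostat}:
#'     \code{{rho, phi}}.
#'   \item \code{solver}: \code{{t_end, rtol, atol}} (optional).
#'   \item \code{initial_state}: \code{{x: [...], y: [...], r: ...}}
#'     (optional).
#' }
#'
#' @param path file path (\code{.yaml}/\code{.yml}/\code{.json}).
#' @return list of class \code{"run_config"} with elements \code{model},
#'   \code{pool}, \code{env}, \code{solver}, \code{state0}.
#' @export
load_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else yaml::read_yaml(path)
  parse_config(raw)
}

parse_config <- function(raw) {
  model <- raw$model %||% "mass"
  if (!model %in% c("mass", "chemostat", "phenomenological"))
    stop("config error at 'model': must be mass, chemostat or ",
         "phenomenological")
  sources <- c("species", "table1", "grid_sample")
  given <- sources[vapply(sources, function(s) !is.null(raw[[s]]), FALSE)]
  if (length(given) != 1L)
    stop("config error: exactly one species source required ",
         "(species | table1 | grid_sample); got: ",
         if (length(given)) paste(given, collapse = ", ") else "none")
  pool <- switch(given,
    species = {
      sp <- raw$species
      if (is.data.frame(sp)) sp <- as.list(sp)
      else sp <- as.list(do.call(rbind.data.frame, lapply(sp, as.data.frame)))
      if (model == "phenomenological") {
        if (is.null(sp$k) || is.null(sp$p))
          stop("config error at 'species': phenomenological species need ",
               "fields k and p")
        phenomenological_pool(sp$k, sp$p, sp$label)
      } else {
        if (is.null(sp$a) || is.null(sp$b) || is.null(sp$c))
          stop("config error at 'species': need fields a, b, c")
        species_pool(sp$a, sp$b, sp$c, sp$label)
      }
    },
    table1 = {
      flag <- is.list(raw$table1) && isTRUE(raw$table1$exponential_species_3)
      table1_pool(exponential_species_3 = flag)
    },
    grid_sample = {
      gs <- raw$grid_sample
      if (is.null(gs$n)) stop("config error at 'grid_sample.n': required")
      if (!is.null(gs$seed)) set.seed(gs$seed)
      sample_grid_pool(gs$n)
    })
  env <- if (model == "chemostat") {
    ch <- raw$chemostat
    if (is.null(ch$rho) || is.null(ch$phi))
      stop("config error at 'chemostat': need rho and phi")
    chemostat_environment(ch$rho, ch$phi)
  } else {
    e <- raw$environment
    if (is.null(e$m)) stop("config error at 'environment.m': required")
    mass_environment(e$m, e$r %||% 1)
  }
  solver <- list(t_end = raw$solver$t_end %||% 1e6,
                 rtol = raw$solver$rtol %||% 1e-10,
                 atol = raw$solver$atol %||% 1e-12)
  state0 <- NULL
  if (!is.null(raw$initial_state)) {
    s <- raw$initial_state
    state0 <- if (model == "phenomenological") as.numeric(s$z %||% s$x)
      else community_state(as.numeric(s$x),
                           as.numeric(s$y %||% rep(0, length(s$x))),
                           rvar = if (model == "chemostat")
                             (s$r %||% env$rho))
  }
  structure(list(model = model, pool = pool, env = env, solver = solver,
                 state0 = state0, raw = raw),
            class = "run_config")
}

#' Write and read package outputs
#'
#' `write_trajectory()` writes the time series as CSV (column order: time,
#' then per-species strand concentrations in pool order, then per-species
#' totals, the community total, and the normalized production), with floats
#' at 12 significant digits. `write_equilibrium()` and `write_invasion()`
#' serialize their reports as JSON (numbers unrounded);
#' `write_sweep()` writes the tidy per-cell-per-species table and the
#' per-cell summary as two CSVs.
#'
#' @param traj,sol,outcome,result objects produced by the package.
#' @param path output file path; for `write_sweep`, the summary goes to
#'   `path` and the detail to `sub("\\.csv$", "_detail.csv", path)`.
#' @return the path, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  df <- as.data.frame(traj)
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], signif, digits = 12)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  utils::read.csv(path, check.names = FALSE)
}

#' @rdname write_trajectory
#' @export
write_equilibrium <- function(sol, path) {
  stopifnot(inherits(sol, "replicator_equilibrium"))
  per <- lapply(seq_len(nrow(sol$table)), function(i) {
    row <- sol$table[i, ]
    list(lambda = row$lambda, x_hat = row$x_hat, y_hat = row$y_hat,
         mu_hat = row$mu_hat, survivor = row$survivor)
  })
  names(per) <- sol$table$label
  obj <- list(phi_hat = sol$phi_hat, survivors = sol$survivors,
              species = per,
              flags = list(resident_E = if (is.na(sol$resident_E)) NULL
                           else sol$resident_E,
                           marginal = sol$marginal),
              environment = list(m = sol$env$m, r = sol$env$r))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
write_invasion <- function(outcome, path) {
  stopifnot(inherits(outcome, "invasion_outcome"))
  obj <- list(invader = outcome$invader, lambda = outcome$lambda_invader,
              phi_res = outcome$phi_res, phi_new = outcome$phi_new,
              can_invade = outcome$can_invade, extinct = outcome$extinct,
              survivors = outcome$survivors)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
write_sweep <- function(result, path) {
  stopifnot(inherits(result, "sweep_result"))
  s <- result$summary
  num <- vapply(s, is.numeric, TRUE)
  s[num] <- lapply(s[num], signif, digits = 12)
  utils::write.csv(s, path, row.names = FALSE, quote = FALSE)
  d <- result$detail
  num <- vapply(d, is.numeric, TRUE)
  d[num] <- lapply(d[num], signif, digits = 12)
  utils::write.csv(d, sub("\\.csv$", "_detail.csv", path), row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
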