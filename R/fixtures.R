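#' Reference ten-species community
#'
#' The fixed sample of ten kinetic parameter combinations used throughout the
#' package's worked examples and experiments. Species 3 doubles as the
#' E-species variant: with \code{exponential_species_3 = TRUE} its
#' association rate is set to 0 (keeping \code{b = 7}, \code{c = 3.6}), so a
#' community of nine S-species plus one E-species can be formed without
#' changing any other rate.
#'
#' @param exponential_species_3 logical; make species 3 exponential.
#' @return a \code{\link{species_pool}} of ten species labelled
#'   \code{"s1"} ... \code{"s10"}.
#' @examples
#' round(intrinsic_growth_rate(table1_pool(), r = 1), 3)
#' @export
table1_pool <- function(exponential_species_3 = FALSE) {
  pool <- species_pool(
    a = c(72.5, 72.5, 72.5, 72.5, 77.5, 77.5, 77.5, 82.5, 87.5, 100),
    b = c(5, 6, 7, 7.75, 8.75, 9.75, 10, 6, 5.5, 7),
    c = c(3.4, 5, 3.6, 5, 2, 1.6, 4.4, 2.8, 4.4, 4),
    label = paste0("s", 1:10))
  if (exponential_species_3) pool$a[3] <- 0
  pool
}

#' Kinetic parameter grids
#'
#' The discrete parameter sets that define the permissible kinetic regime
#' (association fastest, replication slowest at order-one concentrations):
#' \code{a} in \code{seq(50, 100, by = 2.5)}, \code{b} in
#' \code{seq(5, 10, by = 0.25)}, \code{c} in \code{seq(1, 5, by = 0.2)} —
#' 21 values each. \code{methods_parameter_grid()} returns the full
#' Cartesian product (21^3 = 9261 combinations, ordered a-major then b then
#' c); \code{methods_bc_grid()} the 21^2 = 441 \code{b}-\code{c}
#' combinations used when all species share a common association rate.
#'
#' @return a \code{\link{species_pool}} (for \code{methods_bc_grid}, a data
#'   frame with columns \code{b} and \code{c} only).
#' @examples
#' nrow(methods_parameter_grid())  # 9261
#' nrow(methods_bc_grid())         # 441
#' @export
methods_parameter_grid <- function() {
  g <- expand.grid(c = seq(1, 5, by = 0.2),
                   b = seq(5, 10, by = 0.25),
                   a = seq(50, 100, by = 2.5))
  g <- g[order(g$a, g$b, g$c), c("a", "b", "c")]
  rownames(g) <- NULL
  species_pool(g$a, g$b, g$c, label = paste0("g", seq_len(nrow(g))))
}

#' @rdname methods_parameter_grid
#' @export
methods_bc_grid <- function() {
  g <- expand.grid(c = seq(1, 5, by = 0.2), b = seq(5, 10, by = 0.25))
  g <- g[order(g$b, g$c), c("b", "c")]
  rownames(g) <- NULL
  g
}

#' Draw random communities from the kinetic parameter grids
#'
#' Samples \code{n} species uniformly (with replacement across the grid, but
#' distinct combinations within one community) from the full a-b-c grid.
#' Randomness flows through R's global RNG; call \code{set.seed()} first for
#' reproducibility.
#'
#' @param n number of species.
#' @return a \code{\link{species_pool}}.
#' @export
sample_grid_pool <- function(n) {
  a <- seq(50, 100, by = 2.5)
  b <- seq(5, 10, by = 0.25)
  c <- seq(1, 5, by = 0.2)
  idx <- sample(21L^3L, n, replace = FALSE)
  ia <- (idx - 1L) %/% 441L
  ib <- ((idx - 1L) %/% 21L) %% 21L
  ic <- (idx - 1L) %% 21L
  species_pool(a[ia + 1L], b[ib + 1L], c[ic + 1L],
               label = paste0("g", idx))
}
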