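#' Define a pool of replicator species by their kinetic rate constants
#'
#' A replicator species is characterized by three rate constants: the
#' association rate \code{a} at which two of its single strands pair into a
#' replication-inert duplex, the dissociation rate \code{b} of that duplex,
#' and the template-directed replication rate \code{c}. Species with
#' \code{a > 0} are self-inhibited and grow sub-exponentially (S-species);
#' a species with \code{a = 0} never pairs spontaneously and grows
#' exponentially (E-species).
#'
#' @param a numeric vector of association rates (concentration^-1 time^-1,
#'   \code{>= 0}); \code{a = 0} marks an E-species.
#' @param b numeric vector of duplex dissociation rates (time^-1, \code{> 0}).
#' @param c numeric vector of replication rates
#'   (concentration^-1 time^-1, \code{> 0}).
#' @param label optional character vector of species identifiers; defaults to
#'   \code{"sp1"}, \code{"sp2"}, ...
#'
#' @return A data frame of class \code{"species_pool"} with columns
#'   \code{label}, \code{a}, \code{b}, \code{c}. Vectors are recycled to a
#'   common length as usual.
#' @examples
#' species_pool(a = c(72.5, 0), b = c(5, 7), c = c(3.4, 3.6))
#' @export
species_pool <- function(a, b, c, label = NULL) {
  n <- max(length(a), length(b), length(c))
  a <- rep_len(as.numeric(a), n)
  b <- rep_len(as.numeric(b), n)
  c <- rep_len(as.numeric(c), n)
  if (is.null(label)) label <- paste0("sp", seq_len(n))
  label <- rep_len(as.character(label), n)
  pool <- data.frame(label = label, a = a, b = b, c = c,
                     stringsAsFactors = FALSE)
  validate_species_pool(pool)
}

#' @rdname species_pool
#' @param x object to test or validate.
#' @export
is_species_pool <- function(x) inherits(x, "species_pool")

#' @rdname species_pool
#' @export
validate_species_pool <- function(x) {
  x <- as.data.frame(x)
  need <- c("label", "a", "b", "c")
  if (!all(need %in% names(x)))
    stop("species pool needs columns: ", paste(need, collapse = ", "))
  if (nrow(x) < 1L) stop("species pool is empty")
  with(x, {
    if (any(!is.finite(a)) || any(!is.finite(b)) || any(!is.finite(c)))
      stop("kinetic rates must be finite")
    if (any(a < 0)) stop("association rates 'a' must be >= 0")
    if (any(b <= 0)) stop("dissociation rates 'b' must be > 0")
    if (any(c <= 0)) stop("replication rates 'c' must be > 0")
  })
  if (anyDuplicated(x$label)) stop("species labels must be unique")
  class(x) <- unique(c("species_pool", class(x)))
  x
}

#' @rdname species_pool
#' @export
is_exponential <- function(x) {
  if (is_species_pool(x) || is.data.frame(x)) x$a == 0 else x == 0
}

#' Intrinsic growth rate of a replicator species
#'
#' The growth rate of a species at vanishing own concentration, once the
#' single-/double-strand ratio has settled:
#' \deqn{\lambda = \frac{-(b + c r) + \sqrt{(b + c r)^2 + 4 b c r}}{2}.}
#' It is the largest value the density-dependent fitness \code{\link{growth_rate}}
#' can take, it does not depend on the association rate \code{a}, and an
#' E-species (\code{a = 0}) grows at exactly this rate at any concentration.
#'
#' Evaluated in the cancellation-free form
#' \eqn{\lambda = 2 b c r / (s + \sqrt{s^2 + 4 b c r})} with
#' \eqn{s = b + c r}, which is exact and avoids loss of precision when
#' \eqn{b c r \ll s^2}.
#'
#' @param pool a \code{\link{species_pool}} (or anything coercible: a data
#'   frame with columns \code{a}, \code{b}, \code{c}).
#' @param r resource concentration (\code{>= 0}).
#' @return numeric vector of intrinsic growth rates, one per species.
#' @examples
#' intrinsic_growth_rate(species_pool(a = 72.5, b = 7, c = 3.6), r = 1) # 2
#' @export
intrinsic_growth_rate <- function(pool, r) {
  pool <- as_pool_df(pool)
  growth_rate(pool, r = r, x = 0)
}

#' Density-dependent growth rate (fitness) of a replicator species
#'
#' The long-term growth rate of a species held at single-strand
#' concentration \code{x}:
#' \deqn{\Lambda(x) = \frac{-(2 a x + b + c r) +
#'   \sqrt{(2 a x + b + c r)^2 + 4 b c r}}{2}.}
#' For an S-species (\code{a > 0}) this is strictly decreasing in \code{x} —
#' the self-inhibition that makes growth sub-exponential — with
#' \eqn{\Lambda(0) = \lambda}, the intrinsic rate.
#'
#' @inheritParams intrinsic_growth_rate
#' @param x single-strand concentration(s) (\code{>= 0}); recycled against
#'   the pool.
#' @return numeric vector of growth rates.
#' @seealso \code{\link{intrinsic_growth_rate}}, \code{\link{invert_growth_rate}}
#' @export
growth_rate <- function(pool, r, x) {
  pool <- as_pool_df(pool)
  if (!is.numeric(r) || length(r) != 1L || !is.finite(r) || r < 0)
    stop("'r' must be a single finite non-negative number")
  if (any(!is.finite(x)) || any(x < 0))
    stop("'x' must be finite and non-negative")
  s <- 2 * pool$a * x + pool$b + pool$c * r
  q <- 4 * pool$b * pool$c * r
  # stable: (-s + sqrt(s^2+q))/2 == 2*b*c*r/(s + sqrt(s^2+q))
  2 * pool$b * pool$c * r / (s + sqrt(s * s + q))
}

# Accept a species_pool, plain data.frame, or a single-row list.
as_pool_df <- function(pool) {
  if (is_species_pool(pool)) return(pool)
  if (is.data.frame(pool)) return(validate_species_pool(pool))
  if (is.list(pool) && all(c("a", "b", "c") %in% names(pool)))
    return(species_pool(pool$a, pool$b, pool$c, pool$label))
  stop("cannot interpret 'pool' as a species pool")
}

#' Combine species pools
#'
#' Row-binds pools (or plain kinetics data frames) into one validated pool.
#'
#' @param ... pools to combine.
#' @return a \code{\link{species_pool}}.
#' @export
rbind_pools <- function(...) {
  parts <- lapply(list(...), function(p) as.data.frame(as_pool_df(p)))
  validate_species_pool(do.call(rbind, parts))
}
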