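# Independent oracles used across the suite.

# Naive textbook form of the growth-rate formula (deliberately not the
# cancellation-free form used by the package).
lambda_naive <- function(b, c, r) {
  (-(b + c * r) + sqrt((b + c * r)^2 + 4 * b * c * r)) / 2
}
Lambda_naive <- function(a, b, c, r, x) {
  s <- 2 * a * x + b + c * r
  (-s + sqrt(s^2 + 4 * b * c * r)) / 2
}

# Integrate a community to its steady state and return per-species totals.
integrated_equilibrium <- function(pool, env, ...) {
  tr <- integrate_dynamics(pool, env, ...)
  st <- final_state(tr)
  list(mu = st$x + 2 * st$y, state = st, traj = tr,
       phi = tr$phi[nrow(tr)])
}

expect_rel_equal <- function(actual, expected, tol, scale = NULL) {
  s <- if (is.null(scale)) pmax(abs(expected), 1e-12) else scale
  expect_true(max(abs(actual - expected) / s) < tol,
              label = paste0("relative difference ",
                             format(max(abs(actual - expected) / s))))
}
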