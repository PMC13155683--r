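env21 <- mass_environment(m = 2, r = 1)

test_that("growth-rate inversion round-trips through the fitness formula", {
  kin <- species_pool(a = 72.5, b = 6, c = 5, label = "k")
  # closed-form worked example
  xh <- invert_growth_rate(kin, r = 1, phi = 2)
  expect_equal(xh, 4 / 290, tolerance = 1e-12)
  expect_equal(growth_rate(kin, r = 1, x = xh), 2, tolerance = 1e-12)
  # phi = lambda forces x = 0 (numerator vanishes by the defining quadratic)
  lam <- intrinsic_growth_rate(kin, r = 1)
  expect_equal(invert_growth_rate(kin, r = 1, phi = lam), 0,
               tolerance = 1e-12)
  # half the intrinsic rate: positive solution, exact round trip
  set.seed(5)
  for (i in 1:10) {
    k2 <- sample_grid_pool(1)
    l2 <- intrinsic_growth_rate(k2, r = 1)
    x2 <- invert_growth_rate(k2, r = 1, phi = l2 / 2)
    expect_gt(x2, 0)
    expect_equal(growth_rate(k2, r = 1, x = x2), l2 / 2, tolerance = 1e-12)
  }
  expect_error(invert_growth_rate(kin, r = 1, phi = lam * 1.01), "excluded")
  expect_error(invert_growth_rate(kin, r = 1, phi = 0), "positive")
  expect_error(invert_growth_rate(species_pool(0, 6, 5), 1, 1), "S-species")
})

test_that("per-species equilibrium mass is decreasing in phi and zero beyond lambda", {
  kin <- species_pool(a = 72.5, b = 6, c = 5, label = "k")
  expect_equal(species_equilibrium_mass(kin, r = 1, phi = 2),
               5 * (4 / 290) / 2, tolerance = 1e-12)
  lam <- intrinsic_growth_rate(kin, r = 1)
  expect_identical(species_equilibrium_mass(kin, r = 1, phi = lam), 0)
  expect_identical(species_equilibrium_mass(kin, r = 1, phi = lam + 1), 0)
  phis <- seq(0.05, lam * 0.999, length.out = 40)
  mus <- vapply(phis, function(p) species_equilibrium_mass(kin, 1, p), 0)
  expect_true(all(diff(mus) < 0))
  # divergence like r*c*b*c*r/(2a phi^2) as phi -> 0+
  expect_equal(species_equilibrium_mass(kin, 1, 1e-5) * (2 * 72.5 * 1e-10),
               1 * 5 * 6 * 5 * 1, tolerance = 1e-3)
})

test_that("pure-S equilibrium: unique root, mass constraint, strand-ratio identities, ODE agreement", {
  pool <- table1_pool()
  eq <- equilibrium_state(pool, env21)
  expect_equal(sum(eq$table$mu_hat), 2, tolerance = 1e-9)
  expect_length(eq$survivors, 10)
  expect_true(is.na(eq$resident_E))
  # survivor growth rates sit exactly at phi_hat
  for (i in which(eq$table$survivor)) {
    expect_equal(growth_rate(pool[i, , drop = FALSE], 1, eq$table$x_hat[i]),
                 eq$phi_hat, tolerance = 1e-9)
  }
  # ratio identities: x/mu = phi/(r c), y/x = (cr - phi)/(2 phi)
  with(eq$table, {
    expect_rel_equal(x_hat / mu_hat, eq$phi_hat / (1 * c), tol = 1e-9)
    expect_rel_equal(y_hat / x_hat, (c * 1 - eq$phi_hat) / (2 * eq$phi_hat),
                     tol = 1e-9)
  })
  # ODE oracle: state matches the long integration per species
  res <- integrated_equilibrium(pool, env21)
  expect_rel_equal(res$mu, eq$table$mu_hat, tol = 1e-6)
  expect_equal(res$phi, eq$phi_hat, tolerance = 1e-6)
  expect_equal(normalized_production(res$state$x, pool, env21), eq$phi_hat,
               tolerance = 1e-6)
})

test_that("a resident E-species pins the normalized production at its own growth rate", {
  # single E-species: phi_hat = lambda0, mass = m, Eq (6) ratio
  ekin <- species_pool(a = 0, b = 7, c = 3.6, label = "E")
  for (m in c(0.5, 2, 20)) {
    eq <- equilibrium_state(ekin, mass_environment(m, 1))
    expect_equal(eq$phi_hat, 2.000, tolerance = 1e-4)
    expect_equal(eq$table$mu_hat, m)
    expect_equal(eq$table$x_hat / eq$table$mu_hat, eq$phi_hat / (1 * 3.6))
  }
  # ten-species community with species 3 exponential
  poolE <- table1_pool(exponential_species_3 = TRUE)
  eqE <- equilibrium_state(poolE, env21)
  expect_equal(eqE$phi_hat, 2.000, tolerance = 1e-12)
  expect_identical(eqE$resident_E, "s3")
  lam <- intrinsic_growth_rate(poolE, 1)
  expect_setequal(eqE$survivors,
                  c("s3", poolE$label[poolE$a > 0 & lam > 2]))
  expect_equal(sum(eqE$table$mu_hat), 2, tolerance = 1e-9)
  # duplicate-lambda E-species are degenerate input
  twoE <- species_pool(a = c(0, 0), b = c(7, 7), c = c(3.6, 3.6))
  expect_error(equilibrium_state(twoE, env21), "tie-breaking")
  expect_error(equilibrium_state(table1_pool(), mass_environment(2, 0)),
               "no production")
})

test_that("equilibrium matches the ODE steady state across random communities", {
  set.seed(202)
  for (i in 1:10) {
    pool <- sample_grid_pool(sample(2:10, 1))
    env <- mass_environment(runif(1, 0.1, 10), runif(1, 0.25, 4))
    eq <- equilibrium_state(pool, env)
    res <- integrated_equilibrium(pool, env)
    surv <- eq$table$mu_hat > 1e-7
    expect_identical(res$mu > 1e-7, surv)
    if (any(surv))
      expect_rel_equal(res$mu[surv], eq$table$mu_hat[surv], tol = 1e-6)
  }
})

test_that("phi_hat is monotone in m and r, and extinction order follows lambda", {
  pool <- table1_pool()
  ms <- 10^seq(-2, 2, length.out = 41)
  phis_m <- vapply(ms, function(m)
    equilibrium_phi(pool, mass_environment(m, 1))$phi_hat, 0)
  expect_true(all(diff(phis_m) < 0))
  rs <- 10^seq(-1, 1.5, length.out = 41)
  phis_r <- vapply(rs, function(r)
    equilibrium_phi(pool, mass_environment(2, r))$phi_hat, 0)
  expect_true(all(diff(phis_r) > 0))
  # survivor count non-decreasing in m; species leave in order of lambda
  counts <- vapply(ms, function(m)
    length(equilibrium_phi(pool, mass_environment(m, 1))$survivors), 0L)
  expect_true(all(diff(counts) >= 0))
  lam <- intrinsic_growth_rate(pool, 1)
  for (m in ms) {
    surv <- equilibrium_phi(pool, mass_environment(m, 1))$survivors
    # the survivor set is always the top-k species by lambda
    topk <- pool$label[order(lam, decreasing = TRUE)][seq_along(surv)]
    expect_setequal(surv, topk)
  }
})

test_that("an E-species monopolizes any increase in the target concentration", {
  poolE <- table1_pool(exponential_species_3 = TRUE)
  eq1 <- equilibrium_state(poolE, mass_environment(2, 1))
  eq2 <- equilibrium_state(poolE, mass_environment(2.5, 1))
  dm <- 0.5
  dE <- eq2$table$mu_hat[3] - eq1$table$mu_hat[3]
  expect_equal(dE / dm, 1, tolerance = 1e-9)
  dS <- eq2$table$mu_hat[-3] - eq1$table$mu_hat[-3]
  expect_lt(max(abs(dS)), 1e-9)
})

test_that("critical target concentration marks the first extinction", {
  pool <- table1_pool()
  cm <- critical_target_concentration(pool, r = 1)
  expect_identical(cm$exiting, "s6")
  expect_equal(cm$lambda_min, min(intrinsic_growth_rate(pool, 1)))
  # phi_hat at m* equals lambda_min
  eq_star <- equilibrium_phi(pool, mass_environment(cm$m_star, 1))
  expect_equal(eq_star$phi_hat, cm$lambda_min, tolerance = 1e-10)
  # survivor count flips by exactly one across m*
  n_above <- length(equilibrium_phi(pool,
    mass_environment(cm$m_star * 1.001, 1))$survivors)
  n_below <- length(equilibrium_phi(pool,
    mass_environment(cm$m_star * 0.999, 1))$survivors)
  expect_identical(n_above - n_below, 1L)
  # degenerate communities are flagged, not silently resolved
  twins <- species_pool(a = c(60, 80), b = c(6, 6), c = c(3, 3))
  expect_error(critical_target_concentration(twins, 1), "degenerate")
  expect_error(critical_target_concentration(pool[1, , drop = FALSE], 1),
               "single-species")
})
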