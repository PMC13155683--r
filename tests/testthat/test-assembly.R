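env21 <- mass_environment(m = 2, r = 1)

test_that("invasion is gated by lambda' > phi_res, independently of a", {
  fast <- species_pool(a = 77.5, b = 10, c = 4.4)   # lambda = 2.590
  expect_true(can_invade(fast, phi_res = 2.000, r = 1))
  # equality is not enough (strict inequality)
  lam <- intrinsic_growth_rate(fast, 1)
  expect_false(can_invade(fast, phi_res = lam, r = 1))
  # association rate plays no role in the decision
  slow_a <- species_pool(a = 1e-3, b = 10, c = 4.4)
  high_a <- species_pool(a = 500, b = 10, c = 4.4)
  for (phi in c(0.5, 2, 2.5, 2.6))
    expect_identical(can_invade(slow_a, phi, 1), can_invade(high_a, phi, 1))
})

test_that("a successful E-invader displaces the resident E-species", {
  poolE <- table1_pool(exponential_species_3 = TRUE)
  einv <- species_pool(a = 0, b = 9, c = 4.4, label = "Einv")
  out <- invade(poolE, einv, env21)
  expect_true(out$can_invade)
  expect_true("s3" %in% out$extinct)
  # the new E pins production at its own lambda
  expect_equal(out$phi_new, out$lambda_invader, tolerance = 1e-12)
  # extirpated residents have lambda inside the exclusion zone
  lam <- intrinsic_growth_rate(poolE, 1)
  names(lam) <- poolE$label
  for (s in setdiff(out$extinct, "s3")) {
    expect_gt(lam[[s]], out$phi_res)
    expect_lte(lam[[s]], out$phi_new)
  }
})

test_that("a mild S-invader enters a pure-S community without extinctions", {
  residents <- table1_pool()[c(1, 5, 6, 8), ]  # low-lambda subset
  eq_res <- equilibrium_phi(residents, env21)
  inv <- species_pool(a = 90, b = 6.5, c = 2.4, label = "inv")
  out <- invade(residents, inv, env21)
  expect_true(out$can_invade)
  lam_min <- min(intrinsic_growth_rate(residents, 1))
  expect_lt(out$phi_new, lam_min)
  expect_identical(out$extinct, character(0))
  expect_length(out$survivors, 5)
})

test_that("an S-invader into an E-held community leaves production and S-residents unchanged", {
  poolE <- table1_pool(exponential_species_3 = TRUE)
  eq_before <- equilibrium_state(poolE, env21)
  sinv <- species_pool(a = 80, b = 9, c = 4.4, label = "Sinv")
  out <- invade(poolE, sinv, env21)
  expect_true(out$can_invade)
  expect_identical(out$phi_new, out$phi_res)  # production pinned by the E
  expect_identical(out$extinct, character(0))
  after <- out$equilibrium$table
  before <- eq_before$table
  idxS <- match(before$label[before$survivor & before$a > 0], after$label)
  expect_rel_equal(after$mu_hat[idxS],
                   before$mu_hat[before$survivor & before$a > 0], tol = 1e-9)
  # the E-species' mass drops by exactly the invader's equilibrium mass
  mu_inv <- after$mu_hat[after$label == "Sinv"]
  expect_equal(before$mu_hat[before$label == "s3"] -
                 after$mu_hat[after$label == "s3"],
               mu_inv, tolerance = 1e-9)
})

test_that("exclusion-zone width grows with b' and shrinks with a'; invasiveness ignores a'", {
  residents <- table1_pool()[c(1, 5, 6, 8), ]
  widths_b <- vapply(seq(6, 10, by = 1), function(b) {
    out <- invade(residents, species_pool(80, b, 4, label = "v"), env21)
    exclusion_zone(out)$width
  }, 0)
  expect_true(all(diff(widths_b) >= 0))
  outs_a <- lapply(c(55, 70, 85, 100), function(a)
    invade(residents, species_pool(a, 8, 4, label = "v"), env21))
  widths_a <- vapply(outs_a, function(o) exclusion_zone(o)$width, 0)
  expect_true(all(diff(widths_a) <= 0))
  lambdas_a <- vapply(outs_a, `[[`, 0, "lambda_invader")
  expect_equal(diff(lambdas_a), rep(0, 3))
  # a failed invasion has an empty zone
  fail <- invade(residents, species_pool(80, 5, 0.5, label = "v"), env21)
  expect_false(fail$can_invade)
  expect_identical(exclusion_zone(fail)$width, 0)
})

test_that("production never decreases across random successful invasions", {
  set.seed(31)
  n_done <- 0
  while (n_done < 40) {
    residents <- sample_grid_pool(sample(2:8, 1))
    env <- mass_environment(runif(1, 0.5, 5), runif(1, 0.5, 2))
    invader <- sample_grid_pool(1)
    invader$label <- "inv"
    out <- invade(residents, invader, env)
    if (!out$can_invade) next
    n_done <- n_done + 1
    expect_gte(out$phi_new, out$phi_res - 1e-12)
    # the invader survives in the environment it creates
    expect_gt(out$lambda_invader, out$phi_new - 1e-9)
    expect_true("inv" %in% out$survivors)
  }
})

test_that("resident concentration response to a production increase scales inversely with a", {
  # same b, c, different a: equal relative drop, absolute response ~ 1/a
  pool <- species_pool(a = c(55, 75, 95), b = 8, c = 4,
                       label = c("lo", "mid", "hi"))
  dmu <- vapply(seq_len(3), function(i) {
    k <- pool[i, , drop = FALSE]
    (species_equilibrium_mass(k, 1, 1.5 + 1e-6) -
       species_equilibrium_mass(k, 1, 1.5)) / 1e-6
  }, 0)
  expect_true(all(dmu < 0))
  expect_true(all(diff(abs(dmu)) < 0))  # smaller a -> larger drop
  expect_equal(abs(dmu) * c(55, 75, 95) / (abs(dmu[1]) * 55), rep(1, 3),
               tolerance = 1e-4)
  # an E-species cannot re-equilibrate: any phi above its lambda leaves it
  # zero mass, and it only persists by pinning phi at exactly lambda0
  ekin <- species_pool(0, 8, 4, label = "E")
  lam0 <- intrinsic_growth_rate(ekin, 1)
  expect_identical(species_equilibrium_mass(pool[1, , drop = FALSE], 1,
                                            intrinsic_growth_rate(
                                              pool[1, , drop = FALSE], 1)), 0)
  eqE <- equilibrium_state(rbind_pools(pool, ekin), mass_environment(4, 1))
  if (!is.na(eqE$resident_E)) expect_equal(eqE$phi_hat, lam0)
})

test_that("assembly is order-invariant and matches the all-at-once equilibrium", {
  pool <- table1_pool()
  base <- assemble(pool, env21)
  expect_equal(base$phi_hat, equilibrium_phi(pool, env21)$phi_hat)
  set.seed(17)
  for (k in 1:8) {
    ord <- sample(10)
    a <- assemble(pool, env21, order = ord)
    expect_setequal(a$survivors, base$survivors)
    expect_equal(a$phi_hat, base$phi_hat, tolerance = 1e-10)
  }
  # single-species pool
  one <- assemble(pool[4, , drop = FALSE], env21)
  expect_identical(one$survivors, "s4")
  expect_equal(one$phi_hat,
               equilibrium_phi(pool[4, , drop = FALSE], env21)$phi_hat)
  # a pool whose top-lambda member is exponential keeps it, phi_hat = lambda0
  withE <- rbind_pools(table1_pool()[c(1, 5, 6), ],
                       species_pool(0, 10, 4.4, label = "E"))
  asmE <- assemble(withE, env21, order = c(1, 2, 3, 4))
  expect_true("E" %in% asmE$survivors)
  expect_equal(asmE$phi_hat,
               intrinsic_growth_rate(species_pool(0, 10, 4.4), 1))
})

test_that("equilibrium-level invasion agrees with the trajectory-based cross-check", {
  residents <- table1_pool()[c(1, 2, 5), ]
  yes <- species_pool(77.5, 10, 4.4, label = "inv")  # lambda 2.590
  no <- species_pool(77.5, 5, 0.5, label = "inv")    # lambda 0.422 < phi_res
  expect_true(invade(residents, yes, env21)$can_invade)
  expect_false(invade(residents, no, env21)$can_invade)
  dyn_yes <- invade_dynamic(residents, yes, env21, t_end = 1e5)
  dyn_no <- invade_dynamic(residents, no, env21, t_end = 1e5)
  expect_true(dyn_yes$established)
  expect_false(dyn_no$established)
})
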