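test_that("cumulative fecundity quantile ages behave analytically", {
  flat <- flat_curve(10, 50)
  # single-atom schedule: both tails inside the one class
  s1 <- manual_schedule(20, 1)
  expect_true(fecundity_quantile_age(flat, s1, 0.05) >= 20)
  expect_true(fecundity_quantile_age(flat, s1, 0.95) < 21)
  # uniform m over 10..19 with l constant: median at 15
  s2 <- manual_schedule(10:19, rep(0.3, 10))
  expect_equal(fecundity_quantile_age(flat, s2, 0.5), 15, tolerance = 1e-12)
  expect_equal(fecundity_quantile_age(flat, s2, 0.05), 10.5, tolerance = 1e-12)
  # irregular schedule vs dense cumulative interpolation oracle
  ages <- c(10, 11, 12, 13, 14); m <- c(0.1, 0.4, 0.05, 0.3, 0.15)
  s3 <- manual_schedule(ages, m)
  fine <- seq(10, 15, by = 1e-5)
  dens <- m[pmin(5, findInterval(fine, c(ages, 15)))]
  cumf <- cumsum(dens) * 1e-5; cumf <- cumf / cumf[length(cumf)]
  for (q in c(0.05, 0.5, 0.95)) {
    oracle <- fine[which(cumf >= q)[1]]
    expect_equal(fecundity_quantile_age(flat, s3, q, "m_only"), oracle,
                 tolerance = 1e-3)
  }
  expect_error(fecundity_quantile_age(flat, manual_schedule(10:12, rep(0, 3)),
                                      0.5), "zero")
})

test_that("PrR hits its analytic extremes and stays in [0, 1]", {
  # no survival past the 95% fecundity age -> PrR = 0
  cu <- structure(list(age = c(10, 24, 50), surv = c(1, 0, 0),
                       baseline_age = 10, method = "product_limit"),
                  class = "survivorship_curve")
  s <- manual_schedule(10:24, rep(1, 15))
  r0 <- compute_prr(cu, s, "m_only")
  expect_equal(r0$prr, 0)
  expect_equal(r0$age_B, 10.75, tolerance = 1e-12)

  # all fecundity at one age, everyone survives beyond it -> PrR near 1
  r1 <- compute_prr(flat_curve(10, 50), manual_schedule(20, 5), "m_only")
  expect_gt(r1$prr, 0.95)
  expect_lte(r1$prr, 1)
  expect_true(r1$age_B <= r1$age_M)
  expect_true(r1$T_M <= r1$T_B)

  # generated cohorts: always within [0, 1]
  for (seed in c(4, 12)) {
    co <- generate_cohort(sim_config(n_females = 30, seed = seed))
    cu2 <- survivorship(co)
    s2 <- fecundity_schedule(exposure_schedule(co))
    p <- compute_prr(cu2, s2)$prr
    expect_gte(p, 0); expect_lte(p, 1)
  }
})

test_that("constant fecundity makes every permutation a tie: p = 1", {
  pt <- permutation_test(flat_curve(10, 30), manual_schedule(10:29, rep(2, 20)),
                         n_iterations = 200, seed = 1)
  expect_equal(pt$p_value, 1)
  expect_true(all(pt$null_prr == pt$observed_prr))
})

test_that("Monte-Carlo permutation p matches exhaustive enumeration on small schedules", {
  co <- generate_cohort(sim_config(n_females = 40, seed = 21))
  cu <- survivorship(co)
  s <- fecundity_schedule(exposure_schedule(co))
  # collapse to a 4-class schedule so all 24 permutations can be enumerated
  def <- which(!is.na(s$fecundity) & s$births > 0)
  keep <- s[def[1:4], ]
  class(keep) <- c("age_schedule", "data.frame")
  attr(keep, "denominator") <- "females_observed"

  obs <- compute_prr(cu, keep)$prr
  P <- all_perms(4)
  null_exact <- apply(P, 1, function(idx) {
    ks <- keep; ks$fecundity <- keep$fecundity[idx]
    compute_prr(cu, ks)$prr
  })
  p_exact <- mean(null_exact >= obs - 1e-12)

  pt <- permutation_test(cu, keep, n_iterations = 10000, seed = 5)
  se <- sqrt(p_exact * (1 - p_exact) / 10000)
  expect_lt(abs(pt$p_value - p_exact), max(3 * se, 2e-4))
  # determinism from the seed
  pt2 <- permutation_test(cu, keep, n_iterations = 10000, seed = 5)
  expect_identical(pt2$p_value, pt$p_value)
  expect_identical(pt2$null_prr, pt$null_prr)
})

test_that("permutation test refuses degenerate schedules", {
  expect_error(permutation_test(flat_curve(10, 30), manual_schedule(12, 1)),
               "fewer than 2")
})

test_that("zero age errors collapse the uncertainty simulation onto the point estimate", {
  co <- generate_cohort(full_observation_config(n_females = 30, seed = 6))
  expect_true(all(co$females$age_error_years == 0))
  u <- uncertainty_simulation(co, n_iterations = 25, n_permutations = 50,
                              seed = 2)
  expect_equal(u$sd_prr, 0)
  expect_true(all(u$prr_values == u$point$prr))
})

test_that("wider age errors do not narrow the uncertainty distribution", {
  base <- generate_cohort(sim_config(n_females = 30, seed = 14))
  doubled <- base
  doubled$females$age_error_years <- base$females$age_error_years * 2
  sds <- sapply(1:7, function(k) {
    u1 <- uncertainty_simulation(base, n_iterations = 40, n_permutations = 20,
                                 seed = 100 + k)
    u2 <- uncertainty_simulation(doubled, n_iterations = 40,
                                 n_permutations = 20, seed = 100 + k)
    c(u1$sd_prr, u2$sd_prr)
  })
  expect_gte(median(sds[2, ] - sds[1, ]), 0)
})

test_that("uncertainty draws are reproducible from the seed", {
  co <- generate_cohort(sim_config(n_females = 20, seed = 8))
  u1 <- uncertainty_simulation(co, n_iterations = 10, n_permutations = 30,
                               seed = 9)
  u2 <- uncertainty_simulation(co, n_iterations = 10, n_permutations = 30,
                               seed = 9)
  expect_identical(u1$prr_values, u2$prr_values)
  expect_identical(u1$p_values, u2$p_values)
})
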