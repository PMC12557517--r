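test_that("exposure schedule matches analytic overlaps", {
  co <- cohort_from_ages(entry = 10.0, exit = 12.0, died = TRUE)
  s <- exposure_schedule(co)
  tol <- 2 / 365.25  # day rounding of the date-anchored fixture
  expect_equal(s$exposure[s$age == 10], 1.0, tolerance = tol)
  expect_equal(s$exposure[s$age == 11], 1.0, tolerance = tol)
  expect_equal(s$females_observed[s$age %in% c(10, 11)], c(1L, 1L))

  co2 <- cohort_from_ages(entry = 10.5, exit = 11.25, died = FALSE)
  s2 <- exposure_schedule(co2)
  expect_equal(s2$exposure[s2$age == 10], 0.5, tolerance = tol)
  expect_equal(s2$exposure[s2$age == 11], 0.25, tolerance = tol)
})

test_that("exposure agrees with brute-force daily accumulation on random cohorts", {
  set.seed(31)
  for (rep in 1:3) {
    n <- 8
    entry <- runif(n, 5, 20)
    exit <- entry + runif(n, 0.5, 15)
    co <- cohort_from_ages(entry, exit, died = runif(n) < 0.5)
    s <- exposure_schedule(co)
    # oracle: fine-grained midpoint enumeration of time at risk in each class
    ca <- prrlife:::.cohort_ages(co)
    h <- 1 / (365.25 * 24)
    for (k in seq_len(nrow(s))) {
      tg <- seq(s$age[k] + h / 2, s$age[k] + 1 - h / 2, by = h)
      acc <- 0
      for (i in seq_len(n))
        acc <- acc + sum(tg >= ca$entry[i] & tg < ca$exit[i]) * h
      expect_equal(s$exposure[k], acc, tolerance = 2 * n * h)
    }
    # total exposure identity
    expect_equal(sum(s$exposure), sum(ca$exit - ca$entry), tolerance = 1e-9)
  }
})

test_that("fecundity is births over the chosen denominator, NA where undefined", {
  co <- cohort_from_ages(entry = c(10, 10.25), exit = c(12, 11.5),
                         died = c(TRUE, FALSE),
                         birth_mother = c(1L, 2L), birth_age = c(10.6, 10.9))
  s <- fecundity_schedule(exposure_schedule(co))
  expect_equal(s$fecundity[s$age == 10], 2 / 2)
  expect_equal(s$fecundity[s$age == 11], 0 / 2)
  sy <- fecundity_schedule(exposure_schedule(co), denominator = "female_years")
  expect_equal(sy$fecundity[sy$age == 10], 2 / sum(s$exposure[s$age == 10]),
               tolerance = 1e-9)

  # 3 births among 7 females observed in one class
  co7 <- cohort_from_ages(entry = rep(20, 7), exit = rep(21, 7),
                          died = rep(FALSE, 7),
                          birth_mother = c(1L, 2L, 3L),
                          birth_age = c(20.1, 20.5, 20.9))
  s7 <- fecundity_schedule(exposure_schedule(co7))
  expect_equal(s7$fecundity[s7$age == 20], 3 / 7)

  # no births: m = 0 wherever observed, never NA there
  co0 <- cohort_from_ages(entry = c(10, 12), exit = c(15, 18),
                          died = c(TRUE, TRUE))
  s0 <- fecundity_schedule(exposure_schedule(co0))
  expect_true(all(s0$fecundity[s0$females_observed > 0] == 0))
})

test_that("product-limit survivorship matches hand-enumerated risk sets", {
  # at-risk 10-15 died, 12-20 censored, 14-18 died
  co <- cohort_from_ages(entry = c(10, 12, 14), exit = c(15, 20, 18),
                         died = c(TRUE, FALSE, TRUE))
  cu <- survivorship(co)
  ca <- prrlife:::.cohort_ages(co)
  # risk sets: death at ~15 with n=3, death at ~18 with n=2
  expect_equal(prrlife:::.l_at(cu, ca$exit[1]), 2 / 3, tolerance = 1e-12)
  expect_equal(prrlife:::.l_at(cu, ca$exit[3]), (2 / 3) * (1 / 2),
               tolerance = 1e-12)
  expect_equal(cu$surv[1], 1, tolerance = 1e-12)
  expect_equal(cu$baseline_age, ca$entry[1])
  expect_true(all(diff(cu$surv) <= 0))
})

test_that("with no deaths, survivorship is identically 1", {
  co <- cohort_from_ages(entry = c(10, 12), exit = c(15, 25),
                         died = c(FALSE, FALSE))
  cu <- survivorship(co)
  expect_true(all(cu$surv == 1))
})

test_that("on complete cohorts the product-limit curve equals the empirical survival function", {
  set.seed(17)
  for (rep in 1:20) {
    n <- sample(5:30, 1)
    death <- round(runif(n, 1, 40), 2)
    co <- cohort_from_ages(entry = rep(0, n), exit = death,
                           died = rep(TRUE, n))
    cu <- survivorship(co)
    ca <- prrlife:::.cohort_ages(co)
    for (t in cu$age) {
      emp <- mean(ca$exit > t)
      expect_equal(cu$surv[cu$age == t], emp, tolerance = 1e-12)
    }
  }
})

test_that("breslow and product-limit agree closely and l is nonincreasing", {
  co <- generate_cohort(sim_config(n_females = 60, seed = 9))
  pl <- survivorship(co, "product_limit")
  br <- survivorship(co, "breslow")
  expect_true(all(diff(pl$surv) <= 1e-12))
  expect_true(all(diff(br$surv) <= 1e-12))
  expect_true(all(br$surv >= pl$surv - 1e-12))  # exp(-H) >= product form
  # agreement where risk sets are not tiny (l not yet near 0)
  keep <- pl$surv > 0.2
  expect_lt(max(abs(pl$surv[keep] - br$surv[keep])), 0.05)
})

test_that("person-years integration is exact on analytic curves", {
  flat <- flat_curve(10, 50)
  expect_equal(person_years_after(flat, 10), 40)
  expect_equal(person_years_after(flat, 50), 0)
  expect_equal(person_years_after(flat, 30.5), 19.5)
  expect_error(person_years_after(flat, 55), "outside")

  # piecewise curve vs dense-grid quadrature
  cu <- structure(list(age = c(10, 15, 18, 30, 40),
                       surv = c(1, 0.8, 0.5, 0.2, 0),
                       baseline_age = 10, method = "product_limit"),
                  class = "survivorship_curve")
  dense <- seq(10, 40, by = 1e-4)
  ldense <- approx(cu$age, cu$surv, dense)$y
  for (x in c(10, 12.3, 18, 25, 39.9)) {
    num <- sum(ldense[dense >= x]) * 1e-4
    expect_equal(person_years_after(cu, x), num, tolerance = 1e-3)
  }
  # T is nonincreasing and continuous in x
  xs <- seq(10, 40, by = 0.37)
  Ts <- person_years_after(cu, xs)
  expect_true(all(diff(Ts) <= 1e-12))
})

test_that("renormalizing survivorship rescales T uniformly and leaves PrR unchanged", {
  co <- generate_cohort(sim_config(n_females = 40, seed = 3))
  cu <- survivorship(co)
  s <- fecundity_schedule(exposure_schedule(co))
  base <- compute_prr(cu, s)
  cu2 <- cu; cu2$surv <- cu$surv * 0.37
  expect_equal(person_years_after(cu2, 20) / person_years_after(cu, 20), 0.37,
               tolerance = 1e-12)
  expect_equal(compute_prr(cu2, s)$prr, base$prr, tolerance = 1e-12)
})

test_that("degenerate survivorship inputs are rejected", {
  co <- cohort_from_ages(entry = 10, exit = 10, died = TRUE)
  expect_error(survivorship(co), "zero time")
})
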