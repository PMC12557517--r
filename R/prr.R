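# Post-reproductive representation: PrR = T(M) / T(B), where B and M are the
# ages by which 5% and 95% of population fecundity have accrued, and T(x) is
# the person-years lived after x under the survivorship curve.

.fec_weights <- function(curve, schedule, weighting) {
  def <- !is.na(schedule$fecundity)
  ages <- schedule$age[def]
  m <- schedule$fecundity[def]
  lmid <- .l_at(curve, ages + 0.5)
  w <- if (weighting == "l_times_m") m * lmid else m
  list(ages = ages, m = m, lmid = lmid, w = w)
}

# age at which the normalized cumulative fecundity crosses q; fecundity is
# treated as uniform within each one-year class, so the crossing age is
# linearly interpolated inside the crossing class
.cum_cross <- function(ages, w, q) {
  tot <- sum(w)
  cum <- cumsum(w)
  target <- q * tot
  k <- which(cum >= target - 1e-12)[1]
  prev <- if (k > 1) cum[k - 1] else 0
  ages[k] + (target - prev) / w[k]
}

#' Age at a given quantile of cumulative population fecundity
#'
#' Accumulates the age-class fecundity weights in age order, normalizes, and
#' returns the age at which the running total crosses `q`, interpolating
#' linearly within the crossing class. With `weighting = "l_times_m"` the
#' weights are realized cohort fecundity l(x) * m(x) (l evaluated at the class
#' midpoint); with `"m_only"` the raw birth-rate schedule is used.
#'
#' @param curve a `survivorship_curve`.
#' @param schedule an `age_schedule` with a `fecundity` column.
#' @param q quantile in (0, 1).
#' @param weighting `"l_times_m"` (default) or `"m_only"`.
#' @return age in years.
#' @export
fecundity_quantile_age <- function(curve, schedule, q,
                                   weighting = c("l_times_m", "m_only")) {
  weighting <- match.arg(weighting)
  stopifnot(q > 0, q < 1, inherits(schedule, "age_schedule"))
  if (is.null(schedule$fecundity))
    stop("schedule has no fecundity column; run fecundity_schedule() first",
         call. = FALSE)
  fw <- .fec_weights(curve, schedule, weighting)
  if (!length(fw$w) || sum(fw$w) <= 0)
    stop("all fecundity weights are zero; quantile age undefined",
         call. = FALSE)
  .cum_cross(fw$ages, fw$w, q)
}

#' Post-reproductive representation (PrR)
#'
#' The fraction of adult female person-years in the population lived after
#' reproductive cessation: PrR = T(M) / T(B), where B and M are the ages by
#' which 5% and 95% of population fecundity have occurred and T(x) integrates
#' the survivorship curve beyond x. PrR is 0 when no female-years are lived
#' past M and 1 when reproduction is concentrated at a single age that all
#' females outlive; it is invariant to any uniform rescaling of l (and hence
#' to the choice of baseline age).
#'
#' @inheritParams fecundity_quantile_age
#' @return a `prr_result`: list with `prr`, `age_B`, `age_M`, `T_B`, `T_M`,
#'   `weighting`.
#' @export
compute_prr <- function(curve, schedule,
                        weighting = c("l_times_m", "m_only")) {
  weighting <- match.arg(weighting)
  age_B <- fecundity_quantile_age(curve, schedule, 0.05, weighting)
  age_M <- fecundity_quantile_age(curve, schedule, 0.95, weighting)
  tx <- .t_machine(curve)
  T_B <- tx(age_B)  # quantile ages are clamped to the curve's grid range
  T_M <- tx(age_M)
  if (T_B <= 0)
    stop("no person-years lived after the 5% fecundity age; PrR undefined",
         call. = FALSE)
  structure(list(prr = T_M / T_B, age_B = age_B, age_M = age_M,
                 T_B = T_B, T_M = T_M, weighting = weighting),
            class = "prr_result")
}

#' @export
print.prr_result <- function(x, ...) {
  cat(sprintf("PrR = %.4f  (T(M)/T(B) = %.2f / %.2f; B = %.2f y, M = %.2f y; weighting %s)\n",
              x$prr, x$T_M, x$T_B, x$age_B, x$age_M, x$weighting))
  invisible(x)
}

# Vectorized PrR over B permutations of the m-values (l held fixed).
# Returns the null vector; obs is computed through the identical code path so
# that ties (e.g. constant m) compare exactly.
.perm_null <- function(ages, m, lmid, tx, weighting, B) {
  K <- length(m)
  idx <- vapply(seq_len(B), function(i) sample.int(K), integer(K))
  M <- matrix(m[idx], nrow = K)
  W <- if (weighting == "l_times_m") M * lmid else M
  C <- apply(W, 2, cumsum)
  if (K == 1) C <- matrix(C, nrow = 1)
  tot <- C[K, ]
  aB <- aM <- numeric(B)
  for (b in seq_len(B)) {
    tb <- 0.05 * tot[b]; tm <- 0.95 * tot[b]
    kb <- which(C[, b] >= tb - 1e-12)[1]
    km <- which(C[, b] >= tm - 1e-12)[1]
    aB[b] <- ages[kb] + (tb - if (kb > 1) C[kb - 1, b] else 0) / W[kb, b]
    aM[b] <- ages[km] + (tm - if (km > 1) C[km - 1, b] else 0) / W[km, b]
  }
  TB <- tx(aB); TM <- tx(aM)
  out <- ifelse(TB > 0, TM / TB, 0)  # degenerate: no years past B => no signal
  out
}

#' Permutation significance test for PrR
#'
#' Tests whether the observed PrR exceeds what the age pattern of fecundity
#' alone would produce by chance: each iteration shuffles the m(x) values
#' uniformly at random across the age classes where m is defined, holds the
#' survivorship curve fixed, and recomputes PrR. The p-value uses the add-one
#' estimator (1 + #{null >= observed}) / (1 + n_iterations), so it is never
#' exactly zero.
#'
#' @inheritParams fecundity_quantile_age
#' @param n_iterations number of random shuffles.
#' @param seed optional integer; when given, results are exactly reproducible.
#' @return a `permutation_result`: `observed_prr`, `null_prr`, `n_iterations`,
#'   `p_value`, `seed`.
#' @export
permutation_test <- function(curve, schedule, n_iterations = 10000,
                             seed = NULL,
                             weighting = c("l_times_m", "m_only")) {
  weighting <- match.arg(weighting)
  fw <- .fec_weights(curve, schedule, weighting)
  if (length(fw$ages) < 2)
    stop("fewer than 2 age classes with defined fecundity; nothing to permute",
         call. = FALSE)
  if (sum(fw$w) <= 0) stop("all fecundity weights are zero", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  tx <- .t_machine(curve)
  obs_B <- .cum_cross(fw$ages, fw$w, 0.05)
  obs_M <- .cum_cross(fw$ages, fw$w, 0.95)
  TB <- tx(obs_B)
  obs <- if (TB > 0) tx(obs_M) / TB else 0
  null <- .perm_null(fw$ages, fw$m, fw$lmid, tx, weighting, n_iterations)
  structure(list(observed_prr = obs, null_prr = null,
                 n_iterations = n_iterations,
                 p_value = (1 + sum(null >= obs)) / (1 + n_iterations),
                 seed = seed),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("PrR permutation test: observed %.4f, null mean %.4f, p = %.4g (%d shuffles)\n",
              x$observed_prr, mean(x$null_prr), x$p_value, x$n_iterations))
  invisible(x)
}

#' Propagate age-estimation uncertainty into PrR
#'
#' Female birth dates are estimates; each carries a half-width error in years.
#' Per iteration, every female receives one offset drawn uniformly from
#' [-error, +error], shifting her entry age, exit age and (by default) the
#' ages at which her birth events occurred — all her ages share the single
#' offset because the uncertainty is in her birth date. Fecundity and
#' survivorship schedules are rebuilt from the shifted ages, and PrR plus its
#' permutation p-value are recorded.
#'
#' @param x a [cohort()].
#' @param n_iterations number of error-resampling iterations.
#' @param n_permutations shuffles for the permutation test inside each
#'   iteration (reduce for quick exploratory runs).
#' @param seed optional integer seed governing all draws.
#' @param weighting,denominator,method forwarded to the schedule and
#'   survivorship builders.
#' @param shift `"all"` (default: entry, exit and birth-event ages move
#'   together) or `"entry_exit"` (birth-event ages held fixed).
#' @return an `uncertainty_result`: `prr_values`, `p_values`, `mean_prr`,
#'   `sd_prr`, `point` (the unshifted `prr_result`), `n_iterations`, `seed`.
#' @export
uncertainty_simulation <- function(x, n_iterations = 1000,
                                   n_permutations = 10000, seed = NULL,
                                   weighting = c("l_times_m", "m_only"),
                                   denominator = c("females_observed",
                                                   "female_years"),
                                   method = c("product_limit", "breslow"),
                                   shift = c("all", "entry_exit")) {
  weighting <- match.arg(weighting); denominator <- match.arg(denominator)
  method <- match.arg(method); shift <- match.arg(shift)
  stopifnot(n_iterations >= 1)
  ca <- .cohort_ages(x)
  point_curve <- .surv_from_ages(ca$entry, ca$exit, ca$died, method)
  point_sched <- .add_fecundity(
    .schedule_from_ages(ca$entry, ca$exit, ca$mother_age), denominator)
  point <- compute_prr(point_curve, point_sched, weighting)
  if (!is.null(seed)) set.seed(seed)
  nf <- length(ca$entry)
  prr_values <- p_values <- numeric(n_iterations)
  for (it in seq_len(n_iterations)) {
    e <- runif(nf, -ca$err, ca$err)
    entry2 <- ca$entry + e
    exit2  <- ca$exit + e
    bage2  <- if (shift == "all") ca$mother_age + e[ca$mother_idx]
              else ca$mother_age
    curve <- .surv_from_ages(entry2, exit2, ca$died, method)
    sched <- .add_fecundity(.schedule_from_ages(entry2, exit2, bage2),
                            denominator)
    pt <- permutation_test(curve, sched, n_iterations = n_permutations,
                           weighting = weighting)
    prr_values[it] <- pt$observed_prr
    p_values[it] <- pt$p_value
  }
  structure(list(prr_values = prr_values, p_values = p_values,
                 mean_prr = mean(prr_values),
                 sd_prr = if (n_iterations > 1) sd(prr_values) else 0,
                 point = point, n_iterations = n_iterations, seed = seed),
            class = "uncertainty_result")
}

#' @export
print.uncertainty_result <- function(x, ...) {
  cat(sprintf("age-uncertainty simulation (%d iterations): PrR %.4f +/- %.4f (point %.4f); %d/%d p < 0.05\n",
              x$n_iterations, x$mean_prr, x$sd_prr, x$point$prr,
              sum(x$p_values < 0.05), x$n_iterations))
  invisible(x)
}
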