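# Individual-based life-history simulator. Defaults emulate a wild mountain
# gorilla population: successful interbirth intervals around 5.1 +/- 1.3 y,
# first birth near age 10, reproductive cessation (when enabled) around age
# 35, lifespans capped at 50 y, a roughly three-decade observation window
# with staggered entry (habituation, immigration, birth in study) producing
# left truncation, and exits by death, emigration/disappearance or study end
# producing right censoring. Age-estimation errors of up to several years are
# attached to females whose birth predates observation.

#' Simulator configuration
#'
#' All parameters of the synthetic life-history generator, validated. The
#' defaults are the package's reference study conditions; mortality and
#' dispersal rates are plausibility choices for wild mountain gorillas, not
#' estimates from any dataset.
#'
#' @param n_females cohort size to generate (observed females).
#' @param mortality list: `model` is `"gompertz"` (hazard a*exp(b*age) with
#'   `parameters = list(a, b)`) or `"piecewise_constant"` (`parameters =
#'   list(breaks, rates)`, hazard `rates[i]` on `[breaks[i], breaks[i+1])`).
#' @param age_first_birth list `mean`, `sd`, `min` in years.
#' @param ibi list `mean`, `sd`, `min` in years, plus `model`: `"normal"`
#'   (truncated-normal renewal intervals) or `"exponential"` (memoryless
#'   birth process at rate 1/mean from `age_first_birth$min`, giving an
#'   age-constant birth hazard; infant-death shortening is disabled).
#' @param infant_death list: `prob`, probability an infant dies before the
#'   next conception; `ibi`, the shorter `mean`/`sd`/`min` interval that
#'   follows such a death.
#' @param cessation list: `enabled`; `mean`, `sd` of the age at which
#'   reproduction stops.
#' @param max_age years; lifespans are truncated here.
#' @param observation list: `study_start`, `study_end` (ISO dates),
#'   `habituation_fraction` (females alive at study start entering then),
#'   `immigration_rate` (per-year rate of the exponential entry delay for the
#'   rest), `emigration_hazard` (per-year, produces censoring; half of
#'   emigration exits are recorded as disappearances), `min_entry_age`
#'   (observe females only from this age).
#' @param age_error list `max_years`: errors for habituated/immigrant females
#'   are drawn uniformly on [0, max_years].
#' @param twin_prob probability a parity event is a twin birth.
#' @param seed integer; every draw in [generate_cohort()] flows from it.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(n_females = 25,
                       mortality = list(model = "gompertz",
                                        parameters = list(a = 0.012, b = 0.06)),
                       age_first_birth = list(mean = 10, sd = 1.5, min = 8),
                       ibi = list(mean = 5.1, sd = 1.3, min = 1.5,
                                  model = "normal"),
                       infant_death = list(prob = 0.2,
                                           ibi = list(mean = 2, sd = 0.6,
                                                      min = 0.75)),
                       cessation = list(enabled = TRUE, mean = 32, sd = 2.5),
                       max_age = 50,
                       observation = list(study_start = "1995-01-01",
                                          study_end = "2025-01-01",
                                          habituation_fraction = 0.5,
                                          immigration_rate = 0.2,
                                          emigration_hazard = 0.01,
                                          min_entry_age = 0),
                       age_error = list(max_years = 4),
                       twin_prob = 0.015,
                       seed = 1) {
  cfg <- list(n_females = n_females, mortality = mortality,
              age_first_birth = age_first_birth, ibi = ibi,
              infant_death = infant_death, cessation = cessation,
              max_age = max_age, observation = observation,
              age_error = age_error, twin_prob = twin_prob, seed = seed)
  with(cfg, {
    stopifnot(n_females >= 1, max_age > 0,
              age_first_birth$sd >= 0, age_first_birth$min > 0,
              ibi$sd >= 0, ibi$min >= 0,
              infant_death$prob >= 0, infant_death$prob <= 1,
              cessation$sd >= 0,
              observation$habituation_fraction >= 0,
              observation$habituation_fraction <= 1,
              observation$emigration_hazard >= 0,
              age_error$max_years >= 0)
    if (age_first_birth$mean >= max_age)
      stop("degenerate config: mean age at first birth >= max_age",
           call. = FALSE)
    if (!mortality$model %in% c("gompertz", "piecewise_constant"))
      stop("unknown mortality model '", mortality$model, "'", call. = FALSE)
    if (!ibi$model %in% c("normal", "exponential"))
      stop("unknown ibi model '", ibi$model, "'", call. = FALSE)
  })
  structure(cfg, class = "sim_config")
}

# inverse-CDF draw of a death age, truncated at max_age
.draw_death_age <- function(mortality, max_age) {
  h <- -log(runif(1))
  t <- if (mortality$model == "gompertz") {
    a <- mortality$parameters$a; b <- mortality$parameters$b
    log(1 + b * h / a) / b
  } else {
    br <- mortality$parameters$breaks; rt <- mortality$parameters$rates
    up <- c(br[-1], Inf)
    t <- NA_real_
    for (i in seq_along(rt)) {
      seg <- (up[i] - br[i]) * rt[i]
      if (h <= seg) { t <- br[i] + h / rt[i]; break }
      h <- h - seg
    }
    if (is.na(t)) max_age else t
  }
  min(t, max_age)
}

.tnorm <- function(mean, sd, min) max(min, rnorm(1, mean, sd))

# One complete (unobserved) female life history. Draw order: death age,
# cessation age, age at first birth, then per birth: twin flag, infant fate,
# next gap, infant death age.
.sim_history <- function(cfg) {
  death <- .draw_death_age(cfg$mortality, cfg$max_age)
  cess <- if (isTRUE(cfg$cessation$enabled))
    max(cfg$age_first_birth$min, rnorm(1, cfg$cessation$mean, cfg$cessation$sd))
  else Inf
  expo <- cfg$ibi$model == "exponential"
  t <- if (expo) cfg$age_first_birth$min + rexp(1, 1 / cfg$ibi$mean)
       else .tnorm(cfg$age_first_birth$mean, cfg$age_first_birth$sd,
                   cfg$age_first_birth$min)
  ages <- twin <- inf_died <- inf_death_age <- c()
  while (t < death && t < cess) {
    tw <- runif(1) < cfg$twin_prob
    if (expo) {
      died <- FALSE
      gap <- rexp(1, 1 / cfg$ibi$mean)
      da <- NA_real_
    } else {
      died <- runif(1) < cfg$infant_death$prob
      gap <- if (died)
        .tnorm(cfg$infant_death$ibi$mean, cfg$infant_death$ibi$sd,
               cfg$infant_death$ibi$min)
      else .tnorm(cfg$ibi$mean, cfg$ibi$sd, cfg$ibi$min)
      da <- if (died) runif(1, 0, min(0.5, gap)) else NA_real_
    }
    ages <- c(ages, t); twin <- c(twin, tw)
    inf_died <- c(inf_died, died); inf_death_age <- c(inf_death_age, da)
    t <- t + gap
  }
  list(death_age = death, birth_ages = ages, twin = twin,
       infant_died = inf_died, infant_death_age = inf_death_age)
}

.days <- function(y) round(365.25 * y)

#' Generate a synthetic observed cohort
#'
#' Simulates complete female life histories under the configured mortality,
#' fertility and (optional) reproductive-cessation model, intersects each life
#' with the study observation window to produce staggered entry (left
#' truncation) and exit (right censoring), and returns a [cohort()] that
#' passes all data validation. Rejection sampling keeps only females with a
#' positive observation span. Fully reproducible from `config$seed`.
#'
#' @param config a [sim_config()].
#' @return a validated [cohort()].
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  obs <- config$observation
  start <- as.Date(obs$study_start); end <- as.Date(obs$study_end)
  span <- as.numeric(end - start) / 365.25
  fem <- list(); bir <- list()
  made <- 0L; tries <- 0L
  while (made < config$n_females && tries < 1000L * config$n_females) {
    tries <- tries + 1L
    birth_cal <- start + .days(runif(1, -(config$max_age - 5), span - 1))
    h <- .sim_history(config)
    death_cal <- birth_cal + .days(h$death_age)

    if (birth_cal >= start && obs$min_entry_age == 0) {
      mode <- "born_in_study"; entry_cal <- birth_cal; err <- 0
    } else {
      earliest <- max(start, birth_cal + .days(obs$min_entry_age))
      if (runif(1) < obs$habituation_fraction) {
        mode <- "habituation"; entry_cal <- earliest
      } else {
        mode <- "immigration"
        entry_cal <- earliest + .days(rexp(1, obs$immigration_rate))
      }
      err <- runif(1, 0, config$age_error$max_years)
    }

    exit_cal <- min(death_cal, end)
    fate <- if (death_cal <= end) "died" else "alive"
    if (obs$emigration_hazard > 0) {
      em_cal <- entry_cal + .days(rexp(1, obs$emigration_hazard))
      if (em_cal < exit_cal) {
        exit_cal <- em_cal
        fate <- if (runif(1) < 0.5) "emigrated" else "disappeared"
      }
    }
    if (entry_cal >= exit_cal || entry_cal >= end) next

    made <- made + 1L
    id <- sprintf("F%03d", made)
    fem[[made]] <- data.frame(
      female_id = id, birth_date = birth_cal, age_error_years = err,
      entry_date = entry_cal, exit_date = exit_cal,
      exit_fate = fate, entry_mode = mode)

    for (j in seq_along(h$birth_ages)) {
      bcal <- birth_cal + .days(h$birth_ages[j])
      if (bcal < entry_cal || bcal > exit_cal) next
      died <- isTRUE(h$infant_died[j])
      bir[[length(bir) + 1]] <- data.frame(
        mother_id = id,
        offspring_id = sprintf("%s-O%d", id, j),
        birth_date = bcal,
        offspring_exit_date = if (died)
          bcal + .days(h$infant_death_age[j]) else as.Date(NA),
        offspring_exit_fate = if (died) "died" else "alive",
        is_twin_event = isTRUE(h$twin[j]))
    }
  }
  if (made < config$n_females)
    stop("could not generate the requested cohort; observation window and ",
         "life-history parameters are incompatible", call. = FALSE)
  births <- if (length(bir)) do.call(rbind, bir) else NULL
  cohort(do.call(rbind, fem), births,
         min_maturation_age = min(5, config$age_first_birth$min))
}

#' Ground-truth PrR of a simulator configuration
#'
#' Monte-Carlo reference value for parameter-recovery checks: simulates a very
#' large cohort of complete life histories (no truncation, no censoring —
#' every female observed from birth to death), builds the fecundity schedule
#' and the empirical survivorship from those complete lives, and computes PrR
#' exactly as the estimation pipeline would. This is the target the pipeline
#' should recover from truncated, censored observational data generated under
#' the same configuration.
#'
#' @param config a [sim_config()].
#' @param n_cohort number of complete lives to simulate.
#' @param weighting,denominator as in [compute_prr()] and
#'   [fecundity_schedule()]; match the options used by the estimate under
#'   comparison.
#' @param seed integer; defaults to the config's seed.
#' @return PrR as a single number.
#' @export
true_prr <- function(config, n_cohort = 20000,
                     weighting = c("l_times_m", "m_only"),
                     denominator = c("females_observed", "female_years"),
                     seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  weighting <- match.arg(weighting); denominator <- match.arg(denominator)
  set.seed(seed)
  deaths <- numeric(n_cohort)
  bages <- vector("list", n_cohort)
  for (i in seq_len(n_cohort)) {
    h <- .sim_history(config)
    deaths[i] <- h$death_age
    bages[[i]] <- h$birth_ages
  }
  entry <- rep(0, n_cohort)
  curve <- .surv_from_ages(entry, deaths, rep(TRUE, n_cohort), "product_limit")
  sched <- .add_fecundity(.schedule_from_ages(entry, deaths, unlist(bages)),
                          denominator)
  compute_prr(curve, sched, weighting)$prr
}
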