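# Builders for small hand-specified cohorts and reusable study configs.

iso <- function(x) as.Date(x)

# females table from parallel vectors; dates as strings
females_tbl <- function(id, birth, entry, exit,
                        fate = "died", mode = "habituation", err = 0) {
  data.frame(female_id = id, birth_date = birth,
             age_error_years = err, entry_date = entry, exit_date = exit,
             exit_fate = fate, entry_mode = mode)
}

births_tbl <- function(mother, offspring, birth, off_exit = NA,
                       off_fate = "alive", twin = FALSE) {
  data.frame(mother_id = mother, offspring_id = offspring, birth_date = birth,
             offspring_exit_date = off_exit, offspring_exit_fate = off_fate,
             is_twin_event = twin)
}

# cohort specified directly by at-risk ages (years); dates are anchored at a
# common origin so ages are exact up to day rounding (<= 1/365.25 y)
cohort_from_ages <- function(entry, exit, died,
                             birth_mother = integer(), birth_age = numeric()) {
  origin <- as.Date("1950-01-01")
  n <- length(entry)
  id <- sprintf("F%02d", seq_len(n))
  f <- females_tbl(id,
                   birth = rep(origin, n),
                   entry = origin + round(365.25 * entry),
                   exit  = origin + round(365.25 * exit),
                   fate  = ifelse(died, "died", "alive"),
                   mode  = ifelse(entry == 0, "born_in_study", "habituation"))
  b <- NULL
  if (length(birth_mother)) {
    b <- births_tbl(id[birth_mother],
                    sprintf("%s-O%d", id[birth_mother], seq_along(birth_mother)),
                    birth = origin + round(365.25 * birth_age))
  }
  cohort(f, b)
}

# schedule with prescribed per-class fecundity on a flat survivorship curve
flat_curve <- function(from = 10, to = 50, l_end = 1) {
  structure(list(age = c(from, to), surv = c(1, l_end),
                 baseline_age = from, method = "product_limit"),
            class = c("survivorship_curve"))
}

manual_schedule <- function(ages, m) {
  s <- data.frame(age = ages, exposure = rep(1, length(ages)),
                  females_observed = rep(1L, length(ages)),
                  births = rep(0L, length(ages)))
  class(s) <- c("age_schedule", "data.frame")
  s$fecundity <- m
  attr(s, "denominator") <- "females_observed"
  s
}

# all permutations of 1..n (n small), for exhaustive enumeration oracles
all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- seq_len(n)[-k]
    cbind(k, matrix(rest[sub], nrow(sub)))
  }))
}

# reference config for a fully observed cohort: study window spans all lives,
# everyone born in study, no emigration, no age error
full_observation_config <- function(n_females = 200, seed = 1, ...) {
  sim_config(n_females = n_females,
             observation = list(study_start = "1800-01-01",
                                study_end = "2100-01-01",
                                habituation_fraction = 1,
                                immigration_rate = 0.2,
                                emigration_hazard = 0,
                                min_entry_age = 0),
             age_error = list(max_years = 0),
             seed = seed, ...)
}

# mortality and cessation switched off until senescence, so that completed
# interbirth intervals are not selected through mother survival (a long gap
# only completes if the mother lives through it)
selection_free_config <- function(n_females = 400, seed = 1) {
  full_observation_config(
    n_females = n_females, seed = seed,
    mortality = list(model = "piecewise_constant",
                     parameters = list(breaks = c(0, 45), rates = c(1e-4, 1))),
    cessation = list(enabled = FALSE, mean = 32, sd = 2.5))
}

# constant-birth-hazard null: memoryless births from a shared maturity age,
# no cessation, observation from maturity
null_hazard_config <- function(n_females = 150, seed = 1) {
  sim_config(n_females = n_females,
             ibi = list(mean = 5.1, sd = 1.3, min = 0, model = "exponential"),
             age_first_birth = list(mean = 10, sd = 0, min = 10),
             cessation = list(enabled = FALSE, mean = 32, sd = 2.5),
             observation = list(study_start = "1800-01-01",
                                study_end = "2100-01-01",
                                habituation_fraction = 1,
                                immigration_rate = 0.2,
                                emigration_hazard = 0,
                                min_entry_age = 10),
             age_error = list(max_years = 0),
             seed = seed)
}
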