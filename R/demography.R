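# Age classes are 1-year and left-closed, [x, x+1). Exposure is the exact
# overlap of each female's at-risk interval with the class; headcount is the
# number of females with positive overlap.
.schedule_from_ages <- function(entry, exit, birth_ages) {
  if (!length(entry)) {
    out <- data.frame(age = integer(), exposure = numeric(),
                      females_observed = integer(), births = integer())
    class(out) <- c("age_schedule", "data.frame")
    return(out)
  }
  lo <- floor(min(entry))
  hi <- ceiling(max(exit)) - 1
  ages <- lo:hi
  ov <- vapply(ages, function(a) pmax(0, pmin(exit, a + 1) - pmax(entry, a)),
               numeric(length(entry)))
  ov <- matrix(ov, nrow = length(entry))
  cls <- factor(floor(birth_ages), levels = ages)
  out <- data.frame(age = ages,
                    exposure = colSums(ov),
                    females_observed = colSums(ov > 0),
                    births = as.integer(table(cls)))
  class(out) <- c("age_schedule", "data.frame")
  out
}

#' Age-specific exposure schedule
#'
#' Tallies, per one-year age class `[x, x+1)`, the female-years of observation
#' (summed overlap of each female's entry-to-exit interval with the class),
#' the number of females observed at all in the class, and the number of
#' parity events whose mother age falls in the class. Twins count as one
#' event.
#'
#' @param x a [cohort()].
#' @return an `age_schedule` data.frame with columns `age`, `exposure`,
#'   `females_observed`, `births`.
#' @export
exposure_schedule <- function(x) {
  ca <- .cohort_ages(x)
  .schedule_from_ages(ca$entry, ca$exit, ca$mother_age)
}

.add_fecundity <- function(schedule, denominator) {
  den <- switch(denominator,
                females_observed = schedule$females_observed,
                female_years     = schedule$exposure)
  m <- ifelse(den > 0, schedule$births / den, NA_real_)
  schedule$fecundity <- m
  attr(schedule, "denominator") <- denominator
  schedule
}

#' Age-specific fecundity m(x)
#'
#' Births per age class divided by the females observed in that class. The
#' default denominator is the headcount of females observed at that age; the
#' `female_years` option divides by exact person-years of exposure instead,
#' which is unbiased when observation windows cut across class boundaries.
#' Classes with a zero denominator have `NA` fecundity (undefined, not zero).
#'
#' @param schedule an `age_schedule` from [exposure_schedule()].
#' @param denominator `"females_observed"` (headcount) or `"female_years"`.
#' @return the schedule with a `fecundity` column added.
#' @export
fecundity_schedule <- function(schedule,
                               denominator = c("females_observed",
                                               "female_years")) {
  stopifnot(inherits(schedule, "age_schedule"))
  .add_fecundity(schedule, match.arg(denominator))
}

.surv_from_ages <- function(entry, exit, died,
                            method = c("product_limit", "breslow")) {
  method <- match.arg(method)
  if (!length(entry)) stop("empty cohort: no survivorship estimable",
                           call. = FALSE)
  keep <- exit > entry
  if (!any(keep))
    stop("all individuals at risk for zero time", call. = FALSE)
  if (any(!keep)) {
    warning(sum(!keep), " individual(s) with zero-length at-risk interval ",
            "dropped from survivorship")
    entry <- entry[keep]; exit <- exit[keep]; died <- died[keep]
  }
  # Counting-process estimator: at-risk on (entry, exit]; ties between deaths
  # and censorings at the same age keep the censored female in the risk set.
  if (method == "product_limit") {
    fit <- survival::survfit(survival::Surv(entry, exit, died) ~ 1,
                             stype = 1, ctype = 1)
  } else {
    fit <- survival::survfit(survival::Surv(entry, exit, died) ~ 1,
                             stype = 2, ctype = 1)
  }
  baseline <- min(entry)
  grid <- sort(unique(c(baseline, fit$time, max(exit))))
  sf <- stats::stepfun(fit$time, c(1, fit$surv), right = FALSE)
  structure(list(age = grid,
                 surv = pmin(1, pmax(0, sf(grid))),
                 baseline_age = baseline,
                 method = method),
            class = "survivorship_curve")
}

#' Nonparametric survivorship under delayed entry
#'
#' Estimates the survivorship curve l(x) on the age axis from staggered-entry
#' observational data: each female is at risk from her study-entry age to her
#' exit age, a death event occurs at the exit age only when the exit fate is
#' `died`, and all other fates (alive at study end, disappeared, emigrated)
#' are right-censoring. `product_limit` is the Kaplan-Meier form
#' l(x) = prod over death ages <= x of (1 - d/n); `breslow` is
#' exp(-cumulative Nelson-Aalen hazard), identical to the baseline survival of
#' a covariate-free Cox fit with Breslow ties.
#'
#' The curve is anchored at l = 1 at the youngest entry age: survival below
#' the earliest entry is unidentifiable under left truncation. All T-ratios
#' (and so PrR) are invariant to this anchoring.
#'
#' @param x a [cohort()].
#' @param method `"product_limit"` (default) or `"breslow"`.
#' @return a `survivorship_curve`: list with `age` (grid containing all event
#'   and censoring ages), `surv`, `baseline_age`, `method`.
#' @export
survivorship <- function(x, method = c("product_limit", "breslow")) {
  ca <- .cohort_ages(x)
  .surv_from_ages(ca$entry, ca$exit, ca$died, match.arg(method))
}

#' @export
print.survivorship_curve <- function(x, ...) {
  cat(sprintf("survivorship_curve (%s): %d grid ages on [%.2f, %.2f], final l = %.4f\n",
              x$method, length(x$age), x$age[1], x$age[length(x$age)],
              x$surv[length(x$surv)]))
  invisible(x)
}

# piecewise-linear interpolation of l, clamped to the grid range
.l_at <- function(curve, x) {
  g <- curve$age; l <- curve$surv
  if (length(g) == 1) return(rep(l, length(x)))
  stats::approx(g, l, xout = pmin(pmax(x, g[1]), g[length(g)]),
                ties = "ordered")$y
}

# Precompute the tail integrals of the piecewise-linear l so that
# T(x) = integral_x^omega l can be evaluated in O(log n) per call.
.t_machine <- function(curve) {
  g <- curve$age; l <- curve$surv; K <- length(g)
  if (K == 1) return(function(x) rep(0, length(x)))
  seg <- diff(g) * (l[-K] + l[-1]) / 2
  tail_int <- rev(cumsum(rev(c(seg, 0))))   # tail_int[i] = int from g[i] to g[K]
  function(x) {
    x <- pmin(pmax(x, g[1]), g[K])
    i <- findInterval(x, g, rightmost.closed = TRUE)
    w <- g[i + 1] - g[i]
    lx <- ifelse(w > 0, l[i] + (l[i + 1] - l[i]) * (x - g[i]) / w, l[i])
    (lx + l[i + 1]) / 2 * (g[i + 1] - x) + tail_int[i + 1]
  }
}

#' Person-years lived after age x
#'
#' T(x), the expected years lived beyond age `x` per female alive at the
#' curve's baseline age, obtained by trapezoidal integration of the
#' survivorship curve over its grid from `x` to the oldest grid age, with
#' linear interpolation of l at `x`.
#'
#' @param curve a `survivorship_curve`.
#' @param x age(s) in years, within the curve's grid range.
#' @return numeric vector of person-years.
#' @export
person_years_after <- function(curve, x) {
  stopifnot(inherits(curve, "survivorship_curve"))
  g <- curve$age
  if (any(x < g[1] - 1e-9 | x > g[length(g)] + 1e-9))
    stop(sprintf("age outside the curve's grid [%g, %g]", g[1], g[length(g)]),
         call. = FALSE)
  .t_machine(curve)(x)
}
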