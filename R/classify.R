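# Individual-level criterion: a female is post-reproductive when her years
# since last birth exceed the mean + 2 SD of successful interbirth intervals.

#' Successful interbirth intervals
#'
#' For every mother with at least two recorded parity events, the intervals
#' between consecutive events (in continuous years). An interval is
#' "successful" only if the earlier infant survived: short intervals caused by
#' an infant dying soon after birth, with the mother conceiving again quickly,
#' would otherwise drag the interval distribution down. Under the default rule
#' the earlier infant must have survived until the subsequent birth; under
#' `fixed_years` it must have survived at least `fixed_years`.
#'
#' @param x a [cohort()].
#' @param success_rule `"next_birth"` (default) or `"fixed_years"`.
#' @param fixed_years survival cutoff in years for the `fixed_years` rule.
#' @return an `ibi_stats`: list with `intervals`, `mean`, `sd`, `n`, and an
#'   `excluded` data.frame auditing every interval removed by the filter.
#' @export
successful_ibis <- function(x, success_rule = c("next_birth", "fixed_years"),
                            fixed_years = 1) {
  success_rule <- match.arg(success_rule)
  b <- x$births
  if (!nrow(b)) stop("cohort has no birth events", call. = FALSE)
  intervals <- numeric(0)
  excl <- list()
  for (id in unique(b$mother_id)) {
    bb <- b[b$mother_id == id, , drop = FALSE]
    bb <- bb[order(bb$birth_date), , drop = FALSE]
    if (nrow(bb) < 2) next
    for (i in seq_len(nrow(bb) - 1)) {
      gap <- as.numeric(bb$birth_date[i + 1] - bb$birth_date[i]) / 365.25
      died <- bb$offspring_exit_fate[i] == "died" &&
        !is.na(bb$offspring_exit_date[i])
      ok <- if (success_rule == "next_birth") {
        !(died && bb$offspring_exit_date[i] < bb$birth_date[i + 1])
      } else {
        surv <- if (died)
          as.numeric(bb$offspring_exit_date[i] - bb$birth_date[i]) / 365.25
        else Inf
        surv >= fixed_years
      }
      if (ok) intervals <- c(intervals, gap)
      else excl[[length(excl) + 1]] <-
          data.frame(mother_id = id, offspring_id = bb$offspring_id[i],
                     interval_years = gap)
    }
  }
  if (!length(intervals))
    stop("no successful interbirth intervals in cohort", call. = FALSE)
  structure(list(intervals = intervals,
                 mean = mean(intervals),
                 sd = if (length(intervals) > 1) sd(intervals) else NA_real_,
                 n = length(intervals),
                 excluded = if (length(excl)) do.call(rbind, excl)
                            else data.frame(mother_id = character(),
                                            offspring_id = character(),
                                            interval_years = numeric())),
            class = "ibi_stats")
}

#' @export
print.ibi_stats <- function(x, ...) {
  cat(sprintf("successful IBIs: n = %d, mean = %.2f y, SD = %.2f y (%d excluded after infant death)\n",
              x$n, x$mean, x$sd, nrow(x$excluded)))
  invisible(x)
}

#' Post-reproductive lifespan threshold (mean + 2 SD of successful IBIs)
#'
#' @param x an `ibi_stats` object or a numeric vector of intervals in years;
#'   ignored when `mean` and `sd` are supplied directly.
#' @param mean,sd optionally give the interval mean and sample SD in years.
#' @return threshold in years: mean + 2 * SD (sample SD, n - 1 denominator).
#' @examples
#' prl_threshold(mean = 5.1, sd = 1.3)  # 7.7
#' prl_threshold(c(4, 5, 6))            # 7
#' @export
prl_threshold <- function(x = NULL, mean = NULL, sd = NULL) {
  if (!is.null(mean) && !is.null(sd)) {
    stopifnot(sd >= 0)
    return(mean + 2 * sd)
  }
  if (inherits(x, "ibi_stats")) {
    if (x$n < 2) stop("need at least 2 intervals for an SD", call. = FALSE)
    return(x$mean + 2 * x$sd)
  }
  x <- as.numeric(x)
  if (length(x) < 2) stop("need at least 2 intervals for an SD", call. = FALSE)
  base::mean(x) + 2 * stats::sd(x)
}

#' Classify females as post-reproductive
#'
#' One row per female with at least one recorded birth: her age at last
#' parity, her age at study exit (death, disappearance, emigration or study
#' end alike), the years between the two, and whether that span strictly
#' exceeds the threshold. Females with no recorded births are skipped with a
#' message, since "years since last reproduction" is undefined for them.
#'
#' @param x a [cohort()].
#' @param threshold years; typically [prl_threshold()] of the cohort's
#'   successful IBIs.
#' @return a data.frame (`female_id`, `age_last_birth`, `age_exit`,
#'   `years_since_last_birth`, `is_postreproductive`, `age_error`), with the
#'   threshold attached as an attribute.
#' @export
classify_females <- function(x, threshold) {
  stopifnot(threshold > 0)
  f <- x$females
  ca <- .cohort_ages(x)
  rows <- list()
  skipped <- 0
  for (i in seq_len(nrow(f))) {
    ev <- which(ca$mother_idx == i)
    if (!length(ev)) { skipped <- skipped + 1; next }
    alb <- max(ca$mother_age[ev])
    ysb <- ca$exit[i] - alb
    rows[[length(rows) + 1]] <- data.frame(
      female_id = f$female_id[i],
      age_last_birth = alb,
      age_exit = ca$exit[i],
      years_since_last_birth = ysb,
      is_postreproductive = ysb > threshold,
      age_error = f$age_error_years[i])
  }
  if (skipped)
    message(skipped, " female(s) without recorded births excluded from classification")
  if (!length(rows)) stop("no females with recorded births", call. = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "threshold") <- threshold
  out
}
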