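#' @importFrom stats rnorm runif rexp sd approx quantile setNames
#' @importFrom utils head tail write.table read.csv
NULL

# controlled vocabularies for the two tables
.exit_fates  <- c("alive", "died", "disappeared", "emigrated")
.entry_modes <- c("habituation", "immigration", "born_in_study")

.females_cols <- c("female_id", "birth_date", "age_error_years",
                   "entry_date", "exit_date", "exit_fate", "entry_mode")
.births_cols  <- c("mother_id", "offspring_id", "birth_date",
                   "offspring_exit_date", "offspring_exit_fate", "is_twin_event")

#' Assemble and validate a longitudinal cohort
#'
#' A cohort couples a table of individually identified females (with their
#' estimated birth dates, the half-width of that estimate's uncertainty in
#' years, and the observation window delimited by study entry and exit) with a
#' table of birth events (one row per parity event; twins are a single event).
#' All downstream demographic schedules are computed from this object.
#'
#' @param females data.frame with columns `female_id`, `birth_date`,
#'   `age_error_years`, `entry_date`, `exit_date`, `exit_fate` (one of
#'   `alive`, `died`, `disappeared`, `emigrated`) and `entry_mode` (one of
#'   `habituation`, `immigration`, `born_in_study`). Dates may be `Date` or
#'   ISO-8601 strings.
#' @param births data.frame with columns `mother_id`, `offspring_id`,
#'   `birth_date`, `offspring_exit_date` (may be `NA`: offspring alive at the
#'   end of observation), `offspring_exit_fate` and `is_twin_event`. May have
#'   zero rows.
#' @param min_maturation_age years; birth events implying a mother younger
#'   than this are rejected as data errors.
#' @return An object of class `cohort`: a list with validated, type-stable
#'   `females` and `births` data.frames.
#' @examples
#' f <- data.frame(female_id = "F1", birth_date = "2000-01-01",
#'                 age_error_years = 2, entry_date = "2010-06-01",
#'                 exit_date = "2024-01-01", exit_fate = "alive",
#'                 entry_mode = "habituation")
#' b <- data.frame(mother_id = "F1", offspring_id = "F1-O1",
#'                 birth_date = "2012-03-15", offspring_exit_date = NA,
#'                 offspring_exit_fate = "alive", is_twin_event = FALSE)
#' cohort(f, b)
#' @export
cohort <- function(females, births = NULL, min_maturation_age = 5) {
  if (is.null(births)) {
    births <- data.frame(mother_id = character(), offspring_id = character(),
                         birth_date = as.Date(character()),
                         offspring_exit_date = as.Date(character()),
                         offspring_exit_fate = character(),
                         is_twin_event = logical())
  }
  females <- .coerce_females(females)
  births  <- .coerce_births(births)
  obj <- structure(list(females = females, births = births), class = "cohort")
  validate_cohort(obj, min_maturation_age = min_maturation_age)
  obj
}

.parse_date <- function(x, what, ids, allow_na = FALSE) {
  if (inherits(x, "Date")) return(x)
  x <- as.character(x)
  out <- as.Date(rep(NA_real_, length(x)), origin = "1970-01-01")
  blank <- is.na(x) | !nzchar(trimws(x))
  if (any(!blank)) {
    parsed <- as.Date(x[!blank], format = "%Y-%m-%d")
    if (anyNA(parsed)) {
      bad <- which(!blank)[which(is.na(parsed))[1]]
      stop(sprintf("unparseable %s '%s' (row %s, id '%s'); expected YYYY-MM-DD",
                   what, x[bad], bad, ids[bad]), call. = FALSE)
    }
    out[!blank] <- parsed
  }
  if (!allow_na && any(blank)) {
    bad <- which(blank)[1]
    stop(sprintf("missing %s (row %s, id '%s')", what, bad, ids[bad]),
         call. = FALSE)
  }
  out
}

.require_cols <- function(df, cols, table) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop(sprintf("%s table is missing column(s): %s", table,
                 paste(miss, collapse = ", ")), call. = FALSE)
}

.coerce_females <- function(f) {
  .require_cols(f, .females_cols, "females")
  f <- f[.females_cols]
  ids <- as.character(f$female_id)
  data.frame(
    female_id       = ids,
    birth_date      = .parse_date(f$birth_date, "birth_date", ids),
    age_error_years = as.numeric(f$age_error_years),
    entry_date      = .parse_date(f$entry_date, "entry_date", ids),
    exit_date       = .parse_date(f$exit_date, "exit_date", ids),
    exit_fate       = as.character(f$exit_fate),
    entry_mode      = as.character(f$entry_mode),
    stringsAsFactors = FALSE)
}

.coerce_births <- function(b) {
  .require_cols(b, .births_cols, "births")
  b <- b[.births_cols]
  ids <- as.character(b$mother_id)
  tw <- b$is_twin_event
  if (!is.logical(tw)) tw <- as.logical(tolower(trimws(as.character(tw))))
  data.frame(
    mother_id           = ids,
    offspring_id        = as.character(b$offspring_id),
    birth_date          = .parse_date(b$birth_date, "birth_date", ids),
    offspring_exit_date = .parse_date(b$offspring_exit_date,
                                      "offspring_exit_date", ids,
                                      allow_na = TRUE),
    offspring_exit_fate = as.character(b$offspring_exit_fate),
    is_twin_event       = tw,
    stringsAsFactors = FALSE)
}

#' Validate cohort invariants
#'
#' Checks identifier uniqueness, date ordering (`birth_date <= entry_date <=
#' exit_date`), non-negative age errors, controlled vocabulary for exit fates
#' and entry modes, the born-in-study contract (exact birth date, entry at
#' birth), and that every birth event resolves to exactly one known mother and
#' falls inside her biologically possible reproductive window.
#'
#' @param x a `cohort`.
#' @param min_maturation_age years, minimum mother age at a birth event.
#' @return `x`, invisibly; errors identify the offending row.
#' @export
validate_cohort <- function(x, min_maturation_age = 5) {
  f <- x$females; b <- x$births
  fail <- function(i, id, msg)
    stop(sprintf("females row %s (id '%s'): %s", i, id, msg), call. = FALSE)

  dup <- duplicated(f$female_id)
  if (any(dup)) fail(which(dup)[1], f$female_id[which(dup)[1]],
                     "duplicate female_id")
  for (i in seq_len(nrow(f))) {
    if (is.na(f$age_error_years[i]) || f$age_error_years[i] < 0)
      fail(i, f$female_id[i], "age_error_years must be a number >= 0")
    if (f$birth_date[i] > f$entry_date[i])
      fail(i, f$female_id[i], "entry_date precedes birth_date")
    if (f$entry_date[i] > f$exit_date[i])
      fail(i, f$female_id[i], "exit_date precedes entry_date")
    if (!f$exit_fate[i] %in% .exit_fates)
      fail(i, f$female_id[i], sprintf("unknown exit_fate '%s'", f$exit_fate[i]))
    if (!f$entry_mode[i] %in% .entry_modes)
      fail(i, f$female_id[i], sprintf("unknown entry_mode '%s'", f$entry_mode[i]))
    if (f$entry_mode[i] == "born_in_study" &&
        (f$age_error_years[i] != 0 || f$entry_date[i] != f$birth_date[i]))
      fail(i, f$female_id[i],
           "born_in_study implies age_error_years = 0 and entry_date = birth_date")
  }

  bfail <- function(i, msg)
    stop(sprintf("births row %s (mother '%s', offspring '%s'): %s",
                 i, b$mother_id[i], b$offspring_id[i], msg), call. = FALSE)
  m <- match(b$mother_id, f$female_id)
  for (i in seq_len(nrow(b))) {
    if (is.na(m[i])) bfail(i, "mother_id matches no female (orphan birth event)")
    if (is.na(b$is_twin_event[i])) bfail(i, "is_twin_event must be true/false")
    if (!b$offspring_exit_fate[i] %in% .exit_fates)
      bfail(i, sprintf("unknown offspring_exit_fate '%s'",
                       b$offspring_exit_fate[i]))
    lo <- f$birth_date[m[i]] + round(365.25 * min_maturation_age)
    if (b$birth_date[i] < lo)
      bfail(i, sprintf("birth implies mother younger than %s y",
                       min_maturation_age))
    if (b$birth_date[i] > f$exit_date[m[i]])
      bfail(i, "birth after mother's exit_date")
  }
  invisible(x)
}

#' @export
print.cohort <- function(x, ...) {
  f <- x$females
  cat(sprintf("cohort: %d females, %d birth events\n", nrow(f), nrow(x$births)))
  if (nrow(f)) {
    cat(sprintf("  observation: %s to %s\n", min(f$entry_date), max(f$exit_date)))
    cat("  exit fates:", paste(sprintf("%s=%d", names(table(f$exit_fate)),
                                       table(f$exit_fate)), collapse = " "), "\n")
  }
  invisible(x)
}

#' Read a cohort from the two CSV tables
#'
#' @param females_path,births_path paths to the `females.csv` and `births.csv`
#'   tables (UTF-8, header row, columns as documented in [cohort()]). An empty
#'   `offspring_exit_date` field means the offspring was alive at last
#'   observation.
#' @param min_maturation_age passed to [validate_cohort()].
#' @return a validated [cohort()].
#' @export
read_cohort <- function(females_path, births_path, min_maturation_age = 5) {
  for (p in c(females_path, births_path))
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  f <- read.csv(females_path, colClasses = "character")
  b <- read.csv(births_path, colClasses = "character")
  cohort(f, b, min_maturation_age = min_maturation_age)
}

#' Write a cohort to the two CSV tables
#'
#' Output is byte-stable (fixed column order, ISO dates, lower-case logicals,
#' empty field for open-ended offspring observation) and round-trips through
#' [read_cohort()] field for field.
#'
#' @param x a `cohort`.
#' @param females_path,births_path output paths.
#' @export
write_cohort <- function(x, females_path, births_path) {
  f <- x$females
  f$birth_date <- format(f$birth_date, "%Y-%m-%d")
  f$entry_date <- format(f$entry_date, "%Y-%m-%d")
  f$exit_date  <- format(f$exit_date, "%Y-%m-%d")
  f$age_error_years <- format(f$age_error_years, trim = TRUE, digits = 15)
  b <- x$births
  b$birth_date <- format(b$birth_date, "%Y-%m-%d")
  b$offspring_exit_date <- ifelse(is.na(b$offspring_exit_date), "",
                                  format(b$offspring_exit_date, "%Y-%m-%d"))
  b$is_twin_event <- ifelse(b$is_twin_event, "true", "false")
  write.table(f, females_path, sep = ",", row.names = FALSE, quote = FALSE,
              na = "", eol = "\n")
  write.table(b, births_path, sep = ",", row.names = FALSE, quote = FALSE,
              na = "", eol = "\n")
  invisible(x)
}

#' Age of a female at a calendar date
#'
#' Continuous age in decimal years using a fixed 365.25-day year, so that age
#' arithmetic is free of leap-year ambiguity.
#'
#' @param female one row of a cohort's `females` table (anything with a
#'   `birth_date` field), or a `Date` taken as the birth date itself.
#' @param date calendar date(s), `Date` or ISO string; must not precede the
#'   birth date.
#' @return numeric vector of ages in years.
#' @examples
#' age_at(as.Date("2000-01-01"), "2002-01-01")
#' @export
age_at <- function(female, date) {
  birth <- if (inherits(female, "Date")) female else as.Date(female$birth_date)
  date <- as.Date(date)
  a <- as.numeric(date - birth) / 365.25
  if (any(a < 0)) stop("date precedes birth_date", call. = FALSE)
  a
}

# Age-level view of a cohort: everything downstream works on ages, not dates.
.cohort_ages <- function(x) {
  f <- x$females
  b <- x$births
  midx <- match(b$mother_id, f$female_id)
  list(female_id  = f$female_id,
       entry      = as.numeric(f$entry_date - f$birth_date) / 365.25,
       exit       = as.numeric(f$exit_date - f$birth_date) / 365.25,
       died       = f$exit_fate == "died",
       err        = f$age_error_years,
       mother_idx = midx,
       mother_age = as.numeric(b$birth_date - f$birth_date[midx]) / 365.25)
}
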