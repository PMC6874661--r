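# Annual-cycle calendar and life-cycle age classes: the scaffolding that maps
# every tracked day of an individual onto an (age-class, stage) combination.

STAGES <- c("breeding", "southward_migration", "wintering", "northward_migration")

#' Life-cycle age-class scheme
#'
#' Defines the partition of integer ages into life-cycle classes. The default
#' scheme follows the standard raptor life cycle: juveniles (age 1), young
#' adults establishing territories (2-6), prime-age breeders (7-11) and
#' senescent individuals (12-28).
#'
#' @param classes A data frame with columns `class_label`, `min_age`,
#'   `max_age`. Classes must be contiguous, non-overlapping and cover ages
#'   1 to the maximum age.
#' @return A tibble of class specification, ordered by `min_age`.
#' @export
#' @examples
#' age_class_scheme()
age_class_scheme <- function(classes = NULL) {
  if (is.null(classes)) {
    classes <- tibble::tibble(
      class_label = c("juvenile", "young_adult", "prime", "senescent"),
      min_age     = c(1L, 2L, 7L, 12L),
      max_age     = c(1L, 6L, 11L, 28L)
    )
  }
  classes <- tibble::as_tibble(classes)
  stopifnot(all(c("class_label", "min_age", "max_age") %in% names(classes)))
  classes <- dplyr::arrange(classes, .data$min_age)
  if (classes$min_age[1] != 1L) {
    stop("age-class scheme must start at age 1", call. = FALSE)
  }
  if (any(classes$min_age[-1] != classes$max_age[-nrow(classes)] + 1L)) {
    stop("age classes must be contiguous and non-overlapping", call. = FALSE)
  }
  if (any(classes$max_age < classes$min_age)) {
    stop("age classes must have max_age >= min_age", call. = FALSE)
  }
  classes
}

#' Assign an age to its life-cycle class
#'
#' @param age Integer vector of ages in years.
#' @param scheme An [age_class_scheme()].
#' @return Character vector of class labels.
#' @export
#' @examples
#' assign_age_class(c(1, 6, 7, 28))
assign_age_class <- function(age, scheme = age_class_scheme()) {
  if (any(age < scheme$min_age[1] | age > max(scheme$max_age))) {
    stop("age outside the range covered by the age-class scheme", call. = FALSE)
  }
  idx <- findInterval(age, scheme$min_age)
  scheme$class_label[idx]
}

#' Annual-cycle stage calendar
#'
#' Per age class, an ordered set of annual-cycle stages (breeding, southward
#' migration, wintering, northward migration) given as a start day-of-year
#' and a duration in days; the stages of each class must tile the full
#' 365-day year. Day-of-year is counted in a 365-day year; in leap years the
#' 29th of February inherits the stage of the 28th.
#'
#' The default calendar places breeding on 1 March - 31 August (184 d), the
#' southward migration in September (20 d for adults), wintering through
#' mid-February (146 d) and the northward migration on 14-28 February
#' (15 d). Juveniles, which remain in Africa and do not undertake the
#' northward migration, get a longer southward migration (25 d) and an
#' extended wintering stage (156 d) in its place.
#'
#' @param stages Data frame with columns `age_class`, `stage`, `start_doy`,
#'   `duration_days`, or `NULL` for the default.
#' @param fledge_doy Day-of-year on which every individual's integer age
#'   advances (the population-level fledging date); default 166 (15 June).
#' @param scheme The [age_class_scheme()] the calendar covers.
#' @return A tibble with attribute `fledge_doy`.
#' @export
annual_cycle_calendar <- function(stages = NULL, fledge_doy = 166L,
                                  scheme = age_class_scheme()) {
  if (is.null(stages)) {
    adult <- tibble::tibble(
      stage         = STAGES,
      start_doy     = c(60L, 244L, 264L, 45L),
      duration_days = c(184L, 20L, 146L, 15L)
    )
    juv <- tibble::tibble(
      stage         = c("breeding", "southward_migration", "wintering"),
      start_doy     = c(60L, 244L, 269L),
      duration_days = c(184L, 25L, 156L)
    )
    stages <- dplyr::bind_rows(
      dplyr::mutate(juv, age_class = "juvenile", .before = 1),
      purrr::map_dfr(
        setdiff(scheme$class_label, "juvenile"),
        ~ dplyr::mutate(adult, age_class = .x, .before = 1)
      )
    )
  }
  stages <- tibble::as_tibble(stages)
  stopifnot(all(c("age_class", "stage", "start_doy", "duration_days") %in% names(stages)))
  if (!all(stages$stage %in% STAGES)) {
    stop("unknown stage name(s): ",
         paste(setdiff(stages$stage, STAGES), collapse = ", "), call. = FALSE)
  }
  if (any(stages$duration_days < 1)) stop("stage durations must be >= 1 day", call. = FALSE)
  # every age class must tile days 1..365 exactly once
  for (cl in unique(stages$age_class)) {
    s <- stages[stages$age_class == cl, ]
    covered <- unlist(purrr::map2(s$start_doy, s$duration_days,
                                  ~ ((.x - 1L + seq_len(.y) - 1L) %% 365L) + 1L))
    if (length(covered) != 365L || anyDuplicated(covered) || !setequal(covered, 1:365)) {
      stop("stages for age class '", cl,
           "' do not tile the 365-day year exactly", call. = FALSE)
    }
  }
  if (!setequal(unique(stages$age_class), scheme$class_label)) {
    stop("calendar age classes must match the age-class scheme", call. = FALSE)
  }
  attr(stages, "fledge_doy") <- as.integer(fledge_doy)
  attr(stages, "scheme") <- scheme
  class(stages) <- c("fullcycle_calendar", class(stages))
  stages
}

#' Stage durations per age class
#'
#' @param calendar An [annual_cycle_calendar()].
#' @return Tibble `(age_class, stage, l)` where `l` is the stage duration in
#'   days — the exponent used to convert daily survival to stage survival.
#' @export
stage_durations <- function(calendar) {
  tibble::tibble(age_class = calendar$age_class, stage = calendar$stage,
                 l = as.integer(calendar$duration_days))
}

# day-of-year in a fixed 365-day year: Feb 29 maps to 59 (the stage of Feb 28)
doy365 <- function(dates) {
  lt <- as.POSIXlt(dates)
  doy <- lt$yday + 1L
  leap <- (lt$year %% 4 == 0 & lt$year %% 100 != 0) | (lt$year + 1900) %% 400 == 0
  ifelse(leap & doy >= 60L, doy - 1L, doy)
}

# number of fledging anniversaries up to and including a date
fledge_index <- function(dates, fledge_doy) {
  lt <- as.POSIXlt(dates)
  (lt$year + 1900L) - (doy365(dates) < fledge_doy)
}

# per-age-class stage lookup: matrix [class, 365] of stage names
stage_map <- function(calendar) {
  classes <- unique(calendar$age_class)
  m <- matrix(NA_character_, nrow = length(classes), ncol = 365,
              dimnames = list(classes, NULL))
  for (i in seq_len(nrow(calendar))) {
    doys <- ((calendar$start_doy[i] - 1L + seq_len(calendar$duration_days[i]) - 1L) %% 365L) + 1L
    m[calendar$age_class[i], doys] <- calendar$stage[i]
  }
  m
}

# vectorized (age_class, stage) label for arbitrary (date, age-at-tagging,
# tagging-date) triplets; ages clamped into the scheme's covered range
label_days <- function(dates, age_at_tagging, tagging_dates, calendar,
                       scheme = attr(calendar, "scheme")) {
  fdoy <- attr(calendar, "fledge_doy")
  age <- age_at_tagging + fledge_index(dates, fdoy) - fledge_index(tagging_dates, fdoy)
  age_eff <- pmin(pmax(age, scheme$min_age[1]), max(scheme$max_age))
  cls <- assign_age_class(age_eff, scheme)
  sm <- stage_map(calendar)
  stage <- sm[cbind(match(cls, rownames(sm)), doy365(dates))]
  tibble::tibble(date = dates, age = age, age_class = cls, stage = stage)
}

#' Decompose tracking records into exposure segments
#'
#' Walks each individual's tracked period day by day, labels every day with
#' its life-cycle age class and annual-cycle stage, and collapses runs of
#' identical labels into contiguous exposure segments. A new segment starts
#' at every stage boundary and at every age-class transition — an animal
#' exiting a period alive enters the following period as a new individual,
#' so the within-segment clock restarts at 1 at each boundary. Exactly one
#' segment (the last) carries the death event for individuals that died.
#'
#' Ages below the scheme's minimum (fledglings tagged before their first
#' fledging anniversary) are treated as the youngest class, and ages beyond
#' the maximum as the oldest.
#'
#' @param records Tracking records, as from [simulate_tracking()] or
#'   [read_tracking_csv()].
#' @param calendar An [annual_cycle_calendar()].
#' @param scheme An [age_class_scheme()].
#' @return Tibble with one row per segment: `individual_id`, `age_class`,
#'   `stage`, `start_date`, `end_date`, `days_at_risk`, `event`.
#' @export
decompose_exposure <- function(records, calendar = annual_cycle_calendar(),
                               scheme = attr(calendar, "scheme")) {
  records <- tibble::as_tibble(records)
  if (nrow(records) == 0) {
    return(tibble::tibble(individual_id = character(), age_class = character(),
                          stage = character(), start_date = as.Date(character()),
                          end_date = as.Date(character()),
                          days_at_risk = integer(), event = logical()))
  }
  stopifnot(all(records$fate_date >= records$tagging_date))
  len <- as.integer(records$fate_date - records$tagging_date) + 1L
  idx <- rep(seq_len(nrow(records)), len)
  dates <- records$tagging_date[idx] + (sequence(len) - 1L)
  lab <- label_days(dates, records$age_at_tagging[idx],
                    records$tagging_date[idx], calendar, scheme)
  key <- paste(lab$age_class, lab$stage, sep = "\r")
  new_seg <- c(TRUE, idx[-1] != idx[-length(idx)] | key[-1] != key[-length(key)])
  seg_id <- cumsum(new_seg)
  first <- which(new_seg)
  last <- c(first[-1] - 1L, length(idx))
  seg <- tibble::tibble(
    individual_id = records$individual_id[idx[first]],
    age_class     = lab$age_class[first],
    stage         = lab$stage[first],
    start_date    = dates[first],
    end_date      = dates[last],
    days_at_risk  = as.integer(dates[last] - dates[first]) + 1L,
    event         = FALSE
  )
  # the terminal segment of a died individual carries the event
  seg$event <- last == cumsum(len)[idx[last]] & records$fate[idx[last]] == "died"
  seg
}
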