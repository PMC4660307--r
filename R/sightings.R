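#' Construct a sighting dataset
#'
#' A `sighting_data` object holds photo-identification-style sighting records:
#' an individual registry, an ordered list of sampling periods (calendar days),
#' and grouped survey observations. Two individuals are *associated* in a
#' sampling period when they occur together in at least one group (survey) of
#' that period; all association analyses in the package are built on this
#' day-level definition.
#'
#' @param records data.frame with columns `date` (Date or "YYYY-MM-DD"
#'   character), `survey_id`, `individual_id`. One row per individual per
#'   survey.
#' @param attributes optional data.frame with columns `individual_id`, `sex`
#'   (`male`/`female`/`unknown`) and `community_class` (`NC`/`SC`/`unknown`).
#'   Individuals absent from the table default to `unknown`/`unknown`.
#' @return An object of class `sighting_data` with components `individuals`
#'   (registry data.frame), `samples` (sorted Date vector of sampling
#'   periods), `groups` (list of character id vectors), `group_sample`
#'   (integer index of each group's sampling period) and `group_survey`
#'   (survey labels).
#' @examples
#' rec <- data.frame(date = c("2000-01-01", "2000-01-01", "2000-01-02"),
#'                   survey_id = c("s1", "s1", "s2"),
#'                   individual_id = c("a", "b", "a"))
#' d <- sighting_data(rec)
#' n_individuals(d)
#' @export
sighting_data <- function(records, attributes = NULL) {
  stopifnot(is.data.frame(records))
  need <- c("date", "survey_id", "individual_id")
  if (!all(need %in% names(records)))
    stop("records must have columns date, survey_id, individual_id")
  if (nrow(records) == 0L) stop("no records")
  date <- .parse_dates(records$date)
  survey_id <- as.character(records$survey_id)
  individual_id <- as.character(records$individual_id)

  key <- paste(date, survey_id, individual_id, sep = "\r")
  if (anyDuplicated(key)) {
    warning("duplicate (date, survey_id, individual_id) rows collapsed")
    keep <- !duplicated(key)
    date <- date[keep]; survey_id <- survey_id[keep]
    individual_id <- individual_id[keep]
  }

  samples <- sort(unique(date))
  gkey <- paste(as.integer(date), survey_id, sep = "\r")
  gfac <- factor(gkey, levels = unique(gkey))
  groups <- split(individual_id, gfac)
  names(groups) <- NULL
  first_row <- match(levels(gfac), gkey)
  group_sample <- match(date[first_row], samples)
  group_survey <- survey_id[first_row]
  ord <- order(group_sample, group_survey)
  groups <- groups[ord]
  group_sample <- group_sample[ord]
  group_survey <- group_survey[ord]

  ids <- sort(unique(individual_id))
  agg_first <- vapply(split(date, individual_id), min, numeric(1))
  agg_last <- vapply(split(date, individual_id), max, numeric(1))
  individuals <- data.frame(
    id = ids,
    sex = "unknown",
    community_class = "unknown",
    first_seen = as.Date(agg_first[ids], origin = "1970-01-01"),
    last_seen = as.Date(agg_last[ids], origin = "1970-01-01"),
    stringsAsFactors = FALSE, row.names = NULL)

  if (!is.null(attributes)) {
    if (!all(c("individual_id", "sex", "community_class") %in% names(attributes)))
      stop("attributes must have columns individual_id, sex, community_class")
    m <- match(individuals$id, as.character(attributes$individual_id))
    got <- !is.na(m)
    individuals$sex[got] <- as.character(attributes$sex)[m[got]]
    individuals$community_class[got] <-
      as.character(attributes$community_class)[m[got]]
    individuals$sex[is.na(individuals$sex) | individuals$sex == ""] <- "unknown"
    individuals$community_class[is.na(individuals$community_class) |
                                  individuals$community_class == ""] <- "unknown"
  }

  structure(list(individuals = individuals, samples = samples,
                 groups = groups, group_sample = group_sample,
                 group_survey = group_survey),
            class = "sighting_data")
}

.parse_dates <- function(x) {
  if (inherits(x, "Date")) return(x)
  d <- as.Date(as.character(x), format = "%Y-%m-%d")
  if (anyNA(d))
    stop("malformed date at row ", which(is.na(d))[1L], ": '",
         as.character(x)[which(is.na(d))[1L]], "' (expected YYYY-MM-DD)")
  d
}

#' Read sighting records (and optional attributes) from CSV
#'
#' The sightings file must have the header `date,survey_id,individual_id`
#' with ISO-8601 dates; the optional attributes file has the header
#' `individual_id,sex,community_class`.
#'
#' @param path path to the sightings CSV.
#' @param attributes_path optional path to the individual attributes CSV.
#' @return A [sighting_data] object.
#' @export
read_sightings <- function(path, attributes_path = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  rec <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  if (nrow(rec) == 0L) stop("no records in ", path)
  attrs <- NULL
  if (!is.null(attributes_path)) {
    if (!file.exists(attributes_path))
      stop("file not found: ", attributes_path)
    attrs <- utils::read.csv(attributes_path, stringsAsFactors = FALSE,
                             colClasses = "character")
  }
  sighting_data(rec, attrs)
}

#' Write a sighting dataset back to CSV
#'
#' Inverse of [read_sightings()]: the written file reproduces the record
#' multiset (one row per individual per survey) exactly.
#'
#' @param dataset a [sighting_data] object.
#' @param path output path for the sightings CSV.
#' @param attributes_path optional output path for the attributes CSV.
#' @return `path`, invisibly.
#' @export
write_sightings <- function(dataset, path, attributes_path = NULL) {
  stopifnot(inherits(dataset, "sighting_data"))
  n <- lengths(dataset$groups)
  rec <- data.frame(
    date = format(dataset$samples[rep(dataset$group_sample, n)], "%Y-%m-%d"),
    survey_id = rep(dataset$group_survey, n),
    individual_id = unlist(dataset$groups, use.names = FALSE),
    stringsAsFactors = FALSE)
  utils::write.csv(rec, path, row.names = FALSE, quote = FALSE)
  if (!is.null(attributes_path)) {
    attrs <- dataset$individuals[, c("id", "sex", "community_class")]
    names(attrs)[1L] <- "individual_id"
    utils::write.csv(attrs, attributes_path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' @export
print.sighting_data <- function(x, ...) {
  cat("sighting_data:", nrow(x$individuals), "individuals,",
      length(x$samples), "sampling periods,",
      length(x$groups), "groups\n")
  cat("  date span:", format(min(x$samples)), "to", format(max(x$samples)), "\n")
  invisible(x)
}

#' @export
summary.sighting_data <- function(object, ...) {
  days_seen <- .days_seen(object)
  cat("sighting_data summary\n")
  cat("  individuals:      ", nrow(object$individuals), "\n")
  cat("  sampling periods: ", length(object$samples), "\n")
  cat("  groups (surveys): ", length(object$groups), "\n")
  cat("  group size:        median", stats::median(lengths(object$groups)),
      " max", max(lengths(object$groups)), "\n")
  cat("  days seen/indiv:   median", stats::median(days_seen),
      " range", min(days_seen), "-", max(days_seen), "\n")
  tab <- table(object$individuals$sex, object$individuals$community_class)
  print(tab)
  invisible(object)
}

#' Number of individuals in a sighting dataset
#' @param dataset a [sighting_data] object.
#' @return integer count.
#' @export
n_individuals <- function(dataset) nrow(dataset$individuals)

# distinct sampling periods each individual was seen in (named integer)
.days_seen <- function(dataset) {
  ix <- .sd_index(dataset)
  stats::setNames(ix$n_seen, ix$ids)
}

# Integer-indexed internal representation shared by the C++ kernels:
# ids, groups as 1-based integer vectors, per-group sample index, and the
# individuals x periods "seen" incidence.
.sd_index <- function(dataset, ids = dataset$individuals$id) {
  n_ind <- length(ids)
  n_samples <- length(dataset$samples)
  groups_i <- lapply(dataset$groups, function(g) {
    m <- match(g, ids)
    sort(m[!is.na(m)])
  })
  seen <- matrix(FALSE, n_ind, n_samples)
  for (k in seq_along(groups_i)) {
    g <- groups_i[[k]]
    if (length(g)) seen[cbind(g, dataset$group_sample[k])] <- TRUE
  }
  list(ids = ids, n_ind = n_ind, n_samples = n_samples,
       groups = groups_i, sample_of_group = dataset$group_sample,
       seen = seen, n_seen = rowSums(seen))
}

# rebuild a sighting_data from an index representation (after permutation)
.sd_from_index <- function(dataset, groups_i, ids = dataset$individuals$id) {
  out <- dataset
  out$groups <- lapply(groups_i, function(g) ids[g])
  out
}

#' Apply the study inclusion filter to a sighting dataset
#'
#' Retains individuals identified on strictly more than `min_days` distinct
#' sampling periods and in at least `min_years` distinct calendar years (the
#' pooled reading of "more than 6 days over at least 4 years"). With
#' `strict_per_year = TRUE` the per-year reading is used instead: more than
#' `min_days` days within each of at least `min_years` years.
#'
#' Groups whose membership becomes empty are dropped; sampling periods with no
#' remaining groups are dropped too. The operation is idempotent.
#'
#' @param dataset a [sighting_data] object.
#' @param min_days minimum distinct days (exclusive bound), default 6.
#' @param min_years minimum distinct calendar years (inclusive), default 4.
#' @param strict_per_year logical; see Details.
#' @return A filtered [sighting_data] object (possibly with zero individuals).
#' @export
filter_individuals <- function(dataset, min_days = 6, min_years = 4,
                               strict_per_year = FALSE) {
  stopifnot(inherits(dataset, "sighting_data"),
            min_days >= 0, min_years >= 1)
  ix <- .sd_index(dataset)
  yr <- as.integer(format(dataset$samples, "%Y"))
  keep <- vapply(seq_len(ix$n_ind), function(i) {
    periods <- which(ix$seen[i, ])
    if (!length(periods)) return(FALSE)
    if (strict_per_year) {
      per_year <- table(yr[periods])
      sum(per_year > min_days) >= min_years
    } else {
      length(periods) > min_days && length(unique(yr[periods])) >= min_years
    }
  }, logical(1))
  keep_ids <- ix$ids[keep]
  .subset_dataset(dataset, keep_ids)
}

# restrict a dataset to a set of individuals, dropping emptied groups/periods
.subset_dataset <- function(dataset, keep_ids) {
  groups <- lapply(dataset$groups, function(g) g[g %in% keep_ids])
  nonempty <- lengths(groups) > 0L
  groups <- groups[nonempty]
  group_sample <- dataset$group_sample[nonempty]
  group_survey <- dataset$group_survey[nonempty]
  used <- sort(unique(group_sample))
  samples <- dataset$samples[used]
  group_sample <- match(dataset$samples[group_sample], samples)
  individuals <- dataset$individuals[dataset$individuals$id %in% keep_ids, ,
                                     drop = FALSE]
  row.names(individuals) <- NULL
  structure(list(individuals = individuals, samples = samples,
                 groups = groups, group_sample = group_sample,
                 group_survey = group_survey),
            class = "sighting_data")
}

#' Classify sex from observation histories
#'
#' Applies the photo-identification sexing rules: an individual is *female*
#' when it has at least two calf observations on different days spanning at
#' least two seasons (meteorological quarters); it is *male* when its
#' observation span is at least `male_span_years` (default 10) years with no
#' calf observation ever, or when it carries a distinctive-notch flag, was
#' independent of its mother at first identification, and has a calf-free
#' span of at least `notch_span_years` (default 9) years. The 9-year bound
#' rests on inter-birth intervals in this species being shorter than 8 years.
#' Everything else is `unknown`.
#'
#' @param dataset a [sighting_data] object.
#' @param calf_records data.frame with columns `female_id`, `date`,
#'   `age_class` (`calf` or `juvenile`), or NULL.
#' @param notch_flags named logical vector (id -> has distinctive notches),
#'   missing ids treated as FALSE.
#' @param independent_flags named logical vector (id -> independent from its
#'   mother at first identification), missing ids treated as FALSE.
#' @param male_span_years,notch_span_years span thresholds in years.
#' @return Named character vector id -> `male`/`female`/`unknown`.
#' @export
classify_sex <- function(dataset, calf_records = NULL, notch_flags = NULL,
                         independent_flags = NULL,
                         male_span_years = 10, notch_span_years = 9) {
  stopifnot(inherits(dataset, "sighting_data"))
  ids <- dataset$individuals$id
  span <- as.numeric(dataset$individuals$last_seen -
                       dataset$individuals$first_seen) / 365.25
  names(span) <- ids
  out <- stats::setNames(rep("unknown", length(ids)), ids)

  calf <- .check_calf_records(calf_records, ids)
  has_calf <- ids %in% calf$female_id

  for (id in ids) {
    rec <- calf[calf$female_id == id, , drop = FALSE]
    if (nrow(rec)) {
      days <- unique(rec$date)
      seasons <- unique((as.integer(format(rec$date, "%m")) - 1L) %/% 3L)
      if (length(days) >= 2L && length(seasons) >= 2L) {
        out[id] <- "female"
      } else if (span[id] >= male_span_years) {
        # calf evidence too weak for the female rule, yet the history would
        # otherwise qualify as male: flag the conflict, leave unknown
        warning("individual ", id, " has calf records despite a ",
                round(span[id], 1), "-year otherwise male-qualifying history")
      }
      next
    }
    notch <- isTRUE(unname(notch_flags[id]))
    indep <- isTRUE(unname(independent_flags[id]))
    if (span[id] >= male_span_years ||
        (notch && indep && span[id] >= notch_span_years))
      out[id] <- "male"
  }
  out
}

.check_calf_records <- function(calf_records, ids) {
  if (is.null(calf_records) || nrow(calf_records) == 0L)
    return(data.frame(female_id = character(), date = as.Date(character()),
                      age_class = character(), stringsAsFactors = FALSE))
  need <- c("female_id", "date", "age_class")
  if (!all(need %in% names(calf_records)))
    stop("calf_records must have columns female_id, date, age_class")
  bad <- setdiff(unique(as.character(calf_records$female_id)), ids)
  if (length(bad))
    stop("calf_records reference unknown individuals: ",
         paste(bad, collapse = ", "))
  data.frame(female_id = as.character(calf_records$female_id),
             date = .parse_dates(calf_records$date),
             age_class = as.character(calf_records$age_class),
             stringsAsFactors = FALSE)
}

#' Read calf-observation records from CSV
#'
#' Header `female_id,date,age_class` with `age_class` in `{calf, juvenile}`.
#' @param path CSV path.
#' @return data.frame with parsed dates.
#' @export
read_calf_records <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = "character")
  x$date <- .parse_dates(x$date)
  x
}

#' Reproductive condition of a female at a date
#'
#' Returns the reproductive-condition category (`with_calf`, `with_juvenile`,
#' `without`) from the most recent calf record at or before `at_date` that
#' falls within the dependency window (`window_years`, default 3). With no
#' qualifying record the female is `without` calves or juveniles.
#'
#' @param dataset a [sighting_data] object (used to validate the id).
#' @param female_id individual id.
#' @param at_date Date (or ISO string) at which to assess the condition.
#' @param calf_records data.frame with columns `female_id`, `date`,
#'   `age_class`.
#' @param window_years dependency window in years.
#' @return One of `"with_calf"`, `"with_juvenile"`, `"without"`.
#' @export
reproductive_condition <- function(dataset, female_id, at_date, calf_records,
                                   window_years = 3) {
  stopifnot(inherits(dataset, "sighting_data"))
  if (!female_id %in% dataset$individuals$id)
    stop("unknown individual: ", female_id)
  at_date <- .parse_dates(at_date)
  calf <- .check_calf_records(calf_records, dataset$individuals$id)
  rec <- calf[calf$female_id == female_id & calf$date <= at_date &
                as.numeric(at_date - calf$date) <= window_years * 365.25, ,
              drop = FALSE]
  if (nrow(rec) == 0L) return("without")
  latest <- rec[which.max(as.numeric(rec$date)), ]
  switch(latest$age_class,
         calf = "with_calf",
         juvenile = "with_juvenile",
         stop("unknown age_class: ", latest$age_class))
}
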