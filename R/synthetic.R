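#' Configuration for the synthetic fission-fusion society generator
#'
#' Parameterises a generative model of a two-community fission-fusion
#' society observed by boat surveys: individuals in four sex-by-class cells,
#' day-level sampling with 1-3 surveys per day, per-individual detection
#' scaled by lognormal gregariousness, and survey-level group formation by
#' affinity-weighted agglomeration (or, for temporal scenarios, by explicit
#' dyadic bonds with exponential lifetimes).
#'
#' Defaults mirror the study system the package is modelled on: 54 NC males,
#' 14 SC males, 51 NC females and 4 SC females observed on 84 days spread
#' over 7 years with one to three surveys per day, a strong within-class
#' male affinity (SC males tighter still), fluid female associations driven
#' by per-survey noise only, and NC males associating with females more than
#' SC males do.
#'
#' @param n_nc_male,n_sc_male,n_nc_female,n_sc_female cell counts.
#' @param n_days number of observation days.
#' @param span_years calendar span containing the days.
#' @param start_date first possible survey date.
#' @param surveys_per_day_probs probabilities of 1, 2, 3 surveys on a day.
#' @param detection_prob baseline per-survey detection probability.
#' @param greg_sigma SD of the lognormal per-individual gregariousness
#'   multiplier applied to `detection_prob` (mean 1).
#' @param w0 baseline dyadic affinity.
#' @param male_class_boost added affinity for male dyads of the same class.
#' @param sc_male_extra additional boost among SC males (tight small unit).
#' @param cross_sex_boost named vector `c(NC=, SC=)`: affinity added to
#'   male-female dyads by the male's class.
#' @param noise_scale scale of the per-survey exponential affinity noise
#'   (the only structure female dyads have, hence their fluidity).
#' @param merge_threshold agglomeration stops when no cluster pair has mean
#'   affinity at or above this value.
#' @param size_cap maximum group size (defaults high: the emulated society
#'   forms one large group of roughly 80).
#' @param grouping `"affinity"` (default) or `"bonded_pairs"` (groups are
#'   exactly the currently bonded pairs; used by the temporal scenarios).
#' @param bond_init `"none"` or `"random_pairs"` (random perfect matching).
#' @param bond_rate per-day dissolution hazard of a bond (`b_true`); 0
#'   means permanent bonds. Lifetimes are exponential with mean
#'   `1/bond_rate`.
#' @param bond_bonus affinity added to an active bond under `"affinity"`
#'   grouping.
#' @param rebond `"avoid_past"` (dissolved partners never re-pair; matches
#'   the casual-acquaintances notion of associations that end for good) or
#'   `"allow"`.
#' @param calf_fraction fraction of females given calf histories.
#' @param seed integer seed; identical configs and seeds give byte-identical
#'   output.
#' @return Object of class `ff_config`.
#' @export
ff_config <- function(n_nc_male = 54, n_sc_male = 14, n_nc_female = 51,
                      n_sc_female = 4, n_days = 84, span_years = 7,
                      start_date = "1994-01-01",
                      surveys_per_day_probs = c(0.70, 0.24, 0.06),
                      detection_prob = 0.55, greg_sigma = 0.25,
                      w0 = 1, male_class_boost = 3, sc_male_extra = 3,
                      cross_sex_boost = c(NC = 1.5, SC = 0),
                      noise_scale = 1, merge_threshold = 3, size_cap = 100,
                      grouping = c("affinity", "bonded_pairs"),
                      bond_init = c("none", "random_pairs"), bond_rate = 0,
                      bond_bonus = 20, rebond = c("avoid_past", "allow"),
                      calf_fraction = 0.5, seed = 1) {
  cfg <- list(n_nc_male = n_nc_male, n_sc_male = n_sc_male,
              n_nc_female = n_nc_female, n_sc_female = n_sc_female,
              n_days = as.integer(n_days), span_years = span_years,
              start_date = as.character(start_date),
              surveys_per_day_probs = surveys_per_day_probs,
              detection_prob = detection_prob, greg_sigma = greg_sigma,
              w0 = w0, male_class_boost = male_class_boost,
              sc_male_extra = sc_male_extra,
              cross_sex_boost = cross_sex_boost,
              noise_scale = noise_scale,
              merge_threshold = merge_threshold, size_cap = size_cap,
              grouping = match.arg(grouping),
              bond_init = match.arg(bond_init), bond_rate = bond_rate,
              bond_bonus = bond_bonus, rebond = match.arg(rebond),
              calf_fraction = calf_fraction, seed = as.integer(seed))
  counts <- unlist(cfg[1:4])
  stopifnot(all(counts >= 0), sum(counts) >= 2, cfg$n_days >= 2,
            cfg$detection_prob > 0, cfg$detection_prob <= 1,
            all(surveys_per_day_probs >= 0),
            abs(sum(surveys_per_day_probs) - 1) < 1e-9,
            cfg$bond_rate >= 0, cfg$calf_fraction >= 0,
            cfg$calf_fraction <= 1)
  if (cfg$n_days > round(cfg$span_years * 365.25))
    stop("n_days exceeds the number of days in span_years")
  structure(cfg, class = "ff_config")
}

#' @export
print.ff_config <- function(x, ...) {
  cat("ff_config:", x$n_nc_male + x$n_sc_male + x$n_nc_female + x$n_sc_female,
      "individuals (", x$n_nc_male, "/", x$n_sc_male, "/", x$n_nc_female,
      "/", x$n_sc_female, " NCm/SCm/NCf/SCf ),",
      x$n_days, "days over", x$span_years, "years;",
      "grouping:", x$grouping, "; seed", x$seed, "\n")
  invisible(x)
}

#' Generate a synthetic fission-fusion sighting dataset
#'
#' Simulates the survey process described by an [ff_config]: for each
#' observation day, 1-3 surveys; for each survey, per-individual detection
#' (baseline times lognormal gregariousness); the detected individuals are
#' partitioned into groups by greedy affinity-weighted agglomeration (merge
#' the cluster pair with the highest mean affinity while it stays at or
#' above the threshold, subject to the size cap), where the dyadic affinity
#' is the configured baseline plus class/sex boosts, an active-bond bonus,
#' and fresh per-survey exponential noise. Under `"bonded_pairs"` grouping
#' the groups are the currently bonded pairs (plus singletons), with bonds
#' dissolving at the configured hazard and members re-pairing.
#'
#' @param config an [ff_config].
#' @return list with `dataset` (a [sighting_data] with sex/class attributes
#'   attached), `truth` (ground truth: per-individual sex, class,
#'   gregariousness and detection probability, initial bonds and the bond
#'   event log, plus the config) and `calf_records` (data.frame usable with
#'   [classify_sex()] / [reproductive_condition()]).
#' @export
generate_sightings <- function(config) {
  stopifnot(inherits(config, "ff_config"))
  set.seed(config$seed)
  cells <- data.frame(
    sex = rep(c("male", "male", "female", "female"),
              c(config$n_nc_male, config$n_sc_male,
                config$n_nc_female, config$n_sc_female)),
    community_class = rep(c("NC", "SC", "NC", "SC"),
                          c(config$n_nc_male, config$n_sc_male,
                            config$n_nc_female, config$n_sc_female)),
    stringsAsFactors = FALSE)
  n <- nrow(cells)
  prefix <- paste0(ifelse(cells$community_class == "NC", "N", "S"),
                   ifelse(cells$sex == "male", "M", "F"))
  ids <- sprintf("%s%03d", prefix, stats::ave(seq_len(n), prefix,
                                              FUN = seq_along))
  greg <- exp(stats::rnorm(n, 0, config$greg_sigma) - config$greg_sigma^2 / 2)
  p_det <- pmin(pmax(config$detection_prob * greg, 0.01), 0.98)

  start <- as.Date(config$start_date)
  span_days <- round(config$span_years * 365.25)
  days <- start + sort(sample.int(span_days, config$n_days) - 1L)

  W_struct <- .affinity_structure(cells, config)
  bonds <- .init_bonds(n, config)

  rec_date <- character(0); rec_survey <- character(0); rec_id <- character(0)
  survey_counter <- 0L
  prev_day <- days[1L]
  for (d in seq_along(days)) {
    if (config$bond_rate > 0 || config$bond_init != "none")
      bonds <- .update_bonds(bonds, as.numeric(days[d] - prev_day), config)
    prev_day <- days[d]
    n_surveys <- sample.int(3L, 1L, prob = config$surveys_per_day_probs)
    for (s in seq_len(n_surveys)) {
      survey_counter <- survey_counter + 1L
      detected <- which(stats::runif(n) < p_det)
      if (length(detected) == 0L) next
      groups <- .form_groups(detected, W_struct, bonds, config)
      for (gi in seq_along(groups)) {
        g <- groups[[gi]]
        rec_date <- c(rec_date, rep(format(days[d], "%Y-%m-%d"), length(g)))
        # one record set per simulated group: the data model treats each
        # (date, survey) as one observed group
        rec_survey <- c(rec_survey,
                        rep(sprintf("sv%05d_g%02d", survey_counter, gi),
                            length(g)))
        rec_id <- c(rec_id, ids[g])
      }
    }
  }
  if (!length(rec_id)) stop("infeasible config: no individuals ever detected")
  records <- data.frame(date = rec_date, survey_id = rec_survey,
                        individual_id = rec_id, stringsAsFactors = FALSE)
  attributes_tab <- data.frame(individual_id = ids, sex = cells$sex,
                               community_class = cells$community_class,
                               stringsAsFactors = FALSE)
  dataset <- sighting_data(records, attributes_tab)
  calf_records <- .gen_calf_records(ids, cells, days, config)
  truth <- list(config = config,
                ids = ids, sex = stats::setNames(cells$sex, ids),
                community_class = stats::setNames(cells$community_class, ids),
                gregariousness = stats::setNames(greg, ids),
                detection_prob = stats::setNames(p_det, ids),
                initial_partner = stats::setNames(
                  ifelse(is.na(bonds$initial_partner), NA, ids[bonds$initial_partner]),
                  ids),
                bond_events = bonds$events)
  list(dataset = dataset, truth = truth, calf_records = calf_records)
}

# structural (noise-free) part of the affinity matrix
.affinity_structure <- function(cells, config) {
  n <- nrow(cells)
  W <- matrix(config$w0, n, n)
  male <- cells$sex == "male"
  same_class <- outer(cells$community_class, cells$community_class, "==")
  mm <- outer(male, male, "&")
  W[mm & same_class] <- W[mm & same_class] + config$male_class_boost
  sc_m <- male & cells$community_class == "SC"
  W[outer(sc_m, sc_m, "&")] <- W[outer(sc_m, sc_m, "&")] + config$sc_male_extra
  for (cl in c("NC", "SC")) {
    m_cl <- male & cells$community_class == cl
    block <- outer(m_cl, !male, "&")
    W[block] <- W[block] + config$cross_sex_boost[[cl]]
    W[t(block)] <- W[t(block)] + config$cross_sex_boost[[cl]]
  }
  diag(W) <- NA_real_
  W
}

.init_bonds <- function(n, config) {
  partner <- rep(NA_integer_, n)
  past <- lapply(seq_len(n), function(i) integer(0))
  events <- data.frame(day_index = integer(0), member_1 = integer(0),
                       member_2 = integer(0), event = character(0))
  if (config$bond_init == "random_pairs") {
    ord <- sample.int(n)
    for (k in seq_len(n %/% 2L)) {
      i <- ord[2L * k - 1L]; j <- ord[2L * k]
      partner[i] <- j; partner[j] <- i
    }
  }
  list(partner = partner, past = past, events = events,
       initial_partner = partner)
}

.update_bonds <- function(bonds, dt_days, config) {
  if (config$bond_rate > 0 && dt_days > 0) {
    p_die <- 1 - exp(-config$bond_rate * dt_days)
    bonded_i <- which(!is.na(bonds$partner) & seq_along(bonds$partner) <
                        bonds$partner)
    for (i in bonded_i) {
      if (stats::runif(1) < p_die) {
        j <- bonds$partner[i]
        bonds$partner[c(i, j)] <- NA_integer_
        bonds$past[[i]] <- c(bonds$past[[i]], j)
        bonds$past[[j]] <- c(bonds$past[[j]], i)
      }
    }
  }
  # re-pair the unpartnered pool
  if (config$bond_init != "none") {
    pool <- sample(which(is.na(bonds$partner)))
    while (length(pool) >= 2L) {
      i <- pool[1L]; pool <- pool[-1L]
      ok <- if (config$rebond == "avoid_past")
        pool[!pool %in% bonds$past[[i]]] else pool
      if (!length(ok)) next
      j <- ok[1L]
      bonds$partner[i] <- j; bonds$partner[j] <- i
      pool <- pool[pool != j]
    }
  }
  bonds
}

.form_groups <- function(detected, W_struct, bonds, config) {
  if (config$grouping == "bonded_pairs") {
    det <- logical(length(bonds$partner)); det[detected] <- TRUE
    groups <- list()
    used <- logical(length(det))
    for (i in detected) {
      if (used[i]) next
      j <- bonds$partner[i]
      if (!is.na(j) && det[j] && !used[j]) {
        groups[[length(groups) + 1L]] <- c(i, j)
        used[c(i, j)] <- TRUE
      } else {
        groups[[length(groups) + 1L]] <- i
        used[i] <- TRUE
      }
    }
    return(groups)
  }
  m <- length(detected)
  if (m == 1L) return(list(detected))
  W <- W_struct[detected, detected, drop = FALSE]
  if (!all(is.na(bonds$partner))) {
    pj <- bonds$partner[detected]
    hit <- which(!is.na(pj) & pj %in% detected)
    for (a in hit) {
      b <- match(pj[a], detected)
      W[a, b] <- W[a, b] + config$bond_bonus
    }
  }
  noise <- matrix(0, m, m)
  noise[upper.tri(noise)] <- stats::rexp(m * (m - 1) / 2,
                                         rate = 1 / config$noise_scale)
  W <- W + noise + t(noise)
  diag(W) <- -Inf
  .partition_by_affinity(W, config$merge_threshold, config$size_cap,
                         detected)
}

# greedy agglomeration: repeatedly merge the pair of clusters with the
# largest mean affinity, while that mean >= threshold and sizes permit
.partition_by_affinity <- function(W, threshold, cap, labels) {
  m <- nrow(W)
  S <- W
  size <- rep(1L, m)
  active <- rep(TRUE, m)
  members <- as.list(seq_len(m))
  repeat {
    Sa <- S
    Sa[!active, ] <- -Inf
    Sa[, !active] <- -Inf
    feas <- outer(size, size, "+") <= cap
    Sa[!feas] <- -Inf
    mx <- max(Sa)
    if (!is.finite(mx) || mx < threshold) break
    idx <- which(Sa == mx, arr.ind = TRUE)[1L, ]
    i <- idx[[1L]]; j <- idx[[2L]]
    newS <- (size[i] * S[i, ] + size[j] * S[j, ]) / (size[i] + size[j])
    newS[c(i, j)] <- -Inf
    S[i, ] <- newS; S[, i] <- newS
    members[[i]] <- c(members[[i]], members[[j]])
    size[i] <- size[i] + size[j]
    active[j] <- FALSE
  }
  lapply(members[active], function(ix) labels[ix])
}

.gen_calf_records <- function(ids, cells, days, config) {
  out <- data.frame(female_id = character(0), date = as.Date(character(0)),
                    age_class = character(0), stringsAsFactors = FALSE)
  females <- which(cells$sex == "female")
  if (!length(females) || config$calf_fraction <= 0) return(out)
  mothers <- females[stats::runif(length(females)) < config$calf_fraction]
  span_end <- max(days)
  for (i in mothers) {
    birth <- min(days) + round(stats::runif(1, 0, 365))
    while (birth < span_end) {
      # observations with the calf (<1 yr) in distinct quarters, then as a
      # juvenile (>1 yr) while still dependent
      obs <- birth + c(30, 130, 230)
      obs <- obs[obs <= span_end]
      if (length(obs))
        out <- rbind(out, data.frame(female_id = ids[i], date = obs,
                                     age_class = "calf",
                                     stringsAsFactors = FALSE))
      juv <- birth + round(stats::runif(1, 400, 900))
      if (juv <= span_end)
        out <- rbind(out, data.frame(female_id = ids[i], date = juv,
                                     age_class = "juvenile",
                                     stringsAsFactors = FALSE))
      birth <- birth + round(stats::runif(1, 3, 8) * 365.25)
    }
  }
  out[order(out$female_id, out$date), , drop = FALSE]
}

#' Canned generator scenarios
#'
#' Named instantiations of [ff_config] used throughout the package's tests
#' and examples:
#' \describe{
#'   \item{random_association}{30 individuals, 50 days, no structural
#'     affinity: grouping is driven by per-survey noise only.}
#'   \item{preferred_companions}{40 males in permanent exclusive pairs,
#'     500 near-daily sampling periods.}
#'   \item{casual_acquaintances}{As above but bonds dissolve at 0.01/day and
#'     dissolved partners never re-pair.}
#'   \item{class_split}{Two sealed 15-male cliques (strong within-class
#'     affinity), 50 days.}
#'   \item{paper_like}{The default configuration: 123 individuals in the
#'     54/14/51/4 cells, 84 days over 7 years, male class assortativity,
#'     tight SC males, fluid females.}
#' }
#'
#' @param name scenario name.
#' @param seed integer seed.
#' @return For `scenario_config`, an [ff_config]; for `generate_scenario`,
#'   the result of [generate_sightings()].
#' @export
scenario_config <- function(name = c("random_association",
                                     "preferred_companions",
                                     "casual_acquaintances", "class_split",
                                     "paper_like"), seed = 1) {
  name <- tryCatch(match.arg(name), error = function(e)
    stop("unknown scenario '", name[1L], "'; available: ",
         "random_association, preferred_companions, casual_acquaintances, ",
         "class_split, paper_like"))
  switch(name,
    random_association = ff_config(
      n_nc_male = 15, n_sc_male = 0, n_nc_female = 15, n_sc_female = 0,
      n_days = 50, span_years = 1, detection_prob = 0.5,
      male_class_boost = 0, sc_male_extra = 0,
      cross_sex_boost = c(NC = 0, SC = 0), merge_threshold = 4,
      seed = seed),
    preferred_companions = ff_config(
      n_nc_male = 40, n_sc_male = 0, n_nc_female = 0, n_sc_female = 0,
      n_days = 500, span_years = 1.6, detection_prob = 0.5,
      grouping = "bonded_pairs", bond_init = "random_pairs", bond_rate = 0,
      calf_fraction = 0, seed = seed),
    casual_acquaintances = ff_config(
      n_nc_male = 40, n_sc_male = 0, n_nc_female = 0, n_sc_female = 0,
      n_days = 500, span_years = 1.6, detection_prob = 0.5,
      grouping = "bonded_pairs", bond_init = "random_pairs",
      bond_rate = 0.01, rebond = "avoid_past", calf_fraction = 0,
      seed = seed),
    class_split = ff_config(
      n_nc_male = 15, n_sc_male = 15, n_nc_female = 0, n_sc_female = 0,
      n_days = 50, span_years = 1, detection_prob = 0.5,
      male_class_boost = 6, sc_male_extra = 0,
      cross_sex_boost = c(NC = 0, SC = 0), merge_threshold = 4,
      seed = seed),
    paper_like = ff_config(seed = seed))
}

#' @rdname scenario_config
#' @export
generate_scenario <- function(name, seed = 1) {
  generate_sightings(scenario_config(name, seed))
}

#' Write ground truth (and the generating config) as JSON
#' @param truth the `truth` component of [generate_sightings()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  tr <- truth
  tr$config <- unclass(tr$config)
  tr$bond_events <- NULL
  jsonlite::write_json(tr, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}
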