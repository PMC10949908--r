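#' Default age bins for demographic disaggregation
#'
#' Children under 18, working-age adults 18-64, elderly 65 and over.
#'
#' @return named list of `c(lo, hi)` inclusive age ranges.
#' @export
default_age_bins <- function() {
  list(children = c(0L, 17L), adults = c(18L, 64L), elderly = c(65L, 200L))
}

age_bin_label <- function(age, bins) {
  lab <- rep(NA_character_, length(age))
  for (nm in names(bins)) {
    b <- bins[[nm]]
    lab[is.na(lab) & age >= b[1] & age <= b[2]] <- nm
  }
  lab
}

#' Daily displaced-person counts from a trajectory
#'
#' Counts persons by (lag-shifted) crossing day, optionally restricted to a
#' migration type. Disjoint type filters partition the all-type series.
#'
#' @param trajectory a `migration_trajectory`.
#' @param type_filter `NULL` (all types) or a subset of
#'   `c("refugee", "idp")`.
#' @param days integer vector of days the series should cover; defaults to
#'   `1..(horizon + decision_lag)` shifted by the lag, i.e. every possible
#'   crossing day of the run.
#' @return data frame with columns `day` and `count` (class
#'   `daily_series`).
#' @export
daily_series <- function(trajectory, type_filter = NULL, days = NULL) {
  rec <- trajectory$records
  if (!is.null(type_filter)) {
    rec <- rec[rec$migration_type %in% type_filter, , drop = FALSE]
  }
  if (is.null(days)) {
    days <- seq(1L + trajectory$decision_lag,
                trajectory$horizon + trajectory$decision_lag)
  }
  count <- as.integer(tabulate(match(rec$day, days), nbins = length(days)))
  out <- data.frame(day = days, count = count)
  class(out) <- c("daily_series", "data.frame")
  out
}

#' Centered moving average with truncated edges
#'
#' Each point is replaced by the mean of the window centred on it, with the
#' window truncated at the series edges (so the output has the input's
#' length). `window = 1` is the identity.
#'
#' @param series numeric vector, or a `daily_series` data frame (whose
#'   `count` column is smoothed).
#' @param window window width in days (>= 1, default 7).
#' @return same shape as the input.
#' @export
moving_average <- function(series, window = 7L) {
  if (window < 1L) stop_config("window must be >= 1")
  if (is.data.frame(series)) {
    series$count <- moving_average(series$count, window)
    return(series)
  }
  n <- length(series)
  left <- (window - 1L) %/% 2L
  right <- window - 1L - left
  out <- numeric(n)
  for (i in seq_len(n)) {
    a <- max(1L, i - left)
    b <- min(n, i + right)
    out[i] <- sum(series[a:b]) / (b - a + 1L)
  }
  out
}

#' Disaggregate a trajectory into group counts
#'
#' Person counts by demographic or administrative group; group totals
#' always sum to the trajectory total (each grouping is a partition).
#'
#' @param trajectory a `migration_trajectory`.
#' @param by one of `"age_bin"`, `"gender"`, `"age_gender"`, `"admin1"`,
#'   `"admin2"`.
#' @param age_bins named list of `c(lo, hi)` ranges
#'   (default [default_age_bins()]).
#' @param by_day if `TRUE`, counts are additionally split by crossing day.
#' @param type_filter optional migration-type filter.
#' @return data frame with column `group` (and `day` if `by_day`) and
#'   `count`.
#' @export
disaggregate <- function(trajectory, by = "age_gender",
                         age_bins = default_age_bins(), by_day = FALSE,
                         type_filter = NULL) {
  rec <- trajectory$records
  if (!is.null(type_filter)) {
    rec <- rec[rec$migration_type %in% type_filter, , drop = FALSE]
  }
  group <- switch(by,
    age_bin = age_bin_label(rec$age, age_bins),
    gender = rec$gender,
    age_gender = paste(age_bin_label(rec$age, age_bins), rec$gender,
                       sep = ":"),
    admin1 = rec$admin1,
    admin2 = rec$admin2,
    stop_config("unknown grouping key: ", by)
  )
  if (by_day) {
    agg <- stats::aggregate(list(count = rep(1L, nrow(rec))),
                            by = list(group = group, day = rec$day), sum)
    agg <- agg[order(agg$group, agg$day), , drop = FALSE]
  } else {
    tt <- table(group)
    agg <- data.frame(group = names(tt), count = as.integer(tt),
                      stringsAsFactors = FALSE)
  }
  rownames(agg) <- NULL
  agg
}

#' Mean of per-scenario totals
#'
#' @param values nonempty numeric vector of scenario totals.
#' @return their arithmetic mean.
#' @export
scenario_average <- function(values) {
  if (length(values) == 0L) stop_contract("scenario_average: empty input")
  mean(values)
}

#' Percent difference of an estimate from a reference
#'
#' `100 * (estimate - reference) / reference`; positive values are
#' overestimates.
#'
#' @param estimate,reference numeric; `reference > 0`.
#' @return percent difference.
#' @export
percent_difference <- function(estimate, reference) {
  if (any(reference <= 0)) {
    stop_contract("percent_difference: reference must be > 0")
  }
  100 * (estimate - reference) / reference
}

#' Percentage of households remaining in a region
#'
#' `100 * (total - migrated) / total`: the complement of household
#' depletion, which caps future outflow from a region.
#'
#' @param total_households total household count (> 0).
#' @param migrated_households migrated count in `[0, total]`.
#' @return percent remaining.
#' @export
remaining_fraction <- function(total_households, migrated_households) {
  if (any(total_households <= 0) ||
      any(migrated_households < 0) ||
      any(migrated_households > total_households)) {
    stop_contract("remaining_fraction: need 0 <= migrated <= total, total > 0")
  }
  100 * (total_households - migrated_households) / total_households
}

#' Flow of displaced women at elevated risk of wartime sexual violence
#'
#' Counts migrated females in the at-risk age band whose origin household
#' lay within `radius_km` of at least one retained conflict event during
#' the `window_days` before their migration decision (the proxy for an
#' active military presence in the week leading up to the decision to
#' flee).
#'
#' @param trajectory a `migration_trajectory`.
#' @param events a `conflict_events` data frame.
#' @param population the `population` the trajectory was simulated from.
#' @param window_days look-back window in days before the decision day
#'   (default 7; the event day must satisfy
#'   `decision_day - window_days <= day < decision_day`).
#' @param radius_km exposure radius in km (default 30).
#' @param age_range inclusive `c(lo, hi)` age band (default `c(17, 50)`).
#' @return integer count of at-risk displaced women.
#' @export
at_risk_female_flow <- function(trajectory, events, population,
                                window_days = 7L, radius_km = 30,
                                age_range = c(17L, 50L)) {
  rec <- trajectory$records
  rec <- rec[rec$gender == "female" & rec$age >= age_range[1] &
               rec$age <= age_range[2], , drop = FALSE]
  if (nrow(rec) == 0L || nrow(events) == 0L) return(0L)
  hh <- population$households
  hrow <- match(rec$household_id, hh$household_id)
  n <- 0L
  for (i in seq_len(nrow(rec))) {
    d <- rec$decision_day[i]
    sel <- which(events$day < d & events$day >= d - window_days)
    if (length(sel) == 0L) next
    dist <- haversine_km(hh$latitude[hrow[i]], hh$longitude[hrow[i]],
                         events$latitude[sel], events$longitude[sel])
    if (any(dist <= radius_km)) n <- n + 1L
  }
  n
}

#' Scale an at-risk flow by sexual-violence prevalence estimates
#'
#' Multiplies the at-risk displaced-female flow by a central prevalence
#' and, optionally, by lower/upper prevalence bounds taken from conflict
#' meta-analyses.
#'
#' @param at_risk_flow person count (>= 0).
#' @param prevalence central prevalence in `[0, 1]`.
#' @param bounds optional `c(lo, hi)` prevalences in `[0, 1]`.
#' @return list with `central` and, when bounds are given, `interval`.
#' @export
sexual_violence_estimate <- function(at_risk_flow, prevalence,
                                     bounds = NULL) {
  if (prevalence < 0 || prevalence > 1) {
    stop_contract("prevalence must be in [0, 1]")
  }
  out <- list(central = at_risk_flow * prevalence)
  if (!is.null(bounds)) {
    if (any(bounds < 0 | bounds > 1)) {
      stop_contract("prevalence bounds must be in [0, 1]")
    }
    out$interval <- at_risk_flow * bounds
  }
  out
}

#' Per-region scenario-vs-baseline outflow differences
#'
#' Subtracts baseline per-region displaced-person counts from scenario
#' counts (the map-difference view of counterfactual analysis): positive
#' values mark regions producing more displacement under the scenario.
#'
#' @param scenario_traj,baseline_traj `migration_trajectory` objects from
#'   runs on the same population.
#' @param by `"admin1"` or `"admin2"`.
#' @param type_filter optional migration-type filter.
#' @return data frame with `group`, `scenario`, `baseline`, `difference`.
#' @export
scenario_difference <- function(scenario_traj, baseline_traj,
                                by = "admin2", type_filter = NULL) {
  a <- disaggregate(scenario_traj, by = by, type_filter = type_filter)
  b <- disaggregate(baseline_traj, by = by, type_filter = type_filter)
  groups <- sort(union(a$group, b$group))
  sa <- a$count[match(groups, a$group)]
  sb <- b$count[match(groups, b$group)]
  sa[is.na(sa)] <- 0L
  sb[is.na(sb)] <- 0L
  data.frame(group = groups, scenario = sa, baseline = sb,
             difference = sa - sb, stringsAsFactors = FALSE)
}
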