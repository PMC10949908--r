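#' Canonical conflict-event type labels
#'
#' The default analysis retains the three ACLED event families most likely
#' to damage infrastructure and harm civilians: battles, explosions/remote
#' violence, and violence against civilians.
#'
#' @return character vector of the three canonical labels.
#' @export
default_event_types <- function() {
  c("battles", "explosions/remote violence", "violence against civilians")
}

#' Normalise free-text event-type labels
#'
#' Maps ACLED-style labels (and common singular/abbreviated variants) onto
#' the canonical labels of [default_event_types()]; unrecognised labels are
#' returned lower-cased and trimmed.
#'
#' @param x character vector of event-type labels.
#' @return character vector of normalised labels.
#' @export
normalize_event_type <- function(x) {
  y <- tolower(trimws(as.character(x)))
  out <- y
  out[grepl("battle", y)] <- "battles"
  out[grepl("explosion|remote violence|shelling", y)] <-
    "explosions/remote violence"
  out[grepl("violence against civilians", y)] <- "violence against civilians"
  out
}

#' Compute conflict-event intensity
#'
#' Default intensity model: `I = w_type * (1 + fatality_scale * log(1 +
#' fatalities))`. Strictly positive, monotone nondecreasing in fatalities,
#' and independent of event location and time. Both the per-type weights and
#' the fatality scale are configurable, so alternative intensity definitions
#' can be swapped in.
#'
#' @param event_type character vector of (normalised or raw) event types.
#' @param fatalities nonnegative integer vector.
#' @param type_weights `NULL` (all types weight 1) or a named positive
#'   vector of weights by canonical type; a `.default` entry, if present,
#'   covers unknown types, otherwise an unknown type is an error.
#' @param fatality_scale nonnegative scalar (default 1).
#' @return numeric vector of intensities.
#' @export
compute_intensity <- function(event_type, fatalities, type_weights = NULL,
                              fatality_scale = 1) {
  if (!is.numeric(fatality_scale) || length(fatality_scale) != 1L ||
      fatality_scale < 0) {
    stop_config("fatality_scale must be a nonnegative number")
  }
  if (any(fatalities < 0)) stop_config("fatalities must be >= 0")
  ty <- normalize_event_type(event_type)
  if (is.null(type_weights)) {
    w <- rep(1, length(ty))
  } else {
    if (any(type_weights <= 0)) stop_config("type weights must be positive")
    w <- unname(type_weights[ty])
    if (anyNA(w)) {
      if (".default" %in% names(type_weights)) {
        w[is.na(w)] <- type_weights[[".default"]]
      } else {
        stop_config("no weight for event type(s): ",
                    paste(unique(ty[is.na(w)]), collapse = ", "))
      }
    }
  }
  w * (1 + fatality_scale * log1p(fatalities))
}

#' Read an ACLED-style conflict-event table
#'
#' Accepts the ACLED column dialect (`event_date`, `latitude`, `longitude`,
#' `event_type`, `fatalities`) or a minimal dialect with `date` or a
#' pre-computed integer `day` column. Dates must be ISO-8601 and are
#' converted to integer day indices relative to `date_origin` (day 0).
#' Rows with unparseable dates or coordinates are dropped with a warning
#' reporting the count; if every row is bad, reading fails. Events dated
#' before `date_origin` are an error. Only events whose normalised type is
#' in `type_filter` are retained, ordered by (day, input row).
#'
#' @param csv path to the event CSV.
#' @param date_origin `Date` (or ISO string): day 0 of the simulation.
#' @param type_filter character vector of canonical types to keep; `NULL`
#'   keeps everything. Default [default_event_types()].
#' @param type_weights,fatality_scale passed to [compute_intensity()].
#' @return data frame of class `conflict_events` with columns `event_id`,
#'   `day`, `latitude`, `longitude`, `event_type` (normalised), `fatalities`,
#'   `intensity`; attribute `n_dropped` counts discarded bad rows.
#' @export
read_events <- function(csv, date_origin, type_filter = default_event_types(),
                        type_weights = NULL, fatality_scale = 1) {
  raw <- utils::read.csv(csv, stringsAsFactors = FALSE)
  names(raw) <- tolower(names(raw))
  pick <- function(...) {
    for (nm in c(...)) if (nm %in% names(raw)) return(raw[[nm]])
    NULL
  }
  lat <- pick("latitude", "lat")
  lon <- pick("longitude", "lon", "lng")
  ty <- pick("event_type", "type")
  fat <- pick("fatalities")
  if (is.null(ty)) stop_input("no event_type/type column in ", csv)
  if (is.null(lat) || is.null(lon)) {
    stop_input("no latitude/longitude columns in ", csv)
  }
  if (is.null(fat)) fat <- rep(0L, nrow(raw))

  day <- pick("day")
  if (is.null(day)) {
    dt <- pick("event_date", "date")
    if (is.null(dt)) stop_input("no event_date/date/day column in ", csv)
    parsed <- as.Date(as.character(dt), format = "%Y-%m-%d")
    day <- as.integer(parsed - as.Date(date_origin))
  } else {
    day <- suppressWarnings(as.integer(day))
  }
  latn <- suppressWarnings(as.numeric(lat))
  lonn <- suppressWarnings(as.numeric(lon))
  fatn <- suppressWarnings(as.integer(fat))
  fatn[is.na(fatn)] <- 0L

  bad <- is.na(day) | is.na(latn) | is.na(lonn) |
    latn < -90 | latn > 90 | lonn < -180 | lonn > 180
  if (nrow(raw) > 0 && all(bad)) {
    stop_input("no parseable rows in ", csv)
  }
  n_dropped <- sum(bad)
  if (n_dropped > 0) {
    warning(n_dropped, " event rows dropped (unparseable date/coordinates)")
  }
  keep <- !bad
  day <- day[keep]; latn <- latn[keep]; lonn <- lonn[keep]
  ty <- ty[keep]; fatn <- fatn[keep]
  if (any(day < 0)) {
    stop_input(sum(day < 0), " events dated before date_origin ",
               "(negative day index)")
  }
  ev <- data.frame(event_id = seq_along(day),
                   day = day,
                   latitude = latn,
                   longitude = lonn,
                   event_type = normalize_event_type(ty),
                   fatalities = fatn,
                   stringsAsFactors = FALSE)
  if (!is.null(type_filter)) {
    ev <- ev[ev$event_type %in% normalize_event_type(type_filter), ,
             drop = FALSE]
  }
  ev <- ev[order(ev$day, ev$event_id), , drop = FALSE]
  rownames(ev) <- NULL
  ev$intensity <- compute_intensity(ev$event_type, ev$fatalities,
                                    type_weights, fatality_scale)
  attr(ev, "n_dropped") <- n_dropped
  class(ev) <- c("conflict_events", "data.frame")
  ev
}

#' Write conflict events to CSV
#'
#' @param events a `conflict_events` data frame.
#' @param csv output path.
#' @param date_origin optional `Date`: if given, an `event_date` column is
#'   written alongside the integer `day` index.
#' @return the path, invisibly.
#' @export
write_events <- function(events, csv, date_origin = NULL) {
  out <- as.data.frame(events)
  if (!is.null(date_origin)) {
    out$event_date <- as.Date(date_origin) + out$day
  }
  utils::write.csv(out, csv, row.names = FALSE)
  invisible(csv)
}

#' Specify a counterfactual conflict scenario
#'
#' A scenario is a set of spatial components, each emitting events as an
#' inhomogeneous Poisson stream: on every day of the horizon the component
#' produces `Poisson(rate)` events, placed with isotropic Gaussian scatter
#' (`spread_km`) around its centre, with types drawn from `type_mix` and
#' fatalities drawn as `Poisson(fatality_mean)`. This is a
#' specified-intensity sampler for contingency analysis, not a fitted
#' point-process forecast.
#'
#' @param horizon `c(first_day, last_day)` inclusive integer day range.
#' @param components list of component lists with fields `center`
#'   (`c(lat, lon)`), `spread_km` (> 0), `rate` (events/day, >= 0),
#'   `type_mix` (named probability vector over event types; defaults to
#'   equal weight on the three canonical types) and `fatality_mean` (>= 0,
#'   default 1).
#' @param seed integer seed.
#' @return an object of class `scenario_spec`.
#' @export
scenario_spec <- function(horizon, components, seed = 1L) {
  if (length(horizon) != 2L || horizon[2] < horizon[1] || horizon[1] < 0) {
    stop_config("horizon must be c(first_day, last_day) with 0 <= first <= last")
  }
  if (!is.list(components) || length(components) == 0L) {
    stop_config("components must be a nonempty list")
  }
  components <- lapply(components, function(cm) {
    if (is.null(cm$center) || length(cm$center) != 2L) {
      stop_config("each component needs center = c(lat, lon)")
    }
    cm$spread_km <- cm$spread_km %||% 10
    cm$rate <- cm$rate %||% 0
    cm$fatality_mean <- cm$fatality_mean %||% 1
    if (cm$rate < 0) stop_config("component rate must be >= 0")
    if (cm$spread_km <= 0) stop_config("component spread_km must be > 0")
    if (cm$fatality_mean < 0) stop_config("fatality_mean must be >= 0")
    if (is.null(cm$type_mix)) {
      cm$type_mix <- stats::setNames(rep(1 / 3, 3), default_event_types())
    }
    check_prob_vector(cm$type_mix, "type_mix")
    cm
  })
  structure(list(horizon = as.integer(horizon), components = components,
                 seed = as.integer(seed)),
            class = "scenario_spec")
}

#' Sample a synthetic conflict-event stream from a scenario
#'
#' Draws per-day, per-component Poisson event counts and event attributes
#' from a single seeded stream (days outermost, components inner, so a
#' given spec and seed always reproduce the identical stream).
#'
#' @param spec a [scenario_spec()].
#' @param type_weights,fatality_scale passed to [compute_intensity()].
#' @return a `conflict_events` data frame (possibly empty).
#' @export
sample_scenario_events <- function(spec, type_weights = NULL,
                                   fatality_scale = 1) {
  if (!inherits(spec, "scenario_spec")) {
    stop_config("spec must be a scenario_spec object")
  }
  with_seed(spec$seed, {
    rows <- list()
    for (t in seq(spec$horizon[1], spec$horizon[2])) {
      for (cm in spec$components) {
        n <- stats::rpois(1L, cm$rate)
        if (n == 0L) next
        dy <- stats::rnorm(n, 0, cm$spread_km)
        dx <- stats::rnorm(n, 0, cm$spread_km)
        lat <- cm$center[1] + dy / 110.574
        lon <- cm$center[2] + dx / (111.320 * cos(cm$center[1] * pi / 180))
        ty <- names(cm$type_mix)[sample.int(length(cm$type_mix), n,
                                            replace = TRUE,
                                            prob = cm$type_mix)]
        fat <- stats::rpois(n, cm$fatality_mean)
        rows[[length(rows) + 1L]] <- data.frame(
          day = t, latitude = lat, longitude = lon,
          event_type = normalize_event_type(ty),
          fatalities = as.integer(fat), stringsAsFactors = FALSE)
      }
    }
    if (length(rows) == 0L) {
      ev <- data.frame(event_id = integer(0), day = integer(0),
                       latitude = numeric(0), longitude = numeric(0),
                       event_type = character(0), fatalities = integer(0),
                       intensity = numeric(0), stringsAsFactors = FALSE)
      class(ev) <- c("conflict_events", "data.frame")
      return(ev)
    }
    ev <- do.call(rbind, rows)
    ev <- data.frame(event_id = seq_len(nrow(ev)), ev,
                     stringsAsFactors = FALSE)
    ev$intensity <- compute_intensity(ev$event_type, ev$fatalities,
                                      type_weights, fatality_scale)
    rownames(ev) <- NULL
    class(ev) <- c("conflict_events", "data.frame")
    ev
  })
}
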