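# Fixture builders: tiny hand-rolled worlds for exact checks, plus a cached
# mid-size demo world shared by calibration and acceptance tests.

# A population built directly from data frames (bypasses the generator so
# tests control every attribute).
make_world <- function(households, persons) {
  households$migrated <- households$migrated %||% FALSE
  households$migration_day <- NA_integer_
  households$migration_type <- NA_character_
  households$n_members <- as.integer(
    tabulate(match(persons$household_id, households$household_id),
             nbins = nrow(households)))
  persons$risk_proneness <- persons$risk_proneness %||% 1
  persons$migrated <- FALSE
  persons$migration_day <- NA_integer_
  persons$migration_type <- NA_character_
  structure(list(persons = persons, households = households),
            class = "population")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# n households on a ~1.2 km grid near (50, 30); sizes cycle 1..3.
make_grid_world <- function(n_households, seed = 1) {
  set.seed(seed)
  side <- ceiling(sqrt(n_households))
  ix <- seq_len(n_households) - 1L
  households <- data.frame(
    household_id = seq_len(n_households),
    latitude = 50 + (ix %/% side) * 0.011,
    longitude = 30 + (ix %% side) * 0.017,
    admin1 = ifelse(ix %% 2 == 0, "West", "East"),
    admin2 = paste0("R", 1 + ix %% 3),
    stringsAsFactors = FALSE)
  sizes <- 1L + ix %% 3L
  persons <- data.frame(
    person_id = seq_len(sum(sizes)),
    household_id = rep(households$household_id, sizes),
    age = sample(0:85, sum(sizes), replace = TRUE),
    gender = sample(c("male", "female"), sum(sizes), replace = TRUE),
    stringsAsFactors = FALSE)
  make_world(households, persons)
}

# Events as a conflict_events frame from bare vectors.
make_events <- function(day, latitude, longitude, intensity = 1,
                        event_type = "battles", fatalities = 0L) {
  ev <- data.frame(event_id = seq_along(day), day = as.integer(day),
                   latitude = latitude, longitude = longitude,
                   event_type = event_type,
                   fatalities = as.integer(fatalities),
                   intensity = intensity, stringsAsFactors = FALSE)
  class(ev) <- c("conflict_events", "data.frame")
  ev
}

# Shared mid-size study conditions: 500 generated households, a matched-
# density 5 km neighbourhood, a two-theatre event stream, and "true"
# parameters from which an observed refugee series is self-generated.
demo_cache <- new.env(parent = emptyenv())
demo_world <- function() {
  if (is.null(demo_cache$world)) {
    pop <- assign_risk_proneness(
      generate_population(population_config(500L, seed = 2024L)))
    graph <- build_neighborhood(pop$households, radius_km = 5,
                                k_nearest = 20L)
    spec <- scenario_spec(
      c(0L, 29L),
      list(list(center = c(50.4, 30.5), spread_km = 25, rate = 15,
                fatality_mean = 2),
           list(center = c(48.3, 36.4), spread_km = 30, rate = 15,
                fatality_mean = 3)),
      seed = 99L)
    events <- sample_scenario_events(spec)
    true_params <- migration_params(v = 4, Q = 200)
    obs_traj <- run_simulation(pop, events, true_params, horizon = 30L,
                               seed = 555L, graph = graph)
    observed <- daily_series(obs_traj, type_filter = "refugee")
    demo_cache$world <- list(population = pop, graph = graph,
                             events = events, true_params = true_params,
                             observed = observed, horizon = 30L)
  }
  demo_cache$world
}

# Minimal run config for the command layer, writing under a tempdir.
demo_run_config <- function(outdir, seed = 11L, n_households = 120L,
                            horizon = 12L) {
  list(seed = seed, output_dir = outdir, horizon = horizon,
       population = list(generate = list(n_households = n_households)),
       neighborhood = list(radius_km = 5, k_nearest = 20),
       params = list(v = 4, Q = 200))
}
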