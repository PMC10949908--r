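#' Configuration for the synthetic-population generator
#'
#' Describes the marginals a generated population should match: number of
#' households, household-size distribution, age pyramid, gender split, and a
#' spatial layout of administrative regions around whose centroids household
#' locations are scattered.
#'
#' The defaults emulate, at whatever scale `n_households` requests, the
#' structure of a national population of roughly 46 million people in 19
#' million households: mean household size about 2.4, a female share of 53.8%,
#' and a three-bin age pyramid (under 18 / 18-64 / 65 and over).
#'
#' @param n_households number of households to generate (> 0).
#' @param household_size_probs probability vector over household sizes
#'   `1:length(household_size_probs)`; must sum to 1.
#' @param age_bins list of `c(lo, hi)` integer age ranges (inclusive).
#' @param age_probs probability vector over `age_bins`; must sum to 1.
#' @param female_fraction probability a generated person is female.
#' @param regions data frame with columns `admin1`, `admin2`, `latitude`,
#'   `longitude`, `dispersion_km`, `weight`: households are assigned to a
#'   region with probability proportional to `weight` and placed with an
#'   isotropic Gaussian scatter of standard deviation `dispersion_km` around
#'   the centroid.
#' @param seed integer seed; generation is bitwise reproducible from it.
#' @return an object of class `population_config`.
#' @export
population_config <- function(n_households,
                              household_size_probs = c(0.30, 0.31, 0.19,
                                                       0.12, 0.05, 0.03),
                              age_bins = list(c(0L, 17L), c(18L, 64L),
                                              c(65L, 89L)),
                              age_probs = c(0.18, 0.65, 0.17),
                              female_fraction = 0.538,
                              regions = default_regions(),
                              seed = 1L) {
  if (!is.numeric(n_households) || length(n_households) != 1L ||
      is.na(n_households) || n_households < 1) {
    stop_config("n_households must be a positive integer")
  }
  check_prob_vector(household_size_probs, "household_size_probs")
  check_prob_vector(age_probs, "age_probs")
  check_prob(female_fraction, "female_fraction")
  if (length(age_bins) != length(age_probs)) {
    stop_config("age_bins and age_probs must have the same length")
  }
  for (b in age_bins) {
    if (length(b) != 2L || b[1] < 0 || b[2] < b[1]) {
      stop_config("each age bin must be c(lo, hi) with 0 <= lo <= hi")
    }
  }
  req <- c("admin1", "admin2", "latitude", "longitude", "dispersion_km",
           "weight")
  if (!is.data.frame(regions) || !all(req %in% names(regions)) ||
      nrow(regions) < 1L) {
    stop_config("regions must be a data frame with columns ",
                paste(req, collapse = ", "))
  }
  if (any(regions$weight < 0) || sum(regions$weight) <= 0) {
    stop_config("region weights must be nonnegative with positive sum")
  }
  structure(list(n_households = as.integer(n_households),
                 household_size_probs = household_size_probs,
                 age_bins = age_bins,
                 age_probs = age_probs,
                 female_fraction = female_fraction,
                 regions = regions,
                 seed = as.integer(seed)),
            class = "population_config")
}

#' Default synthetic region layout
#'
#' Six synthetic admin-1/admin-2 regions spread over an eastern-European
#' latitude/longitude band, weighted so that eastern regions carry more
#' population. Purely illustrative; real studies should supply their own
#' centroid table.
#'
#' @return data frame usable as the `regions` argument of
#'   [population_config()].
#' @export
default_regions <- function() {
  data.frame(
    admin1 = c("Oblast-A", "Oblast-A", "Oblast-B", "Oblast-B",
               "Oblast-C", "Oblast-C"),
    admin2 = c("Raion-A1", "Raion-A2", "Raion-B1", "Raion-B2",
               "Raion-C1", "Raion-C2"),
    latitude = c(50.4, 50.9, 49.8, 49.2, 48.5, 48.0),
    longitude = c(30.5, 31.6, 33.0, 34.1, 35.8, 37.0),
    dispersion_km = c(8, 12, 10, 10, 9, 12),
    weight = c(0.20, 0.12, 0.16, 0.14, 0.18, 0.20),
    stringsAsFactors = FALSE
  )
}

#' Generate a synthetic population of persons partitioned into households
#'
#' Samples household sizes, locations (Gaussian scatter around weighted
#' region centroids) and person attributes (age from the configured pyramid,
#' gender from the configured split) from a single seeded random stream.
#' Draw order is fixed (sizes, regions, offsets, then person attributes), so
#' the same configuration always yields byte-identical tables.
#'
#' @param config a [population_config()] object.
#' @return a list of class `population` with elements `persons` and
#'   `households`; see Details for columns.
#' @details `persons` has columns `person_id`, `household_id`, `age`,
#'   `gender`, `risk_proneness` (initialised to 1; see
#'   [assign_risk_proneness()]), plus migration-state columns `migrated`,
#'   `migration_day`, `migration_type`. `households` has `household_id`,
#'   `latitude`, `longitude`, `admin1`, `admin2`, `n_members` and the same
#'   migration-state columns. Every person belongs to exactly one household
#'   and a person's location is their household's location.
#' @export
generate_population <- function(config) {
  if (!inherits(config, "population_config")) {
    stop_config("config must be a population_config object")
  }
  with_seed(config$seed, {
    nh <- config$n_households
    sizes <- sample.int(length(config$household_size_probs), nh,
                        replace = TRUE, prob = config$household_size_probs)
    reg <- sample.int(nrow(config$regions), nh, replace = TRUE,
                      prob = config$regions$weight)
    r <- config$regions[reg, , drop = FALSE]
    # km offsets -> degrees; 1 deg lat ~ 110.574 km, lon shrinks with cos(lat)
    dy <- stats::rnorm(nh, 0, r$dispersion_km)
    dx <- stats::rnorm(nh, 0, r$dispersion_km)
    lat <- r$latitude + dy / 110.574
    lon <- r$longitude + dx / (111.320 * cos(r$latitude * pi / 180))

    households <- data.frame(
      household_id = seq_len(nh),
      latitude = lat,
      longitude = lon,
      admin1 = r$admin1,
      admin2 = r$admin2,
      n_members = sizes,
      migrated = FALSE,
      migration_day = NA_integer_,
      migration_type = NA_character_,
      stringsAsFactors = FALSE,
      row.names = NULL
    )

    np <- sum(sizes)
    bin <- sample.int(length(config$age_probs), np, replace = TRUE,
                      prob = config$age_probs)
    lo <- vapply(config$age_bins, `[`, 0L, 1L)[bin]
    hi <- vapply(config$age_bins, `[`, 0L, 2L)[bin]
    age <- lo + floor(stats::runif(np) * (hi - lo + 1L))
    gender <- ifelse(stats::runif(np) < config$female_fraction,
                     "female", "male")

    persons <- data.frame(
      person_id = seq_len(np),
      household_id = rep.int(households$household_id, sizes),
      age = as.integer(age),
      gender = gender,
      risk_proneness = 1,
      migrated = FALSE,
      migration_day = NA_integer_,
      migration_type = NA_character_,
      stringsAsFactors = FALSE,
      row.names = NULL
    )

    structure(list(persons = persons, households = households),
              class = "population")
  })
}

#' @export
print.population <- function(x, ...) {
  cat("Synthetic population:",
      nrow(x$persons), "persons in",
      nrow(x$households), "households\n")
  cat("  female share:",
      sprintf("%.3f", mean(x$persons$gender == "female")),
      "| mean household size:",
      sprintf("%.2f", nrow(x$persons) / nrow(x$households)), "\n")
  invisible(x)
}

#' Default risk-proneness group map
#'
#' Children (< 18) and the elderly (65+) are assigned a higher
#' risk-proneness multiplier than working-age adults, reflecting that these
#' groups are more affected by socio-political violence.
#'
#' @param child,adult,elderly positive multipliers per age band.
#' @return data frame with columns `age_min`, `age_max`, `gender`, `beta`.
#' @export
default_risk_map <- function(child = 1.2, adult = 1.0, elderly = 1.2) {
  data.frame(age_min = c(0L, 18L, 65L),
             age_max = c(17L, 64L, 200L),
             gender = "any",
             beta = c(child, adult, elderly),
             stringsAsFactors = FALSE)
}

#' Assign group-level risk proneness to persons
#'
#' Sets each person's risk-proneness multiplier (the per-agent scaling of
#' perceived conflict impact) from a lookup table of (age range, gender)
#' groups. The first matching row wins, so more specific rows should precede
#' catch-alls. Idempotent: re-applying the same map leaves the table
#' unchanged.
#'
#' @param persons persons data frame (or a `population`, whose persons are
#'   updated in place).
#' @param group_map data frame with columns `age_min`, `age_max`, `gender`
#'   (`"male"`, `"female"` or `"any"`) and positive `beta`.
#' @return the input with `risk_proneness` filled in.
#' @export
assign_risk_proneness <- function(persons, group_map = default_risk_map()) {
  if (inherits(persons, "population")) {
    persons$persons <- assign_risk_proneness(persons$persons, group_map)
    return(persons)
  }
  req <- c("age_min", "age_max", "gender", "beta")
  if (!is.data.frame(group_map) || !all(req %in% names(group_map))) {
    stop_config("group_map must have columns ", paste(req, collapse = ", "))
  }
  if (any(!is.finite(group_map$beta)) || any(group_map$beta <= 0)) {
    stop_config("risk-proneness multipliers must be positive")
  }
  beta <- rep(NA_real_, nrow(persons))
  for (g in seq_len(nrow(group_map))) {
    row <- group_map[g, ]
    hit <- is.na(beta) &
      persons$age >= row$age_min & persons$age <= row$age_max &
      (row$gender == "any" | persons$gender == row$gender)
    beta[hit] <- row$beta
  }
  if (anyNA(beta)) {
    stop_config("group_map does not cover all persons (",
                sum(is.na(beta)), " unmatched)")
  }
  persons$risk_proneness <- beta
  persons
}

#' Write a population to persons/households CSV files
#'
#' @param population a `population` object.
#' @param persons_csv,households_csv output paths.
#' @return invisibly, the two paths.
#' @export
write_population <- function(population, persons_csv, households_csv) {
  validate_population(population)
  p <- population$persons[, c("person_id", "household_id", "age", "gender",
                              "risk_proneness")]
  h <- population$households[, c("household_id", "latitude", "longitude",
                                 "admin1", "admin2")]
  utils::write.csv(p, persons_csv, row.names = FALSE)
  utils::write.csv(h, households_csv, row.names = FALSE)
  invisible(c(persons = persons_csv, households = households_csv))
}

#' Read a population from persons/households CSV files
#'
#' Validates referential integrity (every person's `household_id` exists, no
#' duplicate ids, no empty households) and reconstructs the migration-state
#' columns, so a write/read round trip is lossless.
#'
#' @param persons_csv path to a CSV with columns `person_id`, `household_id`,
#'   `age`, `gender` (optionally `risk_proneness`).
#' @param households_csv path to a CSV with columns `household_id`,
#'   `latitude`, `longitude`, `admin1`, `admin2`.
#' @return a `population` object.
#' @export
read_population <- function(persons_csv, households_csv) {
  p <- utils::read.csv(persons_csv, stringsAsFactors = FALSE)
  h <- utils::read.csv(households_csv, stringsAsFactors = FALSE)
  preq <- c("person_id", "household_id", "age", "gender")
  hreq <- c("household_id", "latitude", "longitude", "admin1", "admin2")
  if (!all(preq %in% names(p))) {
    stop_input("persons CSV must have columns ", paste(preq, collapse = ", "))
  }
  if (!all(hreq %in% names(h))) {
    stop_input("households CSV must have columns ",
               paste(hreq, collapse = ", "))
  }
  if (is.null(p$risk_proneness)) p$risk_proneness <- rep(1, nrow(p))
  p$migrated <- rep(FALSE, nrow(p))
  p$migration_day <- rep(NA_integer_, nrow(p))
  p$migration_type <- rep(NA_character_, nrow(p))
  h$n_members <- as.integer(tabulate(match(p$household_id, h$household_id),
                                     nbins = nrow(h)))
  h$migrated <- rep(FALSE, nrow(h))
  h$migration_day <- rep(NA_integer_, nrow(h))
  h$migration_type <- rep(NA_character_, nrow(h))
  pop <- structure(list(persons = p[, c(preq, "risk_proneness", "migrated",
                                        "migration_day", "migration_type")],
                        households = h[, c(hreq, "n_members", "migrated",
                                           "migration_day",
                                           "migration_type")]),
                   class = "population")
  validate_population(pop)
  pop
}

#' Validate population invariants
#'
#' Checks the partition property (every person in exactly one existing
#' household, every household nonempty), id uniqueness, age and
#' risk-proneness domains.
#'
#' @param population a `population` object.
#' @return the population, invisibly, or an error.
#' @export
validate_population <- function(population) {
  p <- population$persons
  h <- population$households
  if (anyDuplicated(p$person_id)) stop_input("duplicate person_id values")
  if (anyDuplicated(h$household_id)) {
    stop_input("duplicate household_id values")
  }
  idx <- match(p$household_id, h$household_id)
  if (anyNA(idx)) {
    stop_input(sum(is.na(idx)),
               " persons reference a household_id that does not exist")
  }
  if (nrow(h) > 0 && nrow(p) == 0) {
    stop_input("households present but no persons: every household must ",
               "have at least one member")
  }
  empty <- setdiff(h$household_id, p$household_id)
  if (length(empty) > 0) {
    stop_input(length(empty), " households have no members")
  }
  if (any(p$age < 0)) stop_input("ages must be >= 0")
  if (!all(p$gender %in% c("male", "female"))) {
    stop_input("gender must be 'male' or 'female'")
  }
  if (any(p$risk_proneness <= 0)) {
    stop_input("risk_proneness must be positive")
  }
  invisible(population)
}
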