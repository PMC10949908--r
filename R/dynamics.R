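# The daily perception-decision loop. The chain per day t is:
#   per-event observed impact  f' = I / (dt^tau * ds^delta)
#   attitude                   f  = sum of f' over past events (T_j < t)
#   perceived impact           f~ = beta * f + theta * f~(t-1)
#   migration intent           p' = 1 / (1 + Q exp(-v b w f~))
#   household probability      p  = mean of members' p'
#   initial decision           m' ~ Bernoulli(p)
#   peer threshold             m  = forced by neighbour sum vs I_hi / I_lo
# Migrated households are removed: they skip the loop and count 0 in
# neighbour sums thereafter.

#' Observed impact of a single past conflict event on an agent
#'
#' `f' = I / (dt^tau * ds^delta)` with `dt` the elapsed days (floored at
#' `dt_floor`) and `ds` the haversine distance in km (floored at
#' `ds_floor_km`). Strictly decreasing in distance and elapsed time beyond
#' the floors. Only past events contribute: `event$day >= t` is an error.
#'
#' @param agent_lat,agent_lon agent (household) coordinates.
#' @param event one row of a `conflict_events` frame (list-like with `day`,
#'   `latitude`, `longitude`, `intensity`).
#' @param t current day index.
#' @param params a [migration_params()] object.
#' @return scalar impact `f' >= 0`.
#' @export
event_impact <- function(agent_lat, agent_lon, event, t, params) {
  if (any(event$day >= t)) {
    stop_contract("event_impact: only past events (day < t) contribute")
  }
  dt <- pmax(t - event$day, params$dt_floor)
  ds <- pmax(haversine_km(agent_lat, agent_lon,
                          event$latitude, event$longitude),
             params$ds_floor_km)
  event$intensity / (dt^params$tau * ds^params$delta)
}

#' Attitude towards risk: summed decayed impact of past events
#'
#' Sums [event_impact()] over all events with `day < t` that are within the
#' event horizon and contribute at least `impact_cutoff`; 0 when no event
#' qualifies.
#'
#' @param agent_lat,agent_lon agent coordinates.
#' @param events a `conflict_events` data frame.
#' @param t current day index.
#' @param params a [migration_params()] object.
#' @return scalar attitude `f >= 0`.
#' @export
attitude <- function(agent_lat, agent_lon, events, t, params) {
  sel <- which(events$day < t & events$day >= t - params$event_horizon)
  f <- 0
  for (j in sel) {
    fp <- event_impact(agent_lat, agent_lon, events[j, ], t, params)
    if (fp < params$impact_cutoff) fp <- 0
    f <- f + fp
  }
  f
}

#' Perceived impact: risk-proneness scaling plus retained memory
#'
#' `f~(t) = beta * f(t) + theta * f~(t-1)`. With `theta = 0` the agent is
#' memoryless; with constant `f` the recursion accumulates geometrically to
#' `beta * f / (1 - theta)`.
#'
#' @param f current attitude (>= 0).
#' @param f_prev previous perceived impact (0 at the start of a run).
#' @param beta risk-proneness multiplier (> 0).
#' @param theta memory retention in `[0, 1]`.
#' @return perceived impact `f~ >= 0`.
#' @export
perceived_impact <- function(f, f_prev, beta, theta) {
  beta * f + theta * f_prev
}

#' Logistic migration intent
#'
#' `p' = 1 / (1 + Q exp(-v_eff f~))` with `v_eff = v * b * w`. At zero
#' perceived risk `p' = 1 / (1 + Q)`; as perceived risk grows `p' -> 1`.
#'
#' @param f_tilde perceived impact (>= 0); vectorised.
#' @param params a [migration_params()] object (fields `v`, `Q`, `b`, `w`).
#' @return probability vector in `(0, 1)`.
#' @export
migration_probability <- function(f_tilde, params) {
  1 / (1 + params$Q * exp(-(params$v * params$b * params$w) * f_tilde))
}

#' Household migration probability: mean of member intents
#'
#' @param member_p_primes nonempty numeric vector of member probabilities.
#' @return their arithmetic mean.
#' @export
household_probability <- function(member_p_primes) {
  n <- length(member_p_primes)
  if (n == 0L) stop_contract("household_probability: empty household")
  sum(member_p_primes) / n
}

#' Sample initial household decisions
#'
#' Bernoulli draws from the current RNG stream; element `i` uses the `i`-th
#' uniform, so callers that seed the stream and order households by id get
#' reproducible decisions.
#'
#' @param p probability vector in `[0, 1]`.
#' @return integer vector of 0/1 decisions.
#' @export
sample_initial_decision <- function(p) {
  if (any(p < 0 | p > 1)) {
    stop_contract("sample_initial_decision: probabilities outside [0, 1]")
  }
  as.integer(stats::runif(length(p)) < p)
}

#' Inter-household peer-threshold rule
#'
#' Given the same-day initial decisions of a household's neighbours, the
#' final decision is forced to 1 when the neighbour sum exceeds `I_hi`,
#' forced to 0 when it falls below `I_lo`, and otherwise equals the
#' household's own initial decision (boundary sums fall to "otherwise").
#' The pass is synchronous: thresholds read initial decisions only.
#'
#' @param m_initial integer vector of own initial decisions.
#' @param neighbor_sum integer vector of neighbour initial-decision sums.
#' @param params a [migration_params()] object (fields `I_hi`, `I_lo`).
#' @return integer vector of final decisions.
#' @export
apply_peer_threshold <- function(m_initial, neighbor_sum, params) {
  out <- m_initial
  out[neighbor_sum > params$I_hi] <- 1L
  out[neighbor_sum < params$I_lo] <- 0L
  as.integer(out)
}

#' Classify a migrating household as refugee or IDP
#'
#' Each household draws one uniform (ascending household-id order within a
#' day): refugee with probability `refugee_prob`, else IDP. Under the
#' martial-law rule, households whose only adults are males aged 18-60 are
#' always IDP; they still consume a draw so the random stream does not
#' depend on the flag.
#'
#' @param forced_idp logical vector: is the household barred from crossing?
#' @param params a [migration_params()] object.
#' @return character vector of `"refugee"` / `"idp"`.
#' @export
classify_destination <- function(forced_idp, params) {
  u <- stats::runif(length(forced_idp))
  ifelse(forced_idp, "idp",
         ifelse(u < params$refugee_prob, "refugee", "idp"))
}

# Households whose only adults (18+) are males aged 18-60: barred from
# crossing under martial law. Households with no adult are not barred.
martial_law_barred <- function(persons, household_ids) {
  adults <- persons[persons$age >= 18L, , drop = FALSE]
  barred <- logical(length(household_ids))
  idx <- split(seq_len(nrow(adults)), adults$household_id)
  for (i in seq_along(household_ids)) {
    a <- idx[[as.character(household_ids[i])]]
    if (is.null(a)) next
    barred[i] <- all(adults$gender[a] == "male" & adults$age[a] <= 60L)
  }
  barred
}

# --- engine ----------------------------------------------------------------

# Precomputed, immutable per-run structures.
build_sim_context <- function(population, events, params, graph) {
  persons <- population$persons[order(population$persons$person_id), ,
                                drop = FALSE]
  households <- population$households[
    order(population$households$household_id), , drop = FALSE]
  nh <- nrow(households)
  h_row <- match(persons$household_id, households$household_id)
  member_idx <- split(seq_len(nrow(persons)), h_row)   # by household row
  member_idx <- member_idx[as.character(seq_len(nh))]
  if (anyNA(names(member_idx))) stop_input("household without members")
  adj_rows <- lapply(households$household_id, function(id) {
    match(graph$adjacency[[as.character(id)]], households$household_id)
  })
  ds <- if (nrow(events) > 0) {
    pmax(distance_matrix_km(households$latitude, households$longitude,
                            events$latitude, events$longitude),
         params$ds_floor_km)
  } else {
    matrix(0, nh, 0)
  }
  barred <- if (params$martial_law) {
    martial_law_barred(persons, households$household_id)
  } else {
    rep(FALSE, nh)
  }
  list(persons = persons, households = households, nh = nh,
       np = nrow(persons), h_row = h_row, member_idx = member_idx,
       adj_rows = adj_rows, ds = ds, events = events, barred = barred)
}

# One synchronous day of the perception-decision loop operating on mutable
# state; returns the updated state. Exposed through simulation_step() and
# run_simulation().
step_day <- function(ctx, state, t, params) {
  active_h <- which(!state$h_migrated)
  if (length(active_h) == 0L) {
    if (!is.null(state$keep)) {
      state$keep[[t]] <- list(f_house = numeric(ctx$nh),
                              f_tilde = state$f_tilde,
                              p_prime = numeric(ctx$np),
                              p_house = numeric(0), active_h = active_h,
                              m_prime = integer(0), nbr_sum = integer(0),
                              m_final = integer(0))
    }
    return(state)
  }
  ev <- ctx$events
  sel <- which(ev$day < t & ev$day >= t - params$event_horizon)

  # household-level attitude (members share their household's location)
  f_house <- numeric(ctx$nh)
  for (j in sel) {
    fp <- ev$intensity[j] /
      (pmax(t - ev$day[j], params$dt_floor)^params$tau *
         ctx$ds[, j]^params$delta)
    fp[fp < params$impact_cutoff] <- 0
    f_house <- f_house + fp
  }

  active_p <- which(!state$h_migrated[ctx$h_row])
  f_tilde <- state$f_tilde
  f_tilde[active_p] <- perceived_impact(
    f_house[ctx$h_row[active_p]], state$f_tilde[active_p],
    ctx$persons$risk_proneness[active_p], params$theta)
  p_prime <- numeric(ctx$np)
  p_prime[active_p] <- migration_probability(f_tilde[active_p], params)

  p_house <- vapply(active_h, function(k) {
    ix <- ctx$member_idx[[k]]
    sum(p_prime[ix]) / length(ix)
  }, 0.0)

  # draws consumed in ascending household-id order over active households
  m_prime_active <- sample_initial_decision(p_house)
  m_prime_full <- integer(ctx$nh)          # migrated households count 0
  m_prime_full[active_h] <- m_prime_active

  nbr_sum <- vapply(ctx$adj_rows[active_h], function(ix) {
    if (length(ix) == 0L) 0L else sum(m_prime_full[ix])
  }, 0L)
  m_final <- apply_peer_threshold(m_prime_active, nbr_sum, params)

  new_h <- active_h[m_final == 1L]
  if (length(new_h) > 0L) {
    type <- classify_destination(ctx$barred[new_h], params)
    state$h_migrated[new_h] <- TRUE
    state$h_decision_day[new_h] <- t
    state$h_type[new_h] <- type
  }
  state$f_tilde <- f_tilde
  if (!is.null(state$keep)) {
    state$keep[[t]] <- list(f_house = f_house, f_tilde = f_tilde,
                            p_prime = p_prime,
                            p_house = p_house, active_h = active_h,
                            m_prime = m_prime_active, nbr_sum = nbr_sum,
                            m_final = m_final)
  }
  state
}

new_sim_state <- function(ctx, record_state = FALSE) {
  list(f_tilde = numeric(ctx$np),   # perceived impact starts at 0
       h_migrated = ctx$households$migrated,
       h_decision_day = rep(NA_integer_, ctx$nh),
       h_type = rep(NA_character_, ctx$nh),
       keep = if (record_state) list() else NULL)
}

#' Execute one day of the simulation
#'
#' Runs the full perception-decision chain for day `t` on an explicit state,
#' mainly useful for inspection and testing; [run_simulation()] is the
#' user-facing loop. Random draws come from the current RNG stream.
#'
#' @param population a `population` object.
#' @param events a `conflict_events` data frame.
#' @param t day index (>= 1).
#' @param params a [migration_params()] object.
#' @param graph a [build_neighborhood()] graph.
#' @param state `NULL` to start fresh, or the state returned by a previous
#'   call.
#' @param record_state if `TRUE`, per-day intermediate quantities
#'   (`f_house`, `f_tilde`, `p_prime`, `p_house`, `m_prime`, `m_final`) are
#'   kept in `state$keep`.
#' @return the updated state (a plain list).
#' @export
simulation_step <- function(population, events, t, params, graph,
                            state = NULL, record_state = FALSE) {
  ctx <- build_sim_context(population, events, params, graph)
  if (is.null(state)) state <- new_sim_state(ctx, record_state)
  step_day(ctx, state, t, params)
}

#' Run the displacement simulation
#'
#' Applies the daily perception-decision loop for `t = 1..horizon`,
#' freezing migrated households as it goes, and returns a trajectory of
#' person-level migration records. Crossing days are the decision day
#' shifted by `params$decision_lag`. The run is bitwise reproducible from
#' `seed`: one stream drives all draws, consumed in a fixed order (per day:
#' one uniform per active household ascending by id for the Bernoulli
#' decision, then one per newly migrating household for destination
#' classification).
#'
#' @param population a `population` object.
#' @param events a `conflict_events` data frame (may be empty).
#' @param params a [migration_params()] object.
#' @param horizon number of simulated days (>= 1).
#' @param seed integer seed.
#' @param graph optional [build_neighborhood()] graph; built with default
#'   parameters when omitted.
#' @param record_state keep per-day intermediate quantities (memory-heavy;
#'   for diagnostics).
#' @return an object of class `migration_trajectory`: a list with `records`
#'   (person-level data frame: `day` = crossing day, `decision_day`,
#'   `household_id`, `person_id`, `age`, `gender`, `admin1`, `admin2`,
#'   `migration_type`), totals, `horizon`, `decision_lag`, `seed`, `params`,
#'   and optionally `state_history`.
#' @export
run_simulation <- function(population, events, params, horizon, seed,
                           graph = NULL, record_state = FALSE) {
  if (!is.numeric(horizon) || length(horizon) != 1L || horizon < 1) {
    stop_config("horizon must be >= 1")
  }
  validate_population(population)
  if (is.null(graph)) graph <- build_neighborhood(population$households)
  ctx <- build_sim_context(population, events, params, graph)
  state <- new_sim_state(ctx, record_state)
  state <- with_seed(seed, {
    for (t in seq_len(horizon)) {
      state <- step_day(ctx, state, t, params)
    }
    state
  })

  mig_h <- which(state$h_migrated & !ctx$households$migrated)
  rec_rows <- which(ctx$h_row %in% mig_h)
  hh <- ctx$households
  records <- data.frame(
    day = state$h_decision_day[ctx$h_row[rec_rows]] + params$decision_lag,
    decision_day = state$h_decision_day[ctx$h_row[rec_rows]],
    household_id = ctx$persons$household_id[rec_rows],
    person_id = ctx$persons$person_id[rec_rows],
    age = ctx$persons$age[rec_rows],
    gender = ctx$persons$gender[rec_rows],
    admin1 = hh$admin1[ctx$h_row[rec_rows]],
    admin2 = hh$admin2[ctx$h_row[rec_rows]],
    migration_type = state$h_type[ctx$h_row[rec_rows]],
    stringsAsFactors = FALSE
  )
  records <- records[order(records$day, records$household_id,
                           records$person_id), , drop = FALSE]
  rownames(records) <- NULL
  structure(list(records = records,
                 n_households_migrated = length(mig_h),
                 n_persons_migrated = nrow(records),
                 n_households_total = ctx$nh,
                 n_persons_total = ctx$np,
                 horizon = as.integer(horizon),
                 decision_lag = params$decision_lag,
                 seed = as.integer(seed),
                 params = params,
                 state_history = if (record_state) state$keep else NULL),
            class = "migration_trajectory")
}

#' @export
print.migration_trajectory <- function(x, ...) {
  cat("Migration trajectory over", x$horizon, "days:\n")
  cat("  households migrated:", x$n_households_migrated, "of",
      x$n_households_total, "\n")
  cat("  persons migrated:   ", x$n_persons_migrated, "of",
      x$n_persons_total, "\n")
  if (nrow(x$records) > 0) {
    tt <- table(x$records$migration_type)
    cat("  by type:", paste(names(tt), tt, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write a trajectory's person-level records to CSV
#'
#' @param trajectory a `migration_trajectory`.
#' @param csv output path.
#' @return the path, invisibly.
#' @export
write_trajectory <- function(trajectory, csv) {
  utils::write.csv(trajectory$records, csv, row.names = FALSE)
  invisible(csv)
}
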