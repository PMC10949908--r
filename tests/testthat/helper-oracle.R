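# Independent straight-line oracles. These deliberately avoid the package's
# vectorised engine internals: everything is a scalar loop written directly
# from the model definition, consuming random draws one at a time in the
# documented order (ascending household id).

oracle_haversine_km <- function(lat1, lon1, lat2, lon2) {
  # standard haversine, R = 6378137 m (geosphere's default radius)
  r <- 6378137 / 1000
  p <- pi / 180
  a <- sin((lat2 - lat1) * p / 2)^2 +
    cos(lat1 * p) * cos(lat2 * p) * sin((lon2 - lon1) * p / 2)^2
  2 * r * asin(pmin(1, sqrt(a)))
}

# Brute-force neighbourhood: all-pairs distances, radius filter, cap at k
# nearest (ties by distance then id), union re-symmetrization.
oracle_neighborhood <- function(households, radius_km, k) {
  ids <- households$household_id
  n <- length(ids)
  kept <- vector("list", n)
  for (i in seq_len(n)) {
    d <- geosphere::distHaversine(
      cbind(households$longitude[i], households$latitude[i]),
      cbind(households$longitude, households$latitude)) / 1000
    cand <- setdiff(which(d <= radius_km), i)
    if (length(cand) > k) {
      cand <- cand[order(d[cand], ids[cand])][seq_len(k)]
    }
    kept[[i]] <- cand
  }
  adj <- stats::setNames(rep(list(integer(0)), n), as.character(ids))
  for (i in seq_len(n)) {
    for (j in kept[[i]]) {
      adj[[as.character(ids[i])]] <- union(adj[[as.character(ids[i])]],
                                           ids[j])
      adj[[as.character(ids[j])]] <- union(adj[[as.character(ids[j])]],
                                           ids[i])
    }
  }
  lapply(adj, sort)
}

# Scalar reference simulation: returns per-day intermediates and the final
# migration assignment. Draw order per day: one uniform per active
# household (ascending id) for the initial decision, then one per newly
# migrating household (ascending id) for destination classification.
oracle_run <- function(population, events, params, graph, horizon, seed) {
  persons <- population$persons[order(population$persons$person_id), ]
  households <- population$households[
    order(population$households$household_id), ]
  np <- nrow(persons)
  nh <- nrow(households)
  hrow <- match(persons$household_id, households$household_id)

  f_tilde <- numeric(np)
  migrated <- households$migrated
  decision_day <- rep(NA_integer_, nh)
  mig_type <- rep(NA_character_, nh)
  days <- list()

  barred <- logical(nh)
  if (params$martial_law) {
    for (k in seq_len(nh)) {
      mem <- persons[hrow == k, ]
      ad <- mem[mem$age >= 18, ]
      barred[k] <- nrow(ad) > 0 &&
        all(ad$gender == "male" & ad$age <= 60)
    }
  }

  set.seed(seed)
  for (t in seq_len(horizon)) {
    f_house <- numeric(nh)
    p_prime <- numeric(np)
    for (k in seq_len(nh)) {
      if (migrated[k]) next
      f <- 0
      for (j in seq_len(nrow(events))) {
        if (!(events$day[j] < t &&
              events$day[j] >= t - params$event_horizon)) next
        dt <- max(t - events$day[j], params$dt_floor)
        ds <- max(geosphere::distHaversine(
          cbind(households$longitude[k], households$latitude[k]),
          cbind(events$longitude[j], events$latitude[j])) / 1000,
          params$ds_floor_km)
        fp <- events$intensity[j] / (dt^params$tau * ds^params$delta)
        if (fp < params$impact_cutoff) fp <- 0
        f <- f + fp
      }
      f_house[k] <- f
    }
    for (i in seq_len(np)) {
      k <- hrow[i]
      if (migrated[k]) next
      f_tilde[i] <- persons$risk_proneness[i] * f_house[k] +
        params$theta * f_tilde[i]
      p_prime[i] <- 1 / (1 + params$Q *
                           exp(-(params$v * params$b * params$w) *
                                 f_tilde[i]))
    }
    active <- which(!migrated)
    m_prime <- integer(nh)
    p_house <- rep(NA_real_, nh)
    for (k in active) {   # ascending household id: one draw each
      mem <- which(hrow == k)
      p_house[k] <- sum(p_prime[mem]) / length(mem)
      m_prime[k] <- as.integer(stats::runif(1) < p_house[k])
    }
    m_final <- integer(nh)
    nbr_sum <- rep(NA_integer_, nh)
    for (k in active) {
      nb <- graph$adjacency[[as.character(households$household_id[k])]]
      s <- 0L
      for (u in nb) {
        ur <- match(u, households$household_id)
        if (!migrated[ur]) s <- s + m_prime[ur]
      }
      nbr_sum[k] <- s
      m_final[k] <- if (s > params$I_hi) 1L
        else if (s < params$I_lo) 0L
        else m_prime[k]
    }
    new_h <- active[m_final[active] == 1L]
    for (k in new_h) {    # ascending id: one classification draw each
      u <- stats::runif(1)
      mig_type[k] <- if (barred[k]) "idp"
        else if (u < params$refugee_prob) "refugee" else "idp"
      decision_day[k] <- t
      migrated[k] <- TRUE
    }
    days[[t]] <- list(f_house = f_house, f_tilde = f_tilde,
                      p_prime = p_prime, p_house = p_house,
                      m_prime = m_prime, nbr_sum = nbr_sum,
                      m_final = m_final, active = active)
  }
  list(days = days, migrated = migrated, decision_day = decision_day,
       mig_type = mig_type, households = households, persons = persons)
}

# Flatten an oracle result into the engine's record format.
oracle_records <- function(orc, params) {
  hh <- orc$households
  pp <- orc$persons
  hrow <- match(pp$household_id, hh$household_id)
  new_mig <- orc$migrated & !hh$migrated
  keep <- which(new_mig[hrow])
  rec <- data.frame(
    day = orc$decision_day[hrow[keep]] + params$decision_lag,
    decision_day = orc$decision_day[hrow[keep]],
    household_id = pp$household_id[keep],
    person_id = pp$person_id[keep],
    age = pp$age[keep],
    gender = pp$gender[keep],
    admin1 = hh$admin1[hrow[keep]],
    admin2 = hh$admin2[hrow[keep]],
    migration_type = orc$mig_type[hrow[keep]],
    stringsAsFactors = FALSE)
  rec <- rec[order(rec$day, rec$household_id, rec$person_id), ]
  rownames(rec) <- NULL
  rec
}
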