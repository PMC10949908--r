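#' Build the household neighbourhood network
#'
#' Connects every pair of households within `radius_km` of each other
#' (haversine distance), then caps each household's neighbour list at the
#' `k_nearest` closest and re-symmetrizes by keeping an edge if either
#' endpoint retained it. Ties at the cap are broken by distance, then by
#' household id. Isolated households are allowed.
#'
#' The bounded degree keeps the inter-household peer-threshold rule
#' well-scaled (neighbour sums are counts against fixed integer thresholds)
#' and the simulation engine linear in the number of households.
#'
#' @param households households data frame (or a `population`).
#' @param radius_km neighbourhood radius in km (> 0; default 1).
#' @param k_nearest maximum neighbours retained per household before
#'   re-symmetrization (>= 0; default 20).
#' @return an object of class `neighborhood_graph`: a list with `adjacency`
#'   (named list mapping each household id to a sorted integer vector of
#'   neighbour ids), `radius_km` and `k_nearest`.
#' @export
build_neighborhood <- function(households, radius_km = 1, k_nearest = 20L) {
  if (inherits(households, "population")) households <- households$households
  if (!is.numeric(radius_km) || length(radius_km) != 1L || radius_km <= 0) {
    stop_config("radius_km must be a positive number")
  }
  if (!is.numeric(k_nearest) || length(k_nearest) != 1L || k_nearest < 0) {
    stop_config("k_nearest must be a nonnegative integer")
  }
  k_nearest <- as.integer(k_nearest)
  ids <- households$household_id
  n <- length(ids)
  lat <- households$latitude
  lon <- households$longitude

  nbr <- vector("list", n)   # indices of radius-neighbours, capped at k
  dst <- vector("list", n)
  if (n > 1L) {
    # spatial binning: candidates live in the same or an adjacent cell
    dlat <- radius_km / 110.574
    dlon <- radius_km / (111.320 * max(cos(lat * pi / 180), 0.05))
    cx <- floor(lon / dlon)
    cy <- floor(lat / dlat)
    key <- paste(cx, cy)
    cell_members <- split(seq_len(n), key)
    for (i in seq_len(n)) {
      cand <- integer(0)
      for (ox in -1:1) {
        for (oy in -1:1) {
          m <- cell_members[[paste(cx[i] + ox, cy[i] + oy)]]
          if (!is.null(m)) cand <- c(cand, m)
        }
      }
      cand <- cand[cand != i]
      if (length(cand) == 0L) next
      d <- haversine_km(lat[i], lon[i], lat[cand], lon[cand])
      keep <- d <= radius_km
      cand <- cand[keep]
      d <- d[keep]
      if (length(cand) > k_nearest) {
        ord <- order(d, ids[cand])[seq_len(k_nearest)]
        cand <- cand[ord]
        d <- d[ord]
      }
      nbr[[i]] <- cand
      dst[[i]] <- d
    }
  }
  # re-symmetrize after capping: keep an edge if either endpoint kept it
  if (n > 1L) {
    from <- rep.int(seq_len(n), lengths(nbr))
    to <- unlist(nbr, use.names = FALSE)
    if (length(from) > 0L) {
      a <- pmin(from, to)
      b <- pmax(from, to)
      e <- unique(cbind(a, b))
      adj_idx <- split(c(e[, 2], e[, 1]), c(e[, 1], e[, 2]))
    } else {
      adj_idx <- list()
    }
  } else {
    adj_idx <- list()
  }
  adjacency <- stats::setNames(rep(list(integer(0)), n), as.character(ids))
  for (nm in names(adj_idx)) {
    i <- as.integer(nm)
    adjacency[[as.character(ids[i])]] <- sort(ids[adj_idx[[nm]]])
  }
  structure(list(adjacency = adjacency,
                 radius_km = radius_km,
                 k_nearest = k_nearest),
            class = "neighborhood_graph")
}

#' @export
print.neighborhood_graph <- function(x, ...) {
  deg <- lengths(x$adjacency)
  cat("Household neighbourhood graph:", length(deg), "households,",
      sum(deg) / 2, "edges (radius", x$radius_km, "km, cap",
      x$k_nearest, ")\n")
  cat("  degree: min", min(deg), "median", stats::median(deg),
      "max", max(deg), "\n")
  invisible(x)
}
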