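#' Haversine great-circle distance in kilometres
#'
#' Thin wrapper around [geosphere::distHaversine()] returning kilometres.
#' Inputs are WGS84 decimal degrees.
#'
#' @param lat1,lon1 numeric vectors, first set of points.
#' @param lat2,lon2 numeric vectors, second set of points (recycled).
#' @return numeric vector of distances in km.
#' @export
haversine_km <- function(lat1, lon1, lat2, lon2) {
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2)) / 1000
}

# Full distance matrix (km) between two point sets, computed in row chunks to
# bound memory. Rows index (lat1, lon1), columns (lat2, lon2).
distance_matrix_km <- function(lat1, lon1, lat2, lon2, chunk = 2000L) {
  n1 <- length(lat1)
  out <- matrix(0, nrow = n1, ncol = length(lat2))
  p2 <- cbind(lon2, lat2)
  i <- 1L
  while (i <= n1) {
    j <- min(i + chunk - 1L, n1)
    out[i:j, ] <- geosphere::distm(cbind(lon1[i:j], lat1[i:j]), p2,
                                   fun = geosphere::distHaversine) / 1000
    i <- j + 1L
  }
  out
}
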