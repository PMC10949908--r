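#' Model parameter vector
#'
#' Bundles the parameters of the perception-decision model with their
#' domain checks.
#'
#' @param tau temporal decay exponent (> 1): elapsed days enter the impact
#'   denominator as `dt^tau`, an implicit discounting of older events.
#' @param delta spatial decay exponent (> 1): distance enters as `ds^delta`.
#' @param theta memory retention in `[0, 1]`: share of yesterday's perceived
#'   impact carried into today.
#' @param v growth rate of migration intent in perceived impact (> 0).
#' @param Q no-risk migration control (> 0): the probability of migrating
#'   with zero perceived risk is `1 / (1 + Q)`.
#' @param I_hi,I_lo upper/lower peer thresholds (integers >= 0,
#'   `I_lo <= I_hi`): a household is forced to migrate when more than `I_hi`
#'   neighbours intend to, forced to stay when fewer than `I_lo` do.
#' @param b,w bias and conflict scales in `[0, 1]` (default 1). The logistic
#'   uses the folded growth rate `v * b * w`; only `v` is calibrated.
#' @param refugee_prob probability a migrating household crosses the border
#'   (refugee) rather than displacing internally (IDP).
#' @param decision_lag days between the migration decision and the counted
#'   border crossing (default 0).
#' @param ds_floor_km floor on the spatial distance (km) in the impact
#'   denominator, preventing unbounded impact at an event's location.
#' @param dt_floor floor on the elapsed-days term (default 1, so yesterday's
#'   events have `dt = 1`).
#' @param event_horizon events older than this many days are dropped from
#'   the attitude sum (default 30); with `tau > 1` the discarded tail is
#'   negligible.
#' @param impact_cutoff single-event impacts below this are treated as 0
#'   (default 1e-9).
#' @param martial_law if `TRUE`, migrating households whose only adults are
#'   males aged 18-60 are always classified IDP (border closed to them).
#' @return an object of class `migration_params` (a validated list).
#' @export
migration_params <- function(tau = 1.5, delta = 2.0, theta = 0.8,
                             v = 0.5, Q = 1e4,
                             I_hi = 8L, I_lo = 1L,
                             b = 1, w = 1,
                             refugee_prob = 0.6,
                             decision_lag = 0L,
                             ds_floor_km = 1,
                             dt_floor = 1,
                             event_horizon = 30L,
                             impact_cutoff = 1e-9,
                             martial_law = FALSE) {
  if (tau <= 1) stop_config("tau must be > 1")
  if (delta <= 1) stop_config("delta must be > 1")
  if (theta < 0 || theta > 1) stop_config("theta must be in [0, 1]")
  if (v <= 0) stop_config("v must be > 0")
  if (Q <= 0) stop_config("Q must be > 0")
  if (I_hi < 0 || I_lo < 0) stop_config("thresholds must be >= 0")
  if (I_lo > I_hi) stop_config("I_lo must be <= I_hi")
  if (b < 0 || b > 1 || w < 0 || w > 1) {
    stop_config("b and w must be in [0, 1]")
  }
  check_prob(refugee_prob, "refugee_prob")
  if (decision_lag < 0) stop_config("decision_lag must be >= 0")
  if (ds_floor_km <= 0) stop_config("ds_floor_km must be > 0")
  if (dt_floor <= 0) stop_config("dt_floor must be > 0")
  if (event_horizon < 1) stop_config("event_horizon must be >= 1")
  structure(list(tau = tau, delta = delta, theta = theta, v = v, Q = Q,
                 I_hi = as.integer(I_hi), I_lo = as.integer(I_lo),
                 b = b, w = w, refugee_prob = refugee_prob,
                 decision_lag = as.integer(decision_lag),
                 ds_floor_km = ds_floor_km, dt_floor = dt_floor,
                 event_horizon = as.integer(event_horizon),
                 impact_cutoff = impact_cutoff,
                 martial_law = isTRUE(martial_law)),
            class = "migration_params")
}

#' @export
print.migration_params <- function(x, ...) {
  cat("Migration model parameters:\n")
  cat(sprintf("  decay: tau=%.3g delta=%.3g theta=%.3g\n",
              x$tau, x$delta, x$theta))
  cat(sprintf("  logistic: v=%.3g Q=%.3g (b=%.3g, w=%.3g)\n",
              x$v, x$Q, x$b, x$w))
  cat(sprintf("  thresholds: I_lo=%d I_hi=%d | refugee_prob=%.3g lag=%d\n",
              x$I_lo, x$I_hi, x$refugee_prob, x$decision_lag))
  invisible(x)
}

# Replace selected fields, revalidating.
update_params <- function(params, values) {
  stopifnot(inherits(params, "migration_params"))
  p <- unclass(params)
  for (nm in names(values)) p[[nm]] <- values[[nm]]
  do.call(migration_params, p)
}
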