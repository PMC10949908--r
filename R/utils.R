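# Internal helpers: condition classes, seeded evaluation, small validators.

stop_config <- function(...) {
  stop(errorCondition(paste0(...), class = c("displaceabm_config_error",
                                             "displaceabm_error", "error")))
}

stop_input <- function(...) {
  stop(errorCondition(paste0(...), class = c("displaceabm_input_error",
                                             "displaceabm_error", "error")))
}

stop_contract <- function(...) {
  stop(errorCondition(paste0(...), class = c("displaceabm_contract_error",
                                             "displaceabm_error", "error")))
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves the caller's RNG state, seeds the generator, evaluates `code`, and
#' restores the previous state on exit so library code never clobbers the
#' user's random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1) # materialize a state so it can be restored
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

check_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop_config(name, " must be a single probability in [0, 1]")
  }
  invisible(x)
}

check_prob_vector <- function(p, name, tol = 1e-9) {
  if (!is.numeric(p) || length(p) < 1L || anyNA(p) || any(p < 0)) {
    stop_config(name, " must be a nonnegative probability vector")
  }
  if (abs(sum(p) - 1) > tol) {
    stop_config(name, " must sum to 1 (got ", format(sum(p)), ")")
  }
  invisible(p)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
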