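# Internal helpers shared across modules.

#' Run code under a temporary RNG state
#'
#' Sets the seed for the duration of `code` and restores the caller's
#' `.Random.seed` afterwards, so generators never perturb user randomness.
#' @noRd
with_local_seed <- function(seed, code) {
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Derive a child seed from a master seed and a stable text label
#'
#' Polynomial string hash folded into the master seed, kept below 2^31 so it
#' is always a valid `set.seed()` argument. Adding objects with new labels
#' never shifts the stream of existing labels.
#' @noRd
derive_seed <- function(master, label) {
  m <- 2147483647
  h <- 0
  for (k in utf8ToInt(label)) h <- (h * 131 + k) %% m
  as.integer((abs(master) %% m + h * 31) %% m)
}

#' Stop with a consistent invalid-config error class
#' @noRd
stop_invalid <- function(...) {
  stop(structure(class = c("evogut_invalid_config", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

#' Clamp numeric values to an interval
#' @noRd
clamp <- function(x, lo, hi) pmin(hi, pmax(lo, x))

#' Logistic sweep trajectory
#' @noRd
logistic_freq <- function(week, midpoint, rate, final_frequency) {
  final_frequency / (1 + exp(-rate * (week - midpoint)))
}
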