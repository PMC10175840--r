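# Internal helpers: classed error conditions, seeded RNG scopes, window logic.

abort_invalid <- function(msg, call. = FALSE) {
  stop(structure(
    class = c("invalid_argument", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

abort_data <- function(msg) {
  stop(structure(
    class = c("data_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

#' @noRd
check_number <- function(x, name, min = -Inf, strict_min = NULL) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    abort_invalid(sprintf("`%s` must be a single finite number", name))
  if (!is.null(strict_min) && x <= strict_min)
    abort_invalid(sprintf("`%s` must be > %s", name, strict_min))
  if (x < min)
    abort_invalid(sprintf("`%s` must be >= %s", name, min))
  invisible(x)
}

# Evaluate `expr` under a deterministic RNG state without disturbing the
# caller's stream. `seed = NULL` uses the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Deterministic per-animal child seed from (root seed, index). Keeps values
# positive and below 2^31 so set.seed() accepts them on 32-bit integers.
child_seed <- function(root, index) {
  root <- as.numeric(root)
  s <- (root * 48271 + index * 16807 + 12345) %% 2147483647
  as.integer(s + 1)
}

# Half-open window membership: start <= t < end. All analysis windows in the
# package use this convention against frame timestamps.
in_window <- function(t, window) {
  t >= window[1] & t < window[2]
}

check_window <- function(window, name = "window") {
  if (!is.numeric(window) || length(window) != 2L || any(!is.finite(window)))
    abort_invalid(sprintf("`%s` must be two finite numbers (start_s, end_s)", name))
  if (window[1] >= window[2])
    abort_invalid(sprintf("`%s` must satisfy start_s < end_s", name))
  invisible(window)
}

# Smallest absolute angular difference a - b, in (-pi, pi].
ang_diff <- function(a, b) {
  d <- (a - b) %% (2 * pi)
  ifelse(d > pi, d - 2 * pi, d)
}
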