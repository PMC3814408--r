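#' Piecewise-constant BSP target schedule
#'
#' A target schedule is a step function of time: each row gives the start
#' time of a segment and the BSP level held until the next breakpoint.
#'
#' @param start_s Strictly increasing segment start times in seconds
#'   (first typically 0).
#' @param level BSP targets in `(0, 1)`, one per segment.
#' @return A tibble of class `bsp_schedule` with columns `start_s`,
#'   `level`.
#' @examples
#' target_schedule(c(0, 900, 1800), c(0.4, 0.7, 0.9))
#' @export
target_schedule <- function(start_s, level) {
  if (length(start_s) != length(level) || length(level) < 1) {
    stop("`start_s` and `level` must be equal-length, nonempty.",
         call. = FALSE)
  }
  if (any(diff(start_s) <= 0)) {
    stop("`start_s` must be strictly increasing.", call. = FALSE)
  }
  if (any(level <= 0) || any(level >= 1)) {
    stop("All levels must lie in (0, 1).", call. = FALSE)
  }
  out <- tibble::tibble(start_s = as.numeric(start_s),
                        level = as.numeric(level))
  class(out) <- c("bsp_schedule", class(out))
  out
}

#' Target level at given times
#'
#' @param schedule A [target_schedule()].
#' @param t Times in seconds (vectorized). Times before the first
#'   breakpoint take the first level.
#' @return Numeric vector of target BSP levels.
#' @export
target_at <- function(schedule, t) {
  idx <- findInterval(t, schedule$start_s)
  schedule$level[pmax(idx, 1L)]
}

# index-th permutation of seq_len(k) in lexicographic order (1-based)
perm_lex <- function(k, index) {
  if (index < 1 || index > factorial(k)) {
    stop("Permutation index out of range 1..k!.", call. = FALSE)
  }
  items <- seq_len(k)
  out <- integer(k)
  r <- index - 1
  for (i in seq_len(k)) {
    f <- factorial(k - i)
    j <- r %/% f
    r <- r %% f
    out[i] <- items[j + 1]
    items <- items[-(j + 1)]
  }
  out
}

#' Generate a multi-level target protocol
#'
#' Builds the equal-duration multi-level protocol used in simulation-based
#' verification: each of the given BSP levels is held for
#' `minutes_per_level`, in the order given by the `permutation`-th
#' lexicographic permutation of the levels. With the default three levels
#' held 15 minutes each, there are 6 distinct 45-minute protocols.
#'
#' @param levels BSP levels in `(0, 1)` (given in ascending order; the
#'   permutation is applied to this vector).
#' @param minutes_per_level Duration of each level in minutes.
#' @param permutation 1-based lexicographic permutation index in
#'   `1..length(levels)!`.
#' @return A [target_schedule()].
#' @examples
#' target_protocol(permutation = 4)
#' @export
target_protocol <- function(levels = c(0.4, 0.7, 0.9),
                            minutes_per_level = 15, permutation = 1) {
  k <- length(levels)
  ord <- perm_lex(k, permutation)
  target_schedule(
    start_s = (seq_len(k) - 1) * minutes_per_level * 60,
    level = levels[ord]
  )
}
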