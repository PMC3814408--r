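#' Read and write binomial observation streams
#'
#' Observation CSVs carry one row per control interval with columns
#' `t` (interval index or time in seconds), `N` (sub-samples per
#' interval) and `n` (suppression count). `t_index` is accepted as an
#' alias for `t`.
#'
#' @param path File path.
#' @param obs A data frame with columns `t`, `N`, `n`.
#' @return `read_observations()` returns a tibble with columns `t`, `N`,
#'   `n`; `write_observations()` returns `path` invisibly.
#' @export
read_observations <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("t_index" %in% names(d) && !"t" %in% names(d)) {
    names(d)[names(d) == "t_index"] <- "t"
  }
  need <- c("t", "N", "n")
  if (!all(need %in% names(d))) {
    stop("Observation file must have columns t (or t_index), N, n.",
         call. = FALSE)
  }
  if (any(d$n < 0 | d$n > d$N)) {
    stop("Counts must satisfy 0 <= n <= N.", call. = FALSE)
  }
  tibble::as_tibble(d[need])
}

#' @rdname read_observations
#' @export
write_observations <- function(obs, path) {
  utils::write.csv(obs[c("t", "N", "n")], path, row.names = FALSE)
  invisible(path)
}

#' Read and write PK parameter files
#'
#' PK parameters are serialized as JSON (or YAML) with keys `k10`, `k12`,
#' `k21`, `b_in`, `dt` and `transform`.
#'
#' @param path File path (`.json`, `.yaml` or `.yml`).
#' @param params A [pk_params()] object.
#' @return `read_pk_params()` returns a [pk_params()];
#'   `write_pk_params()` returns `path` invisibly.
#' @export
read_pk_params <- function(path) {
  cfg <- read_config(path)
  pk_params(
    k10 = cfg$k10, k12 = cfg$k12, k21 = cfg$k21, b_in = cfg$b_in,
    dt = cfg$dt %||% 1,
    transform = cfg$transform %||% "hyperbolic_ratio"
  )
}

#' @rdname read_pk_params
#' @export
write_pk_params <- function(params, path) {
  x <- params[c("k10", "k12", "k21", "b_in", "dt", "transform")]
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(x, path)
  } else {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read and write target schedules
#'
#' Schedules are serialized as JSON/YAML with arrays `start_s` and
#' `level`, or as two-column CSV.
#'
#' @param path File path.
#' @param schedule A [target_schedule()].
#' @return `read_schedule()` returns a [target_schedule()];
#'   `write_schedule()` returns `path` invisibly.
#' @export
read_schedule <- function(path) {
  if (grepl("\\.csv$", path)) {
    d <- utils::read.csv(path)
    return(target_schedule(d$start_s, d$level))
  }
  cfg <- read_config(path)
  target_schedule(unlist(cfg$start_s), unlist(cfg$level))
}

#' @rdname read_schedule
#' @export
write_schedule <- function(schedule, path) {
  if (grepl("\\.csv$", path)) {
    utils::write.csv(as.data.frame(schedule), path, row.names = FALSE)
  } else if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(list(start_s = schedule$start_s,
                          level = schedule$level), path)
  } else {
    jsonlite::write_json(list(start_s = schedule$start_s,
                              level = schedule$level),
                         path, digits = NA)
  }
  invisible(path)
}

# Parse a JSON or YAML config file into a list.
read_config <- function(path) {
  if (!file.exists(path)) {
    stop("Config file not found: ", path, call. = FALSE)
  }
  if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
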