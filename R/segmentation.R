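#' Segmentation configuration
#'
#' Settings for converting raw burst-suppression EEG into the binary
#' suppression series and per-interval binomial counts consumed by the
#' estimator: the rectified signal is low-pass filtered (default below
#' 5 Hz) and thresholded; the binary series is then sub-sampled at
#' `subrate_hz` (default 10 Hz) within each observation interval
#' (default 1 s), so an interval carries `N = interval_s * subrate_hz`
#' binary sub-samples.
#'
#' @param lowpass_hz Low-pass cutoff applied to the rectified EEG (Hz).
#' @param threshold Filtered-magnitude cutoff in microvolts; samples whose
#'   filtered magnitude is strictly below it are labeled suppressed. When
#'   `NULL`, [binarize_eeg()] calls [suggest_threshold()].
#' @param interval_s Observation interval in seconds.
#' @param subrate_hz Binary sub-sample rate within an interval (Hz).
#' @return An object of class `seg_config`.
#' @export
seg_config <- function(lowpass_hz = 5, threshold = NULL, interval_s = 1,
                       subrate_hz = 10) {
  N <- interval_s * subrate_hz
  if (lowpass_hz <= 0) stop("`lowpass_hz` must be positive.", call. = FALSE)
  if (!is.null(threshold) && threshold <= 0) {
    stop("`threshold` must be positive.", call. = FALSE)
  }
  if (abs(N - round(N)) > 1e-9 || N < 1) {
    stop("`interval_s * subrate_hz` must be a positive integer.",
         call. = FALSE)
  }
  structure(
    list(lowpass_hz = lowpass_hz, threshold = threshold,
         interval_s = interval_s, subrate_hz = subrate_hz,
         N = as.integer(round(N))),
    class = "seg_config"
  )
}

#' Binarize a raw EEG record into suppression labels
#'
#' Real-time segmentation of burst-suppression EEG: the voltage trace is
#' rectified (absolute value), the magnitude is smoothed with a causal
#' 2nd-order Butterworth low-pass filter at `cfg$lowpass_hz`, and each
#' sample is labeled suppressed when the filtered magnitude falls strictly
#' below the threshold. The filter is causal, so labels can be produced
#' sample-by-sample in a running system; its state is initialized at the
#' first sample's magnitude to avoid a startup transient.
#'
#' @param eeg A data frame with columns `time_s` and `uV`, or a numeric
#'   vector of voltages (then `fs` is required).
#' @param cfg A [seg_config()]. If `cfg$threshold` is `NULL` a threshold
#'   is suggested from the data with a message.
#' @param fs Sampling rate in Hz; inferred from `time_s` when omitted.
#' @return A tibble with columns `time_s`, `uV`, `magnitude` (filtered)
#'   and `suppressed` (logical).
#' @export
binarize_eeg <- function(eeg, cfg = seg_config(), fs = NULL) {
  if (is.data.frame(eeg)) {
    if (is.null(fs)) {
      dt <- stats::median(diff(eeg$time_s))
      fs <- 1 / dt
    }
    v <- eeg$uV
    time_s <- eeg$time_s
  } else {
    if (is.null(fs)) stop("`fs` is required for vector input.", call. = FALSE)
    v <- as.numeric(eeg)
    time_s <- (seq_along(v) - 1) / fs
  }
  if (cfg$lowpass_hz >= fs / 2) {
    stop("`lowpass_hz` must be below the Nyquist frequency.", call. = FALSE)
  }
  mag <- filtered_magnitude(v, fs, cfg$lowpass_hz)
  threshold <- cfg$threshold
  if (is.null(threshold)) {
    threshold <- suggest_threshold(mag)
    message(sprintf("Using suggested threshold %.3g uV.", threshold))
  }
  tibble::tibble(
    time_s = time_s, uV = v, magnitude = mag,
    suppressed = mag < threshold
  )
}

# Rectify and causally low-pass the EEG; a 1-s pad at the first sample's
# magnitude stands in for filter initial conditions.
filtered_magnitude <- function(v, fs, lowpass_hz) {
  r <- abs(v)
  bf <- signal::butter(2, lowpass_hz / (fs / 2), type = "low")
  pad <- rep(r[1], ceiling(fs))
  y <- signal::filter(bf, c(pad, r))
  as.numeric(y)[-seq_along(pad)]
}

#' Aggregate binary suppression labels into binomial counts
#'
#' Sub-samples the binary suppression series at `cfg$subrate_hz` within
#' each observation interval (taking the label at each sub-sample
#' instant) and counts suppressed sub-samples, producing the binomial
#' observations `n` out of `N` that feed the estimator. A stream of `T`
#' seconds yields exactly `floor(T / interval_s)` observations; trailing
#' samples short of a full interval are dropped.
#'
#' @param binary A logical vector of per-sample suppression labels, or
#'   the tibble returned by [binarize_eeg()] (its `suppressed` column is
#'   used).
#' @param cfg A [seg_config()].
#' @param fs Sampling rate of the binary series (Hz).
#' @return A tibble with columns `t` (interval index, 1-based), `N`, `n`.
#' @export
aggregate_counts <- function(binary, cfg = seg_config(), fs) {
  if (is.data.frame(binary)) {
    if (missing(fs)) {
      fs <- 1 / stats::median(diff(binary$time_s))
    }
    binary <- binary$suppressed
  }
  spi <- fs * cfg$interval_s              # samples per interval
  n_int <- floor(length(binary) / spi)
  if (n_int < 1) {
    return(tibble::tibble(t = integer(), N = integer(), n = integer()))
  }
  # sub-sample instants: offsets 0, 1/subrate, ... within each interval
  offsets <- round((seq_len(cfg$N) - 1) / cfg$subrate_hz * fs)
  idx <- outer(offsets + 1, round((seq_len(n_int) - 1) * spi), `+`)
  counts <- colSums(matrix(binary[idx], nrow = cfg$N))
  tibble::tibble(t = seq_len(n_int), N = cfg$N, n = as.integer(counts))
}

#' Suggest a suppression threshold from filtered magnitudes
#'
#' Burst-suppression EEG has a bimodal filtered-magnitude distribution:
#' a low mode during suppressions and a high mode during bursts. This fits
#' two components to the log-magnitude distribution (k-means with
#' deterministic quantile initialization) and returns the geometric
#' midpoint of the component centers. The value is advisory — in
#' practice thresholds are confirmed by visual inspection — and a
#' percentile fallback (25th) is used with a warning when the
#' distribution shows no usable separation.
#'
#' @param magnitude Numeric vector of filtered EEG magnitudes (uV),
#'   e.g. the `magnitude` column of [binarize_eeg()] output.
#' @return A scalar threshold in microvolts.
#' @export
suggest_threshold <- function(magnitude) {
  magnitude <- magnitude[is.finite(magnitude)]
  # causal IIR filtering can ring slightly negative after sharp amplitude
  # drops; floor well below the signal scale before taking logs
  floor_ <- 1e-4 * max(magnitude, 1e-12)
  lm_ <- log(pmax(magnitude, floor_))
  fallback <- function() {
    warning("Magnitude distribution is not bimodal; ",
            "falling back to the 25th percentile.", call. = FALSE)
    as.numeric(stats::quantile(magnitude, 0.25, names = FALSE))
  }
  centers <- stats::quantile(lm_, c(0.1, 0.9), names = FALSE)
  if (diff(centers) < 1e-9) return(fallback())
  km <- tryCatch(
    stats::kmeans(lm_, centers = matrix(centers, ncol = 1)),
    error = function(e) NULL
  )
  if (is.null(km)) return(fallback())
  c1 <- min(km$centers); c2 <- max(km$centers)
  within_sd <- sqrt(sum(km$withinss) / max(length(lm_) - 2, 1))
  if ((c2 - c1) < 2 * within_sd) return(fallback())
  exp((c1 + c2) / 2)
}
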