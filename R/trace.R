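#' Global current peak of a chronoamperometry trace
#'
#' Returns the global maximum of the current and the time at which it
#' occurs. Ties are broken by the earliest timestamp. No smoothing is
#' applied; pass the trace through [smooth_trace()] first if desired.
#'
#' @param trace Data frame with columns `time_h` and `current_A`
#'   (times strictly increasing, at least one sample).
#' @return A one-row tibble with `peak_current` (A) and `peak_time` (h).
#' @examples
#' tr <- make_current_pulse(peak_current = 6.43e-6, peak_time = 31.5,
#'                          total_charge = 1.06, duration = 150)
#' find_current_peak(tr)
#' @export
find_current_peak <- function(trace) {
  trace <- check_trace(trace)
  i <- which.max(trace$current_A) # which.max takes the first maximum
  tibble::tibble(peak_current = trace$current_A[i], peak_time = trace$time_h[i])
}

#' Moving-average smoothing of a trace
#'
#' Optional centred moving average applied before peak detection or cycle
#' segmentation. `window = 1` is the identity.
#'
#' @param trace Data frame with `time_h` and a value column.
#' @param window Odd window width in samples.
#' @param column Name of the value column (default `current_A`).
#' @return The trace with the value column smoothed (edges use the
#'   truncated window).
#' @export
smooth_trace <- function(trace, window = 1, column = "current_A") {
  stopifnot(window >= 1, window %% 2 == 1)
  if (window == 1) return(tibble::as_tibble(trace))
  x <- trace[[column]]
  h <- (window - 1) / 2
  n <- length(x)
  sm <- vapply(seq_len(n), function(i) {
    mean(x[max(1, i - h):min(n, i + h)])
  }, numeric(1))
  trace[[column]] <- sm
  tibble::as_tibble(trace)
}

#' Segment a voltage trace into feed cycles
#'
#' Reproduces the fed-batch operating rule of an acclimating microbial fuel
#' cell: each time the cell voltage has fallen below the refeed threshold,
#' the next upward crossing of the threshold starts a new cycle. A
#' one-sample hysteresis suppresses cycle splits from single-sample noise:
#' the voltage must stay below threshold for at least two consecutive
#' samples before a new cycle can begin.
#'
#' @param voltage_trace Data frame with columns `time_h` and `voltage_V`
#'   (times strictly increasing).
#' @param refeed_threshold Volts; a new feeding follows a drop below this
#'   value (default 0.001 V).
#' @return A tibble of per-cycle summaries: `cycle_index`, `peak_voltage`
#'   (V), `peak_time` (h), `start_h`, `end_h`. Empty (zero rows) when the
#'   trace never exceeds the threshold.
#' @examples
#' tr <- data.frame(time_h = 0:10,
#'                  voltage_V = c(0, .3, .2, 0, 0, .4, .1, 0, 0, .5, 0))
#' segment_cycles(tr)
#' @export
segment_cycles <- function(voltage_trace, refeed_threshold = 0.001) {
  if (refeed_threshold <= 0) abort("refeed threshold must be > 0")
  tr <- voltage_trace
  if (!all(c("time_h", "voltage_V") %in% names(tr))) {
    abort("voltage trace needs columns time_h and voltage_V")
  }
  if (any(diff(tr$time_h) <= 0)) abort("trace times must be strictly increasing")
  v <- tr$voltage_V
  n <- length(v)
  starts <- integer()
  below_run <- 0L # consecutive samples seen below threshold
  armed <- TRUE   # start of trace counts as ready for a first cycle
  for (i in seq_len(n)) {
    if (v[i] >= refeed_threshold) {
      if (armed) starts <- c(starts, i)
      armed <- FALSE
      below_run <- 0L
    } else {
      below_run <- below_run + 1L
      if (below_run >= 2L) armed <- TRUE
    }
  }
  if (length(starts) == 0) {
    return(tibble::tibble(cycle_index = integer(), peak_voltage = numeric(),
                          peak_time = numeric(), start_h = numeric(),
                          end_h = numeric()))
  }
  ends <- c(starts[-1] - 1L, n)
  purrr::map_dfr(seq_along(starts), function(k) {
    idx <- starts[k]:ends[k]
    j <- idx[which.max(v[idx])]
    tibble::tibble(cycle_index = k, peak_voltage = v[j],
                   peak_time = tr$time_h[j],
                   start_h = tr$time_h[starts[k]], end_h = tr$time_h[ends[k]])
  })
}

#' Ratio of two cycle peak voltages
#'
#' @param summaries Cycle table from [segment_cycles()].
#' @param cycle_a Index of the reference (denominator) cycle.
#' @param cycle_b Index of the comparison (numerator) cycle.
#' @return `peak_voltage[cycle_b] / peak_voltage[cycle_a]`.
#' @examples
#' cyc <- tibble::tibble(cycle_index = 1:2, peak_voltage = c(0.354, 0.672))
#' peak_ratio(cyc, 1, 2) # ~1.90
#' @export
peak_ratio <- function(summaries, cycle_a, cycle_b) {
  pa <- summaries$peak_voltage[match(cycle_a, summaries$cycle_index)]
  pb <- summaries$peak_voltage[match(cycle_b, summaries$cycle_index)]
  if (is.na(pa) || is.na(pb)) abort("cycle not found")
  if (pa == 0) abort("reference cycle peak is zero")
  pb / pa
}
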