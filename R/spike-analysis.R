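#' Detect spikes in a membrane trace
#'
#' Spikes are the samples the simulator pinned at the stereotyped peak value
#' (`V_spike`, or its mirror about `V_rest` for reverse action potentials).
#' Detection is by value match against the trace, independently of the
#' simulator's own spike log, so the two routes can be cross-checked.
#'
#' @param trace a `membrane_trace`, or any data frame with `time_ms` and
#'   `V_mV` columns.
#' @param V_spike peak value to match (default 20 mV, or the simulating
#'   parameters if the trace carries them).
#' @param V_rest resting potential used to locate mirrored reverse peaks.
#' @return A tibble with `spike_time_ms` (ordered) and `sign`.
#' @export
detect_spikes <- function(trace, V_spike = NULL, V_rest = NULL) {
  p <- attr(trace, "params")
  V_spike <- V_spike %||% (if (!is.null(p)) p$V_spike else 20)
  V_rest <- V_rest %||% (if (!is.null(p)) p$V_rest else -65)
  peak_neg <- 2 * V_rest - V_spike
  pos <- trace$V_mV == V_spike
  neg <- trace$V_mV == peak_neg
  hit <- pos | neg
  tibble(spike_time_ms = trace$time_ms[hit],
         sign = ifelse(pos[hit], 1L, -1L))
}

spike_times_of <- function(spikes) {
  if (is.data.frame(spikes)) spikes$spike_time_ms else as.numeric(spikes)
}

# default burst gap: 3x the median inter-spike interval (scale-free)
default_gap_threshold <- function(times) {
  if (length(times) < 2) return(Inf)
  3 * median(diff(times))
}

#' Segment a spike train into bursts
#'
#' Consecutive spikes whose inter-spike interval is at most `gap_threshold`
#' share a cluster; clusters partition the train. The default threshold is
#' three times the median inter-spike interval of the train, which is
#' scale-free and robust to the gradual interval growth seen during
#' adaptation.
#'
#' @param spikes a spike-train tibble (from [detect_spikes()] or [tidy()])
#'   or a numeric vector of spike times in ms.
#' @param gap_threshold milliseconds; must be positive.
#' @return A tibble with `spike_time_ms` and integer `cluster`.
#' @export
segment_bursts <- function(spikes, gap_threshold = NULL) {
  times <- spike_times_of(spikes)
  gap_threshold <- gap_threshold %||% default_gap_threshold(times)
  if (!is.finite(gap_threshold) && length(times) >= 2) gap_threshold <- Inf
  if (!is.infinite(gap_threshold) && gap_threshold <= 0) {
    abort("`gap_threshold` must be positive.", class = "memlif_invalid_parameter")
  }
  if (length(times) == 0) {
    return(tibble(spike_time_ms = numeric(0), cluster = integer(0)))
  }
  new_cluster <- c(TRUE, diff(times) > gap_threshold)
  tibble(spike_time_ms = times, cluster = cumsum(new_cluster))
}

#' Burst and adaptation summary of a spike train
#'
#' Quantifies spike-frequency adaptation: the train is `adapting` when the
#' internal rate of its first cluster exceeds the late rate by at least
#' `rate_factor` (default 2). The late rate is the internal rate of the
#' last cluster when that is a distinct multi-spike cluster lying in the
#' final half of the horizon (so periodic pulse-train responses, whose
#' clusters all fire at the same internal rate, are not mistaken for
#' adaptation), and otherwise the average rate over the final half of the
#' horizon. `adaptation_duration_ms` is the span
#' of the first cluster.
#'
#' @param clusters output of [segment_bursts()] (or a spike train, which is
#'   segmented with the default gap).
#' @param grid the [time_grid()] of the simulation, or a numeric horizon in
#'   ms.
#' @param rate_factor required ratio of first-cluster rate to late rate.
#' @return A one-row tibble (`burst_summary`): `n_spikes`, `n_clusters`,
#'   `cluster_sizes` (list column), `adaptation_duration_ms`,
#'   `first_rate_hz`, `late_rate_hz`, `mean_rate_hz`, `adapting`.
#' @export
adaptation_metrics <- function(clusters, grid, rate_factor = 2) {
  if (!is.data.frame(clusters) || !"cluster" %in% names(clusters)) {
    clusters <- segment_bursts(clusters)
  }
  horizon <- if (inherits(grid, "time_grid")) grid$T else as.numeric(grid)
  times <- clusters$spike_time_ms
  n <- length(times)
  if (n == 0) {
    return(tibble(n_spikes = 0L, n_clusters = 0L,
                  cluster_sizes = list(integer(0)),
                  adaptation_duration_ms = 0, first_rate_hz = 0,
                  late_rate_hz = 0, mean_rate_hz = 0, adapting = FALSE))
  }
  sizes <- as.integer(table(clusters$cluster))
  first <- times[clusters$cluster == 1]
  span <- diff(range(first))
  internal_rate <- function(ts) {
    if (length(ts) >= 2 && diff(range(ts)) > 0) {
      (length(ts) - 1) / (diff(range(ts)) / 1000)
    } else 0
  }
  first_rate <- internal_rate(first)
  last_cl <- max(clusters$cluster)
  last_times <- times[clusters$cluster == last_cl]
  late_rate <- if (last_cl > 1 && length(last_times) >= 2 &&
                     min(last_times) >= horizon / 2) {
    internal_rate(last_times)
  } else {
    sum(times >= horizon / 2) / (horizon / 2 / 1000)
  }
  adapting <- first_rate > 0 && first_rate > rate_factor * late_rate
  tibble(n_spikes = n, n_clusters = max(clusters$cluster),
         cluster_sizes = list(sizes),
         adaptation_duration_ms = span,
         first_rate_hz = first_rate, late_rate_hz = late_rate,
         mean_rate_hz = n / (horizon / 1000), adapting = adapting)
}

#' Qualitative firing-pattern label of a trace
#'
#' Classifies a simulated response as one of `"silent"` (no spikes),
#' `"bursting"` (at least two multi-spike clusters, with multi-spike
#' clusters still occurring in the late half of the horizon, as in fast
#' rhythmic bursting), `"adapting_tonic"` (an initial dense phase at least
#' twice the late rate), or `"tonic"` (anything else, e.g. regular singles).
#' Labels are invariant to a uniform time translation of the spike train.
#'
#' @param trace a `membrane_trace`, or a numeric vector of spike times (in
#'   which case `horizon_ms` is required).
#' @param gap_threshold burst gap override in ms (see [segment_bursts()]).
#' @param horizon_ms total horizon when `trace` is a bare spike-time vector.
#' @return A single character label.
#' @export
classify_pattern <- function(trace, gap_threshold = NULL, horizon_ms = NULL) {
  if (is.numeric(trace)) {
    times <- as.numeric(trace)
    horizon <- horizon_ms %||% abort("`horizon_ms` required for bare spike times.",
                                     class = "memlif_invalid_parameter")
  } else {
    times <- detect_spikes(trace)$spike_time_ms
    horizon <- attr(trace, "grid")$T
  }
  if (length(times) == 0) return("silent")
  # translation invariance: measure everything relative to the first spike
  times <- times - min(times)
  clusters <- segment_bursts(times, gap_threshold)
  sizes <- as.integer(table(clusters$cluster))
  multi <- which(sizes >= 2)
  late_multi <- any(vapply(multi, function(cl) {
    max(clusters$spike_time_ms[clusters$cluster == cl]) >= horizon / 2
  }, logical(1)))
  summary <- adaptation_metrics(clusters, horizon)
  if (length(multi) >= 2 && late_multi) return("bursting")
  if (summary$adapting) return("adapting_tonic")
  "tonic"
}

#' Export a spike train as single-column CSV
#'
#' @param spikes spike train tibble or numeric times.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_spikes_csv <- function(spikes, path) {
  write.csv(data.frame(time_ms = spike_times_of(spikes)), path,
            row.names = FALSE)
  invisible(path)
}
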