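#' Classification accuracy
#'
#' Percentage of trials whose predicted class matches the label. A
#' prediction of `NA` means the network produced no output spike in that
#' trial ("no decision"); such trials count as incorrect and their number
#' is reported separately.
#'
#' @param predictions vector of predicted class ids (`NA` = no decision).
#' @param labels true class ids, same length.
#' @return list with `accuracy_pct`, `n_correct`, `n_trials`,
#'   `n_no_decision`.
#' @export
classification_accuracy <- function(predictions, labels) {
  stopifnot(length(predictions) == length(labels))
  correct <- !is.na(predictions) & predictions == labels
  list(accuracy_pct = 100 * sum(correct) / length(labels),
       n_correct = sum(correct), n_trials = length(labels),
       n_no_decision = sum(is.na(predictions)))
}

#' Per-trial response latency
#'
#' Latency is the time from the first input-layer spike to the first
#' output-layer spike within each trial window. Windows with no output
#' spike give an undefined latency: they are excluded from the summary and
#' counted. An output spike preceding any input spike in its window yields
#' a negative latency, reported with a warning as a diagnostic rather than
#' clamped.
#'
#' @param input_spikes,output_spikes list of per-neuron spike-time vectors
#'   (ms) for the input and output layers.
#' @param trial_windows data.frame with `start_ms`, `end_ms` (disjoint).
#' @return list with `latency_ms` (per trial, `NA` where undefined),
#'   `mean_ms`, `sd_ms` (over defined trials), `n_excluded`, and
#'   `mean_all_ms` which averages with excluded trials scored at the full
#'   window length (both conventions reported).
#' @export
response_latency <- function(input_spikes, output_spikes, trial_windows) {
  t_in <- sort(unlist(input_spikes, use.names = FALSE))
  t_out <- sort(unlist(output_spikes, use.names = FALSE))
  n <- nrow(trial_windows)
  lat <- rep(NA_real_, n)
  full <- numeric(n)
  for (k in seq_len(n)) {
    a <- trial_windows$start_ms[k]; b <- trial_windows$end_ms[k]
    fi <- t_in[t_in >= a & t_in < b][1]
    fo <- t_out[t_out >= a & t_out < b][1]
    full[k] <- b - a
    if (!is.na(fi) && !is.na(fo)) lat[k] <- fo - fi
  }
  if (any(!is.na(lat) & lat < 0))
    warning("negative latency: output spike before first input spike")
  def <- lat[!is.na(lat)]
  list(latency_ms = lat,
       mean_ms = if (length(def)) mean(def) else NA_real_,
       sd_ms = if (length(def) > 1) stats::sd(def) else NA_real_,
       n_excluded = sum(is.na(lat)),
       mean_all_ms = mean(ifelse(is.na(lat), full, lat)))
}

#' Synaptic operations per biological second
#'
#' One spike transmitted through one synapse is one synaptic operation;
#' a neuron's spike therefore generates as many operations as its
#' fan-out. Sopbs is the total over all spikes divided by the biological
#' duration, and is additive over populations.
#'
#' @param spikes list of per-neuron spike-time vectors (one population).
#' @param fanout_per_neuron per-neuron outgoing synapse count (recycled if
#'   scalar).
#' @param biological_duration_s duration in biological seconds.
#' @return Sopbs (numeric).
#' @seealso [network_fanout()]
#' @export
count_sopbs <- function(spikes, fanout_per_neuron, biological_duration_s) {
  stopifnot(biological_duration_s > 0)
  fan <- rep_len(fanout_per_neuron, length(spikes))
  sum(lengths(spikes) * fan) / biological_duration_s
}

#' Reciprocal energy metrics: J/SE and Sops/W
#'
#' Energy per synaptic event and synaptic operations per second per watt
#' are reciprocal descriptions of the same measurement: with a consistent
#' triple (energy, events, power) the event rate is
#' `events / (joules / watts)` and the identity `J/SE x Sops/W = 1` holds
#' exactly.
#'
#' @param total_joules energy consumed over the run (J).
#' @param total_synaptic_events number of synaptic events (> 0).
#' @param wall_power_w mean power draw (W).
#' @return list with `j_per_se`, `sops_per_w`, and their product
#'   `identity` (1 up to floating-point rounding).
#' @export
energy_metrics <- function(total_joules, total_synaptic_events,
                           wall_power_w) {
  if (total_synaptic_events <= 0) stop("total_synaptic_events must be > 0")
  stopifnot(total_joules > 0, wall_power_w > 0)
  j_per_se <- total_joules / total_synaptic_events
  event_rate <- total_synaptic_events / (total_joules / wall_power_w)
  sops_per_w <- event_rate / wall_power_w
  list(j_per_se = j_per_se, sops_per_w = sops_per_w,
       identity = j_per_se * sops_per_w)
}

#' Benchmark metrics record
#'
#' Bundles the model-level evaluation quantities of one benchmark run:
#' classification accuracy, per-trial response latency, synaptic event
#' rate, and (optionally) the energy figures.
#'
#' @param accuracy result of [classification_accuracy()].
#' @param latency result of [response_latency()].
#' @param sopbs total synaptic operations per biological second.
#' @param input_rate_hz configured total input rate.
#' @param energy optional result of [energy_metrics()].
#' @return an object of class `snn_metrics`.
#' @export
snn_metrics <- function(accuracy, latency, sopbs, input_rate_hz,
                        energy = NULL) {
  stopifnot(accuracy$accuracy_pct >= 0, accuracy$accuracy_pct <= 100,
            sopbs >= 0)
  if (!is.null(energy) &&
      abs(energy$identity - 1) > 1e-9)
    stop("inconsistent energy metrics: J/SE x Sops/W != 1")
  structure(list(accuracy = accuracy, latency = latency, sopbs = sopbs,
                 input_rate_hz = input_rate_hz, energy = energy),
            class = "snn_metrics")
}

#' @export
print.snn_metrics <- function(x, ...) {
  cat(sprintf("SNN metrics: accuracy %.2f%% (%d/%d, %d no-decision)\n",
              x$accuracy$accuracy_pct, x$accuracy$n_correct,
              x$accuracy$n_trials, x$accuracy$n_no_decision))
  if (!is.na(x$latency$mean_ms))
    cat(sprintf("  latency %.2f ms mean (%d excluded trials)\n",
                x$latency$mean_ms, x$latency$n_excluded))
  cat(sprintf("  %.2f Sopbs at %g Hz input\n", x$sopbs, x$input_rate_hz))
  if (!is.null(x$energy))
    cat(sprintf("  %.3g J/SE, %.3g Sops/W\n", x$energy$j_per_se,
                x$energy$sops_per_w))
  invisible(x)
}

#' Serialize a benchmark report
#'
#' Writes (or returns) a structured JSON report combining the metrics with
#' the standard SNN description fields: input conversion method, network
#' topology, neuron and synapse types, training rule and times, input
#' rates. `read_report` round-trips it; `validate_report` checks the
#' required fields against the schema shipped in
#' `inst/extdata/report-schema.json`.
#'
#' @param metrics an [snn_metrics()].
#' @param model_description named list with fields `input`, `network`,
#'   `training`, `recognition` (free-form character or lists).
#' @param path optional output path; omit to get the JSON text.
#' @return `build_report`: the JSON string (invisibly if written);
#'   `read_report`: the parsed report list; `validate_report`: TRUE or an
#'   error.
#' @export
build_report <- function(metrics, model_description, path = NULL) {
  stopifnot(inherits(metrics, "snn_metrics"))
  payload <- list(
    description = model_description,
    metrics = list(
      accuracy_pct = metrics$accuracy$accuracy_pct,
      n_trials = metrics$accuracy$n_trials,
      n_no_decision = metrics$accuracy$n_no_decision,
      latency_mean_ms = metrics$latency$mean_ms,
      latency_sd_ms = metrics$latency$sd_ms,
      latency_excluded = metrics$latency$n_excluded,
      latency_mean_all_ms = metrics$latency$mean_all_ms,
      sopbs = metrics$sopbs,
      input_rate_hz = metrics$input_rate_hz))
  if (!is.null(metrics$energy))
    payload$metrics$energy <- list(j_per_se = metrics$energy$j_per_se,
                                   sops_per_w = metrics$energy$sops_per_w)
  txt <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                          null = "null", na = "null")
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' @rdname build_report
#' @export
read_report <- function(path) jsonlite::read_json(path)

#' @rdname build_report
#' @param report a parsed report (from [read_report()]).
#' @export
validate_report <- function(report) {
  schema <- jsonlite::read_json(system.file("extdata",
                                            "report-schema.json",
                                            package = "spikebench"))
  for (sect in names(schema$required)) {
    if (is.null(report[[sect]]))
      stop("report missing section '", sect, "'")
    for (fld in unlist(schema$required[[sect]]))
      if (is.null(report[[sect]][[fld]]))
        stop("report section '", sect, "' missing field '", fld, "'")
  }
  TRUE
}
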