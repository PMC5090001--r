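#' Fixed-point weight format Qm.f
#'
#' Signed fixed point with `m` integer bits (including the sign bit) and
#' `f` fractional bits: resolution `2^-f`, representable range
#' `[-2^(m-1), 2^(m-1) - 2^-f]`.
#'
#' @param m integer bits including sign (>= 1).
#' @param f fractional bits (>= 0).
#' @return a `fixed_point_format` list with derived `resolution`, `lo`,
#'   `hi`.
#' @examples
#' fmt <- fixed_point_format(3, 8)
#' fmt$hi   # 3.99609375
#' @export
fixed_point_format <- function(m, f) {
  stopifnot(m >= 1, f >= 0)
  structure(list(m = as.integer(m), f = as.integer(f),
                 resolution = 2^(-f), lo = -2^(m - 1),
                 hi = 2^(m - 1) - 2^(-f)),
            class = "fixed_point_format")
}

#' @export
print.fixed_point_format <- function(x, ...) {
  cat(sprintf("Q%d.%d: range [%g, %g], resolution %g\n", x$m, x$f,
              x$lo, x$hi, x$resolution))
  invisible(x)
}

#' Layered feed-forward weight set
#'
#' Ordered dense matrices whose shapes chain (`n0 x n1`, `n1 x n2`, ...),
#' e.g. the 784-500-500-10 deep-belief-network export. Carries a precision
#' tag (`"double"` or `"Qm.f"`).
#'
#' @param matrices list of weight matrices.
#' @param precision precision tag.
#' @return a `layered_weights` object.
#' @export
layered_weights <- function(matrices, precision = "double") {
  stopifnot(is.list(matrices), length(matrices) >= 1)
  for (i in seq_len(length(matrices) - 1))
    if (ncol(matrices[[i]]) != nrow(matrices[[i + 1]]))
      stop("layer shapes do not chain: layer ", i, " is ",
           nrow(matrices[[i]]), "x", ncol(matrices[[i]]), " but layer ",
           i + 1, " is ", nrow(matrices[[i + 1]]), "x",
           ncol(matrices[[i + 1]]))
  structure(list(matrices = matrices, precision = precision),
            class = "layered_weights")
}

#' @export
print.layered_weights <- function(x, ...) {
  dims <- c(nrow(x$matrices[[1]]),
            vapply(x$matrices, ncol, integer(1)))
  cat("Layered weights:", paste(dims, collapse = "-"),
      "architecture,", x$precision, "precision\n")
  invisible(x)
}

#' Load / save layered weights as NumPy .npy matrices
#' @param paths one `.npy` path per layer, in order.
#' @param lw a [layered_weights()].
#' @return `read_layered_weights`: a [layered_weights()].
#' @export
read_layered_weights <- function(paths) {
  layered_weights(lapply(paths, npy_load))
}

#' @rdname read_layered_weights
#' @export
write_layered_weights <- function(lw, paths) {
  stopifnot(length(paths) == length(lw$matrices))
  for (i in seq_along(paths)) npy_save(lw$matrices[[i]], paths[i])
  invisible(paths)
}

#' Quantize weights to fixed point
#'
#' Maps every entry to the representable Qm.f grid — nearest value with
#' half-to-even rounding (`round_nearest`, default) or toward zero
#' (`truncate`) — and saturates at the range ends. For non-saturating
#' entries the rounding error is at most half the resolution,
#' `2^(-f-1)`.
#'
#' @param W a [layered_weights()].
#' @param fmt a [fixed_point_format()].
#' @param mode `"round_nearest"` or `"truncate"`.
#' @return a quantized [layered_weights()] tagged `"Qm.f"`.
#' @export
quantize_weights <- function(W, fmt, mode = c("round_nearest", "truncate")) {
  mode <- match.arg(mode)
  stopifnot(inherits(W, "layered_weights"),
            inherits(fmt, "fixed_point_format"))
  qz <- function(w) {
    scaled <- w / fmt$resolution
    q <- if (mode == "round_nearest") round(scaled) else trunc(scaled)
    pmin(pmax(q * fmt$resolution, fmt$lo), fmt$hi)
  }
  layered_weights(lapply(W$matrices, qz),
                  precision = sprintf("Q%d.%d", fmt$m, fmt$f))
}

#' Run a feed-forward spiking network on a stimulus
#'
#' Builds a chain of LIF populations (delta-current synapses by default,
#' matching the deep-belief-network export convention) from the layered
#' weights, drives layer 0 with the stimulus spikes, and classifies each
#' trial window by the output neuron with the highest spike count.
#'
#' @param W a [layered_weights()]; `nrow` of the first matrix must equal
#'   the stimulus channel count.
#' @param stimulus a [spike_source_arrays()] (e.g. from
#'   [schedule_presentations()], whose windows are reused for scoring).
#' @param lif [lif_params()] for all hidden/output layers (delta-current
#'   default).
#' @param labels optional true labels (one per window) for accuracy.
#' @param class_of_output maps output neuron index (1-based) to class id
#'   (default `0:(n_out-1)`).
#' @param dt simulation step (ms).
#' @param seed seed.
#' @param duration_ms total duration; defaults to the stimulus length.
#' @return list with `predictions`, `metrics` ([snn_metrics()]; accuracy
#'   only when labels given), and the raw `record`.
#' @export
run_feedforward_snn <- function(W, stimulus,
                                lif = lif_params(synapse = "delta_current"),
                                labels = NULL, class_of_output = NULL,
                                dt = 1.0, seed = 1, duration_ms = NULL) {
  stopifnot(inherits(W, "layered_weights"),
            inherits(stimulus, "spike_source_arrays"))
  if (nrow(W$matrices[[1]]) != stimulus$n_neurons)
    stop("stimulus has ", stimulus$n_neurons, " channels but layer 0 ",
         "expects ", nrow(W$matrices[[1]]))
  if (is.null(duration_ms)) duration_ms <- stimulus$duration_ms
  n_layers <- length(W$matrices)
  net <- lif_network(dt = dt)
  net <- add_input(net, "l0", stimulus)
  for (i in seq_len(n_layers)) {
    net <- add_population(net, paste0("l", i), ncol(W$matrices[[i]]), lif)
    net <- add_projection(net, paste0("l", i - 1), paste0("l", i),
                          W$matrices[[i]])
  }
  rec <- simulate(net, seed = seed, duration_ms = duration_ms)
  out_name <- paste0("l", n_layers)
  out <- rec$spikes[[out_name]]
  windows <- presentation_windows(stimulus)
  if (is.null(windows))
    windows <- data.frame(start_ms = 0, end_ms = duration_ms)
  if (is.null(class_of_output)) class_of_output <- seq_along(out) - 1
  preds <- rep(NA_real_, nrow(windows))
  for (k in seq_len(nrow(windows))) {
    cnt <- vapply(out, function(s)
      sum(s >= windows$start_ms[k] & s < windows$end_ms[k]), numeric(1))
    if (sum(cnt) == 0) next
    preds[k] <- class_of_output[which.max(cnt)]
  }
  acc <- if (!is.null(labels)) classification_accuracy(preds, labels)
         else list(accuracy_pct = NA_real_, n_correct = NA_integer_,
                   n_trials = nrow(windows),
                   n_no_decision = sum(is.na(preds)))
  lat <- response_latency(rec$spikes$l0, out, windows)
  dur_s <- duration_ms / 1000
  sopbs <- 0
  for (i in seq_len(n_layers))
    sopbs <- sopbs + count_sopbs(rec$spikes[[paste0("l", i - 1)]],
                                 ncol(W$matrices[[i]]), dur_s)
  sopbs <- sopbs + count_sopbs(out, 1, dur_s)
  metrics <- if (!is.null(labels))
    snn_metrics(acc, lat, sopbs, input_rate_hz = NA_real_)
  else list(accuracy = acc, latency = lat, sopbs = sopbs)
  list(predictions = preds, metrics = metrics, record = rec)
}

#' Accuracy sweep over weight precision and input rate
#'
#' Quantizes the weights to each format, re-runs the feed-forward network
#' at each input rate, and tabulates classification accuracy — the
#' standard picture of how far weight precision can be reduced before the
#' spiking network's accuracy degrades.
#'
#' @param W a [layered_weights()] (double precision).
#' @param formats list of [fixed_point_format()]s; the string `"double"`
#'   may be included to carry the unquantized baseline.
#' @param images,labels evaluation set.
#' @param rates_hz input total-rate values to sweep.
#' @param t_on_ms,t_blank_ms presentation schedule per image.
#' @param lif,dt,seed forwarded to [run_feedforward_snn()].
#' @param class_of_output see [run_feedforward_snn()].
#' @return data.frame with one row per (format, rate): `precision`,
#'   `rate_hz`, `accuracy_pct`, `n_no_decision`, `max_abs_dw` (largest
#'   quantization change, NA for double).
#' @export
precision_sweep <- function(W, formats, images, labels, rates_hz,
                            t_on_ms = 200, t_blank_ms = 100,
                            lif = lif_params(synapse = "delta_current"),
                            dt = 1.0, seed = 1, class_of_output = NULL) {
  rows <- list()
  for (fmt in formats) {
    if (identical(fmt, "double")) {
      Wq <- W; tag <- "double"; dw <- NA_real_
    } else {
      Wq <- quantize_weights(W, fmt)
      tag <- Wq$precision
      dw <- max(mapply(function(a, b) max(abs(a - b)),
                       W$matrices, Wq$matrices))
    }
    for (r in rates_hz) {
      sched <- presentation_schedule(t_on_ms, t_blank_ms, length(images))
      stim <- schedule_presentations(images, r, sched, seed)
      res <- run_feedforward_snn(Wq, stim, lif = lif, labels = labels,
                                 class_of_output = class_of_output,
                                 dt = dt, seed = seed)
      rows[[length(rows) + 1L]] <- data.frame(
        precision = tag, rate_hz = r,
        accuracy_pct = res$metrics$accuracy$accuracy_pct,
        n_no_decision = res$metrics$accuracy$n_no_decision,
        max_abs_dw = dw)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Train a synthetic surrogate for an externally trained network
#'
#' The published deep-belief-network weights are external artifacts this
#' package only loads; for offline testing it ships this conventionally
#' trained surrogate instead. Layer 1 holds matched-filter templates
#' (k-means sub-centroids of each class, several per class); layer 2
#' pools each class's templates with random positive weights; the readout
#' pools the class units. Layer drives are calibrated against the leak
#' rate at threshold — layer 1 analytically from the input rate, deeper
#' layers from hidden rates measured by actually simulating the spiking
#' stack — so every layer stays in its stimulus-dependent regime and all
#' weights land inside the low-precision fixed-point range. Clearly
#' synthetic: it emulates the *shape* of an offline-trained export
#' (chained non-negative matrices, delta synapses, argmax readout), not
#' its accuracy on real handwriting.
#'
#' @param images,labels training images (synthetic digit fixtures).
#' @param hidden sizes of the two hidden layers; `hidden[1]` is rounded
#'   to a multiple of the class count (templates per class), `hidden[2]`
#'   likewise (pool units per class).
#' @param classes class ids in output-neuron order.
#' @param rate_hz input rate used for the calibration runs.
#' @param t_on_ms calibration presentation length per image.
#' @param lif,dt,seed simulation settings.
#' @param drive_gain target mean depolarization drive of each layer in
#'   units of the leak rate at threshold
#'   `(v_thresh - v_rest) / tau_m`; values just above 1 keep neurons
#'   responsive without saturating.
#' @return a [layered_weights()] with 3 matrices
#'   (`n_px - h1 - h2 - n_classes`).
#' @export
surrogate_dbn_weights <- function(images, labels, hidden = c(24, 6),
                                  classes = sort(unique(labels)),
                                  rate_hz = 2000, t_on_ms = 300,
                                  lif = lif_params(synapse =
                                                     "delta_current"),
                                  dt = 1.0, seed = 1, drive_gain = 2) {
  n_px <- length(images[[1]])
  n_cls <- length(classes)
  k1 <- max(1L, round(hidden[1] / n_cls))   # templates per class
  k2 <- max(1L, round(hidden[2] / n_cls))   # pool units per class
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
    globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  leak_rate <- (lif$v_thresh - lif$v_rest) / (lif$tau_m / 1000)  # mV/s
  # layer 1: k-means sub-centroid matched filters, near-threshold drive
  part <- kmeans_subclasses(images, labels, K = k1, seed = seed)
  m1 <- apply(part$centroids, 2, function(v) v / max(sum(v), 1e-9))
  # scale so the mean matching-template drive is drive_gain x leak;
  # the drive is linear in the rates, so calibrate it analytically
  X <- t(vapply(images, function(im) {
    v <- as.vector(t(im)); rate_hz * v / max(sum(v), 1e-9)
  }, numeric(n_px)))
  D <- (X %*% m1) / lif$c_m                     # mV/s, images x templates
  match_cols <- t(vapply(match(labels, classes), function(ci)
    as.integer((ci - 1) * k1 + seq_len(k1)), integer(k1)))
  d_match <- mean(D[cbind(rep(seq_along(images), k1),
                          as.vector(match_cols))])
  m1 <- m1 * drive_gain * leak_rate / max(d_match, 1e-9)
  sched <- presentation_schedule(t_on_ms, 0, length(images))
  stim <- schedule_presentations(images, rate_hz, sched, seed)
  net <- lif_network(dt = dt)
  net <- add_input(net, "l0", stim)
  net <- add_population(net, "l1", ncol(m1), lif)
  net <- add_projection(net, "l0", "l1", m1)
  rec <- simulate(net, seed = seed, duration_ms = stim$duration_ms)
  r1 <- sum(lengths(rec$spikes$l1)) / (stim$duration_ms / 1000)
  # layer 2: positive random pooling of each class's templates
  set.seed(substream_seed(seed, 4242L), kind = "Mersenne-Twister",
           normal.kind = "Inversion")
  m2 <- matrix(0, ncol(m1), n_cls * k2)
  for (c in seq_len(n_cls)) {
    rows <- (c - 1) * k1 + seq_len(k1)
    for (j in seq_len(k2))
      m2[rows, (c - 1) * k2 + j] <- 0.5 + stats::runif(k1)
  }
  m2 <- sweep(m2, 2, pmax(colSums(m2), 1e-9), "/") *
    drive_gain * leak_rate * lif$c_m * ncol(m1) / max(r1, 1)
  net <- add_population(net, "l2", ncol(m2), lif)
  net <- add_projection(net, "l1", "l2", m2)
  rec <- simulate(net, seed = seed, duration_ms = stim$duration_ms)
  r2 <- sum(lengths(rec$spikes$l2)) / (stim$duration_ms / 1000)
  # readout: pool the class units
  B <- matrix(0, ncol(m2), n_cls)
  for (c in seq_len(n_cls))
    B[(c - 1) * k2 + seq_len(k2), c] <- 1
  B <- sweep(B, 2, pmax(colSums(B), 1e-9), "/") *
    drive_gain * leak_rate * lif$c_m * ncol(m2) / max(r2, 1)
  layered_weights(list(m1, m2, B))
}
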