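#' Linear intensity-to-rate map with total-rate normalization
#'
#' Assigns each pixel a firing rate proportional to its intensity, with the
#' summed rate over all pixels normalized to `total_rate_hz`. This is the
#' rate-coding front end of the benchmark protocols: 2000 Hz total during
#' template training, 5000 Hz during testing sweeps.
#'
#' @param image 2-d matrix of non-negative intensities (8-bit values used
#'   as-is; no gamma correction).
#' @param total_rate_hz positive normalization target in Hz.
#' @return an object of class `rate_map`: list with `rates_hz` (matrix, same
#'   shape as `image`) and `total_rate_hz`.
#' @examples
#' img <- matrix(0, 28, 28); img[14, 14] <- 255
#' r <- intensity_to_rates(img, 2000)
#' sum(r$rates_hz)  # 2000
#' @export
intensity_to_rates <- function(image, total_rate_hz) {
  stopifnot(is.matrix(image), total_rate_hz > 0)
  if (any(image < 0)) stop("negative pixel intensity")
  s <- sum(image)
  if (s == 0) {
    warning("all-zero image: rate map is all zero")
    rates <- image * 0
  } else {
    rates <- total_rate_hz * image / s
  }
  structure(list(rates_hz = rates, total_rate_hz = total_rate_hz),
            class = "rate_map")
}

#' @export
print.rate_map <- function(x, ...) {
  cat("Rate map:", nrow(x$rates_hz), "x", ncol(x$rates_hz),
      "pixels, total", sum(x$rates_hz), "Hz\n")
  invisible(x)
}

# deterministic substream seed for (master, image, neuron); stays < 2^31
substream_seed <- function(master, image = 0L, neuron = 0L) {
  h <- (as.double(master) * 2654435761 + as.double(image) * 40503 +
        as.double(neuron) * 2246822519) %% 2147483629
  as.integer(h)
}

# one homogeneous Poisson train on [0, duration_ms) via exponential
# inter-arrival sampling (timestep-free)
poisson_train <- function(rate_hz, duration_ms) {
  if (rate_hz <= 0) return(numeric())
  mean_isi <- 1000 / rate_hz
  expect <- duration_ms / mean_isi
  times <- numeric()
  t_last <- 0
  repeat {
    k <- max(16L, ceiling(1.5 * (expect - length(times)) +
                            4 * sqrt(expect + 1)))
    times <- c(times, t_last + cumsum(stats::rexp(k, rate = 1 / mean_isi)))
    t_last <- times[length(times)]
    if (t_last >= duration_ms) break
  }
  times[times < duration_ms]
}

#' Generate Poisson spike trains from a rate map
#'
#' Each pixel becomes an independent homogeneous Poisson process at its
#' mapped rate, sampled by exponential inter-arrival times so the trains do
#' not depend on any simulator timestep. A master seed spawns one
#' independent substream per neuron (and per image offset), so any neuron's
#' train can be regenerated in isolation.
#'
#' @param rates a [intensity_to_rates()] `rate_map`.
#' @param duration_ms stimulus duration (> 0).
#' @param seed master seed (integer).
#' @param image_index substream index used when encoding many images.
#' @return a [spike_source_arrays()] with row-major neuron indexing
#'   (neuron `id = row * ncol + col`, 0-based, top-left origin).
#' @export
generate_poisson <- function(rates, duration_ms, seed, image_index = 0L) {
  stopifnot(inherits(rates, "rate_map"), duration_ms > 0)
  r <- as.vector(t(rates$rates_hz))    # row-major neuron order
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
    globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  spikes <- vector("list", length(r))
  for (i in seq_along(r)) {
    if (r[i] <= 0) { spikes[[i]] <- numeric(); next }
    set.seed(substream_seed(seed, image_index, i - 1L),
             kind = "Mersenne-Twister", normal.kind = "Inversion")
    spikes[[i]] <- poisson_train(r[i], duration_ms)
  }
  spike_source_arrays(spikes, n_neurons = length(r),
                      duration_ms = duration_ms, channel = "merged")
}

#' Stimulus presentation schedule
#'
#' @param t_on_ms per-image stimulus duration in ms (default 1000, the
#'   protocol's 1 s presentation).
#' @param t_blank_ms silent gap between images (default 200).
#' @param n_images number of images.
#' @return a `presentation_schedule` list.
#' @export
presentation_schedule <- function(t_on_ms = 1000, t_blank_ms = 200,
                                  n_images = 1L) {
  stopifnot(t_on_ms > 0, t_blank_ms >= 0, n_images >= 1)
  structure(list(t_on_ms = t_on_ms, t_blank_ms = t_blank_ms,
                 n_images = as.integer(n_images)),
            class = "presentation_schedule")
}

#' Encode a sequence of images as scheduled Poisson input
#'
#' Image `k` (1-based) is Poisson-encoded over the window
#' `[(k-1) * (t_on + t_blank), (k-1) * (t_on + t_blank) + t_on)`; the blank
#' periods are silent. The per-image on-windows are attached as the
#' `"windows"` attribute (a data.frame with `start_ms`, `end_ms`) for
#' downstream scoring, retrievable with [presentation_windows()].
#'
#' @param images list of intensity matrices (all the same shape).
#' @param total_rate_hz per-image total-rate normalization.
#' @param schedule a [presentation_schedule()]; `n_images` must match.
#' @param seed master seed.
#' @return a [spike_source_arrays()] spanning all presentations.
#' @export
schedule_presentations <- function(images, total_rate_hz, schedule, seed) {
  stopifnot(inherits(schedule, "presentation_schedule"),
            length(images) == schedule$n_images)
  period <- schedule$t_on_ms + schedule$t_blank_ms
  n_px <- length(images[[1]])
  spikes <- rep(list(numeric()), n_px)
  starts <- (seq_along(images) - 1) * period
  for (k in seq_along(images)) {
    seg <- generate_poisson(intensity_to_rates(images[[k]], total_rate_hz),
                            duration_ms = schedule$t_on_ms, seed = seed,
                            image_index = k - 1L)
    for (i in seq_len(n_px))
      if (length(seg$spikes[[i]]))
        spikes[[i]] <- c(spikes[[i]], seg$spikes[[i]] + starts[k])
  }
  out <- spike_source_arrays(spikes, n_neurons = n_px,
                             duration_ms = schedule$n_images * period,
                             channel = "merged")
  attr(out, "windows") <- data.frame(start_ms = starts,
                                     end_ms = starts + schedule$t_on_ms)
  out
}

#' @rdname schedule_presentations
#' @param arrays a spike set produced by `schedule_presentations`.
#' @export
presentation_windows <- function(arrays) attr(arrays, "windows")
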