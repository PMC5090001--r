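#' Partition a labelled image set into per-digit subclasses
#'
#' Runs k-means (Euclidean metric, raw pixel vectors) separately inside
#' each digit class, splitting it into `K` subclasses; each subclass gets
#' its own decision neuron, so a digit is represented by `K` slightly
#' different templates. Deterministic under the seed.
#'
#' @param images list of intensity matrices.
#' @param labels digit labels (one per image).
#' @param K subclasses per digit (default 10, giving the standard
#'   `10 * K` decision neurons for the full digit set).
#' @param seed seed for the k-means starts.
#' @return a `subclass_partition`: `classes` (sorted digits), `K`,
#'   `subclass` (1..K per image), `neuron` (1-based decision neuron per
#'   image), `decision_digit` (digit of each decision neuron), and
#'   `centroids` (one pixel-vector matrix column per decision neuron).
#' @export
kmeans_subclasses <- function(images, labels, K = 10, seed = 1) {
  stopifnot(length(images) == length(labels), K >= 1)
  classes <- sort(unique(labels))
  # row-major pixel order, matching the spike encoders' neuron indexing
  x <- t(vapply(images, function(im) as.vector(t(im)),
                numeric(length(images[[1]]))))
  subclass <- integer(length(labels))
  cents <- matrix(0, ncol(x), length(classes) * K)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
    globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  for (ci in seq_along(classes)) {
    idx <- which(labels == classes[ci])
    if (length(idx) == 0L) stop("empty digit class ", classes[ci])
    if (length(idx) < K)
      stop("digit class ", classes[ci], " has ", length(idx),
           " images, fewer than K = ", K)
    set.seed(substream_seed(seed, ci), kind = "Mersenne-Twister",
             normal.kind = "Inversion")
    if (K == 1L) {
      subclass[idx] <- 1L
      cents[, (ci - 1) * K + 1] <- colMeans(x[idx, , drop = FALSE])
    } else if (length(idx) == K) {
      # one image per subclass: the partition is forced
      subclass[idx] <- seq_len(K)
      cents[, (ci - 1) * K + seq_len(K)] <- t(x[idx, , drop = FALSE])
    } else {
      km <- stats::kmeans(x[idx, , drop = FALSE], centers = K,
                          nstart = 5, iter.max = 50)
      # stable subclass numbering: order centers by their first principal
      # coordinate sum so the labelling does not depend on start order
      o <- order(rowSums(km$centers))
      relab <- match(seq_len(K), o)
      subclass[idx] <- relab[km$cluster]
      cents[, (ci - 1) * K + seq_len(K)] <- t(km$centers[o, , drop = FALSE])
    }
  }
  neuron <- (match(labels, classes) - 1L) * K + subclass
  structure(list(classes = classes, K = as.integer(K),
                 subclass = subclass, neuron = neuron,
                 decision_digit = rep(classes, each = K),
                 centroids = cents,
                 img_dim = dim(images[[1]])),
            class = "subclass_partition")
}

#' @export
print.subclass_partition <- function(x, ...) {
  cat("Subclass partition:", length(x$classes), "digits x", x$K,
      "subclasses =", length(x$decision_digit), "decision neurons\n")
  invisible(x)
}

#' Template weight matrix
#'
#' The `n_pixels x n_decision` synaptic weight matrix of the two-layer
#' classifier. In the training phase all entries are non-negative and
#' plastic; [weak_to_inhibitory()] converts it to the testing phase, where
#' each input neuron carries one excitatory and one inhibitory projection
#' value per decision neuron.
#'
#' @param W weight matrix (`n_pixels x n_decision`).
#' @param decision_digit digit represented by each column.
#' @param phase `"training"` or `"testing"`.
#' @param w_max plastic weight ceiling the matrix was trained under.
#' @param provenance free-form list (seed, protocol) carried along.
#' @return a `template_weights` object.
#' @export
template_weights <- function(W, decision_digit, phase = "training",
                             w_max = max(W), provenance = list()) {
  W <- as.matrix(W)
  stopifnot(ncol(W) == length(decision_digit),
            phase %in% c("training", "testing"))
  if (phase == "training" && any(W < 0))
    stop("training-phase template weights must be non-negative")
  structure(list(W = W, decision_digit = decision_digit, phase = phase,
                 w_max = w_max, provenance = provenance),
            class = "template_weights")
}

#' @export
print.template_weights <- function(x, ...) {
  cat(sprintf("Template weights: %d x %d (%s phase)\n", nrow(x$W),
              ncol(x$W), x$phase))
  invisible(x)
}

#' Train subclass templates with STDP and a teaching signal
#'
#' Each decision neuron is trained independently on the images of its own
#' subclass: an image is Poisson-encoded (total rate normalized to the
#' training default 2000 Hz) and presented for about 300 ms while a 50 Hz
#' suprathreshold teaching signal forces the neuron to fire; the pair-based
#' STDP rule (hard floor at 0) then potentiates the synapses of pixels
#' active just before the forced spikes, embedding the subclass template
#' in the 784 afferent weights. Weight updates are applied at presentation
#' boundaries.
#'
#' @param partition a [kmeans_subclasses()] partition.
#' @param images,labels the training set the partition was built from.
#' @param protocol list with `per_image_ms` (300), `total_rate_hz` (2000),
#'   `teach_rate_hz` (50).
#' @param lif decision-neuron [lif_params()].
#' @param stdp an [stdp_params()].
#' @param dt simulation step (ms).
#' @param seed master seed (initial weights, Poisson encoding, teaching).
#' @param shuffle present each subclass's images in a seeded random order
#'   (the protocol does not fix an order).
#' @return a training-phase [template_weights()].
#' @export
train_case1 <- function(partition, images, labels,
                        protocol = list(per_image_ms = 300,
                                        total_rate_hz = 2000,
                                        teach_rate_hz = 50),
                        lif = lif_params(), stdp = stdp_params(),
                        dt = 0.1, seed = 1, shuffle = TRUE) {
  stopifnot(inherits(partition, "subclass_partition"),
            length(images) == length(partition$neuron))
  n_px <- prod(partition$img_dim)
  n_dec <- length(partition$decision_digit)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
    globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(substream_seed(seed, 9999L), kind = "Mersenne-Twister",
           normal.kind = "Inversion")
  W <- matrix(stats::runif(n_px * n_dec, 0, 0.05 * stdp$w_max), n_px, n_dec)
  for (d in seq_len(n_dec)) {
    imgs_d <- which(partition$neuron == d)
    if (shuffle) imgs_d <- sample(imgs_d)
    w <- W[, d]
    for (ii in seq_along(imgs_d)) {
      img <- images[[imgs_d[ii]]]
      stim <- generate_poisson(
        intensity_to_rates(img, protocol$total_rate_hz),
        duration_ms = protocol$per_image_ms, seed = seed,
        image_index = imgs_d[ii])
      net <- lif_network(dt = dt)
      net <- add_input(net, "in", stim)
      net <- add_population(net, "dec", 1L, lif)
      net <- add_projection(net, "in", "dec", matrix(w, ncol = 1),
                            plastic = TRUE)
      if (protocol$teach_rate_hz > 0)
        net <- attach_teaching_signal(net, "dec", 1L,
                                      rate_hz = protocol$teach_rate_hz)
      rec <- simulate(net, seed = substream_seed(seed, d, ii),
                      duration_ms = protocol$per_image_ms)
      post <- rec$spikes$dec[[1]]
      if (length(post)) {
        for (i in which(lengths(stim$spikes) > 0)) {
          w[i] <- stdp_update(stim$spikes[[i]], post, w[i], stdp)
        }
      }
    }
    W[, d] <- w
  }
  template_weights(W, partition$decision_digit, phase = "training",
                   w_max = stdp$w_max,
                   provenance = list(seed = seed, protocol = protocol,
                                     method = "stdp"))
}

#' Build centroid-derived template weights
#'
#' A non-plastic shortcut to a training-phase weight matrix: each decision
#' neuron's afferent weights are its subclass k-means centroid scaled to
#' peak at `w_max`. Useful for protocol-level experiments (event
#' accounting, latency sweeps) where the template structure matters but a
#' full STDP run is not the quantity under study.
#'
#' @param partition a [kmeans_subclasses()] partition.
#' @param w_max peak weight.
#' @return a training-phase [template_weights()].
#' @export
centroid_templates <- function(partition, w_max = 1) {
  stopifnot(inherits(partition, "subclass_partition"))
  W <- apply(partition$centroids, 2, function(v) {
    if (max(v) > 0) w_max * v / max(v) else v * 0
  })
  template_weights(W, partition$decision_digit, phase = "training",
                   w_max = w_max,
                   provenance = list(method = "centroid"))
}

#' Convert weak weights to inhibitory and freeze for testing
#'
#' After training, plasticity is frozen and every weight below the weak
#' threshold is replaced by one fixed negative value (identical strength
#' for all converted synapses), giving each input neuron an excitatory or
#' inhibitory projection to every decision neuron. Defaults: threshold =
#' 10% of `w_max`; inhibitory magnitude = the mean of the replaced
#' weights.
#'
#' @param tw a training-phase [template_weights()].
#' @param weak_threshold weights strictly below this are converted.
#' @param inhibitory_value magnitude of the replacement (made negative).
#' @return a testing-phase [template_weights()].
#' @export
weak_to_inhibitory <- function(tw, weak_threshold = 0.1 * tw$w_max,
                               inhibitory_value = NULL) {
  stopifnot(inherits(tw, "template_weights"))
  if (tw$phase != "training") stop("weights are already in testing phase")
  W <- tw$W
  weak <- W < weak_threshold
  if (is.null(inhibitory_value))
    inhibitory_value <- if (any(weak)) mean(W[weak]) else 0
  W[weak] <- -abs(inhibitory_value)
  template_weights(W, tw$decision_digit, phase = "testing",
                   w_max = tw$w_max,
                   provenance = c(tw$provenance,
                                  list(weak_threshold = weak_threshold,
                                       inhibitory_value = inhibitory_value,
                                       n_inhibitory = sum(weak))))
}

#' Scale template weights
#'
#' Elementwise multiplication (the "x10 stronger weights" variant of the
#' testing protocol); sign pattern and phase are preserved.
#'
#' @param tw a [template_weights()].
#' @param factor scale factor (default 10).
#' @return scaled [template_weights()].
#' @export
scale_weights <- function(tw, factor = 10) {
  stopifnot(inherits(tw, "template_weights"))
  template_weights(tw$W * factor, tw$decision_digit, phase = tw$phase,
                   w_max = tw$w_max * max(factor, 1),
                   provenance = c(tw$provenance, list(scale = factor)))
}

#' Run the max-rate testing protocol
#'
#' Test images are Poisson-encoded (5000 Hz total by default) and
#' presented on the 1 s / 0.2 s-blank schedule to the frozen network: each
#' input neuron drives every decision neuron through an excitatory and an
#' inhibitory projection (split from the signed testing-phase matrix), so
#' each input spike generates `2 * n_decision` inter-layer synaptic
#' events. The decision neuron with the highest spike count inside each
#' on-window predicts the digit; exact ties go to the lowest neuron index
#' (and are counted), or to a seeded random choice with
#' `tie_break = "random"`. Trials with no output spike are flagged "no
#' decision" (NA) and count as errors. Output spikes in blank windows are
#' ignored for classification but enter the synaptic-event total; event
#' rates average over the full duty cycle.
#'
#' @param tw a testing-phase [template_weights()].
#' @param test_images,labels the test set.
#' @param schedule a [presentation_schedule()] (defaults to
#'   1000 ms / 200 ms x n images).
#' @param total_rate_hz per-image input normalization (5000 default).
#' @param lif decision-neuron [lif_params()].
#' @param dt simulation step (1 ms default for throughput).
#' @param seed master seed.
#' @param tie_break `"lowest"` or `"random"`.
#' @return list with `predictions` (digit or NA per image), `metrics`
#'   (an [snn_metrics()]), `n_ties`, and the raw `record`.
#' @export
test_case1 <- function(tw, test_images, labels, schedule = NULL,
                       total_rate_hz = 5000, lif = lif_params(),
                       dt = 1.0, seed = 1,
                       tie_break = c("lowest", "random")) {
  tie_break <- match.arg(tie_break)
  stopifnot(inherits(tw, "template_weights"))
  if (tw$phase != "testing")
    stop("testing requires testing-phase weights; run weak_to_inhibitory()")
  if (is.null(schedule))
    schedule <- presentation_schedule(1000, 200, length(test_images))
  stim <- schedule_presentations(test_images, total_rate_hz, schedule, seed)
  windows <- presentation_windows(stim)
  n_dec <- ncol(tw$W)
  net <- lif_network(dt = dt)
  net <- add_input(net, "in", stim)
  net <- add_population(net, "dec", n_dec, lif)
  net <- add_projection(net, "in", "dec", pmax(tw$W, 0))   # excitatory
  net <- add_projection(net, "in", "dec", pmin(tw$W, 0))   # inhibitory
  rec <- simulate(net, seed = seed, duration_ms = stim$duration_ms)
  out <- rec$spikes$dec
  preds <- rep(NA_real_, length(test_images))
  n_ties <- 0L
  if (tie_break == "random") {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
      globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(substream_seed(seed, 777L))
  }
  for (k in seq_len(nrow(windows))) {
    cnt <- vapply(out, function(s)
      sum(s >= windows$start_ms[k] & s < windows$end_ms[k]), numeric(1))
    if (sum(cnt) == 0) next
    top <- which(cnt == max(cnt))
    if (length(top) > 1L) {
      n_ties <- n_ties + 1L
      top <- if (tie_break == "random") sample(top, 1L) else top[1L]
    }
    preds[k] <- tw$decision_digit[top[1L]]
  }
  acc <- classification_accuracy(preds, labels)
  lat <- response_latency(rec$spikes$`in`, out, windows)
  dur_s <- stim$duration_ms / 1000
  sopbs <- count_sopbs(rec$spikes$`in`, 2 * n_dec, dur_s) +
    count_sopbs(out, 1, dur_s)   # output spikes count one event each
  metrics <- snn_metrics(acc, lat, sopbs, input_rate_hz = total_rate_hz)
  list(predictions = preds, metrics = metrics, n_ties = n_ties,
       record = rec)
}
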