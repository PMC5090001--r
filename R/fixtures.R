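# Stroke glyphs: seven-segment-style polylines in the unit box (y down),
# rendered with a soft pen. Deliberately synthetic - digit-like statistics
# (dark background, bright connected strokes, 28 x 28) without shipping or
# downloading any real handwriting.
segment_coords <- list(
  A = c(0.2, 0.15, 0.8, 0.15), B = c(0.8, 0.15, 0.8, 0.5),
  C = c(0.8, 0.5, 0.8, 0.85),  D = c(0.2, 0.85, 0.8, 0.85),
  E = c(0.2, 0.5, 0.2, 0.85),  F = c(0.2, 0.15, 0.2, 0.5),
  G = c(0.2, 0.5, 0.8, 0.5))

digit_segments <- list(
  `0` = c("A", "B", "C", "D", "E", "F"), `1` = c("B", "C"),
  `2` = c("A", "B", "G", "E", "D"), `3` = c("A", "B", "G", "C", "D"),
  `4` = c("F", "G", "B", "C"), `5` = c("A", "F", "G", "C", "D"),
  `6` = c("A", "F", "G", "E", "C", "D"), `7` = c("A", "B", "C"),
  `8` = c("A", "B", "C", "D", "E", "F", "G"),
  `9` = c("A", "B", "C", "D", "F", "G"))

render_glyph <- function(digit, size = 28L, rot = 0, shift = c(0, 0),
                         scale = 1, pen = 1.0) {
  img <- matrix(0, size, size)
  segs <- digit_segments[[as.character(digit)]]
  ctr <- (size + 1) / 2
  span <- size * 0.72
  for (s in segs) {
    co <- segment_coords[[s]]
    p1 <- (c(co[1], co[2]) - 0.5) * scale
    p2 <- (c(co[3], co[4]) - 0.5) * scale
    R <- matrix(c(cos(rot), sin(rot), -sin(rot), cos(rot)), 2)
    p1 <- R %*% p1; p2 <- R %*% p2
    a <- c(ctr, ctr) + span * p1 + shift
    b <- c(ctr, ctr) + span * p2 + shift
    n_pts <- max(2L, ceiling(sqrt(sum((b - a)^2)) * 3))
    for (i in seq_len(n_pts)) {
      q <- a + (b - a) * (i - 1) / (n_pts - 1)
      x0 <- max(1L, floor(q[1] - 3)); x1 <- min(size, ceiling(q[1] + 3))
      y0 <- max(1L, floor(q[2] - 3)); y1 <- min(size, ceiling(q[2] + 3))
      if (x0 > x1 || y0 > y1) next
      xs <- x0:x1; ys <- y0:y1
      d2 <- outer((ys - q[2])^2, (xs - q[1])^2, "+")
      img[ys, xs] <- pmax(img[ys, xs], 255 * exp(-d2 / (2 * pen^2)))
    }
  }
  img
}

# held-out linear probe of separability: one-vs-all ridge regression on
# raw pixels, argmax readout
linear_probe_accuracy <- function(images, labels, train_frac = 0.5) {
  x <- t(vapply(images, as.vector, numeric(length(images[[1]])))) / 255
  cls <- sort(unique(labels))
  idx_tr <- unlist(lapply(cls, function(cl) {
    ii <- which(labels == cl)
    ii[seq_len(max(1L, floor(length(ii) * train_frac)))]
  }))
  idx_te <- setdiff(seq_along(labels), idx_tr)
  if (!length(idx_te)) return(NA_real_)
  xtr <- x[idx_tr, , drop = FALSE]
  Y <- outer(labels[idx_tr], cls, "==") * 1
  B <- solve(crossprod(xtr) + diag(1, ncol(x)), crossprod(xtr, Y))
  pred <- cls[max.col(x[idx_te, , drop = FALSE] %*% B)]
  mean(pred == labels[idx_te])
}

#' Generate a synthetic digit-like image set
#'
#' Renders per-class stroke glyphs (seven-segment-style polylines) at
#' 28 x 28 with per-image affine jitter (rotation, translation, scale) and
#' additive pixel noise: dark background, bright strokes, deterministic
#' under the seed. At generation the set is checked with a held-out
#' one-vs-all ridge linear probe; a probe accuracy below 95% (classes not
#' separable at the configured jitter/noise) raises a warning.
#'
#' @param n_per_class images per class.
#' @param classes class ids, a subset of `0:9` (at least 2).
#' @param jitter affine jitter scale: translation sd in px, rotation sd
#'   `0.03 * jitter` rad, scale sd `0.02 * jitter`.
#' @param noise additive noise sd on the 0-255 intensity scale.
#' @param seed master seed.
#' @param size image side length (28 canonical).
#' @return a `synthetic_digits` list: `images` (list of matrices),
#'   `labels`, `probe_accuracy`, and the generator parameters.
#' @export
generate_digits <- function(n_per_class, classes = 0:2, jitter = 1,
                            noise = 8, seed = 1, size = 28L) {
  stopifnot(length(classes) >= 2, all(classes %in% 0:9))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
    globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  images <- list(); labels <- integer()
  k <- 0L
  for (cl in classes) {
    for (j in seq_len(n_per_class)) {
      k <- k + 1L
      set.seed(substream_seed(seed, cl, j), kind = "Mersenne-Twister",
               normal.kind = "Inversion")
      rot <- stats::rnorm(1, 0, 0.03 * jitter)
      shift <- stats::rnorm(2, 0, jitter)
      scale <- max(0.5, stats::rnorm(1, 1, 0.02 * jitter))
      img <- render_glyph(cl, size = size, rot = rot, shift = shift,
                          scale = scale)
      if (noise > 0)
        img <- img + matrix(stats::rnorm(size * size, 0, noise), size)
      images[[k]] <- pmin(pmax(round(img), 0), 255)
      labels[k] <- cl
    }
  }
  probe <- if (n_per_class >= 2) linear_probe_accuracy(images, labels)
           else NA_real_
  if (!is.na(probe) && probe < 0.95)
    warning(sprintf(
      "linear probe accuracy %.1f%% < 95%%: classes not separable at this
 jitter/noise", 100 * probe))
  structure(list(images = images, labels = labels, probe_accuracy = probe,
                 params = list(n_per_class = n_per_class, classes = classes,
                               jitter = jitter, noise = noise, seed = seed,
                               size = size)),
            class = "synthetic_digits")
}

#' @export
print.synthetic_digits <- function(x, ...) {
  cat("Synthetic digit set:", length(x$images), "images,",
      length(unique(x$labels)), "classes",
      if (!is.na(x$probe_accuracy))
        sprintf("(probe %.1f%%)", 100 * x$probe_accuracy) else "", "\n")
  invisible(x)
}

#' Read / write MNIST IDX files
#'
#' `load_mnist_idx` decodes the IDX image/label container (big-endian,
#' magic `0x00000803` for images, `0x00000801` for labels) into 28 x 28
#' intensity matrices and integer labels; counts must agree between the
#' two files. `write_mnist_idx` is the inverse, mainly for fixture
#' construction. No MNIST bytes ship with the package: pass paths to a
#' locally downloaded (and gunzipped) copy to run the full-scale
#' benchmark recipes.
#'
#' @param images_path,labels_path IDX file paths.
#' @return list with `images` (list of matrices, row-major pixel order
#'   preserved) and `labels`.
#' @export
load_mnist_idx <- function(images_path, labels_path) {
  con <- file(images_path, "rb"); on.exit(close(con))
  magic <- readBin(con, "integer", 1, size = 4, endian = "big")
  if (magic != 0x00000803L)
    stop("bad IDX image magic number: ", magic)
  hdr <- readBin(con, "integer", 3, size = 4, endian = "big")
  n <- hdr[1]; nr <- hdr[2]; nc <- hdr[3]
  px <- readBin(con, "integer", n * nr * nc, size = 1, signed = FALSE)
  if (length(px) < n * nr * nc) stop("truncated IDX image file")
  con2 <- file(labels_path, "rb"); on.exit(close(con2), add = TRUE)
  magic2 <- readBin(con2, "integer", 1, size = 4, endian = "big")
  if (magic2 != 0x00000801L)
    stop("bad IDX label magic number: ", magic2)
  n2 <- readBin(con2, "integer", 1, size = 4, endian = "big")
  if (n2 != n)
    stop("image/label count mismatch: ", n, " images vs ", n2, " labels")
  labels <- readBin(con2, "integer", n, size = 1, signed = FALSE)
  images <- lapply(seq_len(n), function(i) {
    m <- px[((i - 1) * nr * nc + 1):(i * nr * nc)]
    t(matrix(m, nc, nr))   # stored row-major
  })
  list(images = images, labels = labels)
}

#' @rdname load_mnist_idx
#' @param images list of equal-sized intensity matrices (0-255).
#' @param labels integer labels.
#' @export
write_mnist_idx <- function(images, labels, images_path, labels_path) {
  stopifnot(length(images) == length(labels))
  nr <- nrow(images[[1]]); nc <- ncol(images[[1]])
  con <- file(images_path, "wb")
  writeBin(c(0x00000803L, length(images), nr, nc), con, size = 4,
           endian = "big")
  for (img in images)
    writeBin(as.integer(as.vector(t(img))), con, size = 1)
  close(con)
  con2 <- file(labels_path, "wb")
  writeBin(c(0x00000801L, length(labels)), con2, size = 4, endian = "big")
  writeBin(as.integer(labels), con2, size = 1)
  close(con2)
  invisible(images_path)
}

#' Generate a bursty toy AER stream
#'
#' Emulates the bursty event statistics of a sensor watching a flashing
#' stimulus: each burst packs its events into a short (default 30 ms)
#' window at random pixels with random polarity. Useful for exercising the
#' AEDAT codec and converters without any recorded data.
#'
#' @param n_bursts number of bursts.
#' @param events_per_burst events in each burst.
#' @param burst_width_ms width of each burst window.
#' @param period_ms burst spacing.
#' @param width,height sensor geometry.
#' @param seed seed.
#' @return an [aer_stream()].
#' @export
generate_toy_aer <- function(n_bursts = 2, events_per_burst = 200,
                             burst_width_ms = 30, period_ms = 1000,
                             width = 128L, height = 128L, seed = 1) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
    globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  if (n_bursts < 1 || events_per_burst < 1)
    return(aer_stream(width = width, height = height))
  ev <- do.call(rbind, lapply(seq_len(n_bursts), function(b) {
    t0 <- (b - 1) * period_ms
    data.frame(
      timestamp_us = round((t0 + stats::runif(events_per_burst, 0,
                                              burst_width_ms)) * 1000),
      x = sample(0:(width - 1L), events_per_burst, replace = TRUE),
      y = sample(0:(height - 1L), events_per_burst, replace = TRUE),
      polarity = sample(0:1, events_per_burst, replace = TRUE))
  }))
  aer_stream(ev, width = width, height = height)
}
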