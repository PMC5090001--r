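#' Difference-of-Gaussians kernel parameters
#'
#' One retinal ganglion-cell layer is modelled by a center-surround
#' difference-of-Gaussians receptive field: a narrow center Gaussian minus a
#' wider surround Gaussian (ON-center), or the reverse (OFF-center).
#'
#' @param layer integer layer id (0-3 in the four-scale retina model).
#' @param sigma_c,sigma_s center and surround standard deviations in
#'   pixels; `sigma_s > sigma_c > 0`.
#' @param center_sign `"ON"` (+ center, - surround) or `"OFF"`.
#' @param kernel_radius integer truncation radius; at least
#'   `ceiling(3 * sigma_s)`.
#' @return a `dog_params` list.
#' @export
dog_params <- function(layer, sigma_c, sigma_s,
                       center_sign = c("ON", "OFF"),
                       kernel_radius = ceiling(3 * sigma_s)) {
  center_sign <- match.arg(center_sign)
  if (!(sigma_s > sigma_c && sigma_c > 0))
    stop("need sigma_s > sigma_c > 0")
  if (kernel_radius < ceiling(3 * sigma_s))
    stop("kernel_radius must be >= ceiling(3 * sigma_s)")
  structure(list(layer = as.integer(layer), sigma_c = sigma_c,
                 sigma_s = sigma_s, center_sign = center_sign,
                 kernel_radius = as.integer(kernel_radius)),
            class = "dog_params")
}

#' Default four-scale ganglion parameter set
#'
#' Scales quadruple across layers (`sigma_c` = 0.8, 1.6, 3.2, 6.4 px with
#' `sigma_s = 2 * sigma_c`); layers 0-1 are ON-center and capture fine
#' detail, layers 2-3 OFF-center blob detectors. All values are
#' configuration, not constants — pass your own list to [build_dog_bank()]
#' to reproduce a specific published encoder.
#'
#' @return list of four [dog_params()].
#' @export
default_dog_params <- function() {
  sc <- c(0.8, 1.6, 3.2, 6.4)
  sign <- c("ON", "ON", "OFF", "OFF")
  lapply(0:3, function(w)
    dog_params(w, sigma_c = sc[w + 1], sigma_s = 2 * sc[w + 1],
               center_sign = sign[w + 1]))
}

#' Build a bank of discrete DoG kernels
#'
#' Each kernel is sampled on the integer grid `[-r, r]^2`; the center and
#' surround Gaussians are separately normalized to unit discrete mass
#' before subtraction, so the kernel's DC response is near zero (exactly
#' zero in the continuum, `|sum| <= 1e-3` after truncation).
#'
#' @param params list of [dog_params()] (default [default_dog_params()]).
#' @return a `dog_bank`: list with `kernels` (list of matrices) and
#'   `params`.
#' @export
build_dog_bank <- function(params = default_dog_params()) {
  kernels <- lapply(params, function(p) {
    r <- p$kernel_radius
    ax <- -r:r
    g <- function(sigma) {
      g1 <- exp(-ax^2 / (2 * sigma^2))
      k <- outer(g1, g1)
      k / sum(k)
    }
    k <- g(p$sigma_c) - g(p$sigma_s)
    if (p$center_sign == "OFF") k <- -k
    k
  })
  structure(list(kernels = kernels, params = params), class = "dog_bank")
}

#' @export
print.dog_bank <- function(x, ...) {
  cat("DoG kernel bank:", length(x$kernels), "layers\n")
  for (i in seq_along(x$params)) {
    p <- x$params[[i]]
    cat(sprintf("  layer %d: %s-center, sigma_c=%.2f sigma_s=%.2f r=%d\n",
                p$layer, p$center_sign, p$sigma_c, p$sigma_s,
                p$kernel_radius))
  }
  invisible(x)
}

# dense 2-D cross-correlation with zero padding, same-size output
xcorr2_same <- function(image, kernel) {
  r <- (nrow(kernel) - 1L) %/% 2L
  nr <- nrow(image); nc <- ncol(image)
  pad <- matrix(0, nr + 2L * r, nc + 2L * r)
  pad[(r + 1L):(r + nr), (r + 1L):(r + nc)] <- image
  out <- matrix(0, nr, nc)
  for (a in seq_len(nrow(kernel))) {
    for (b in seq_len(ncol(kernel))) {
      kv <- kernel[a, b]
      if (kv == 0) next
      out <- out + kv * pad[(a):(a + nr - 1L), (b):(b + nc - 1L)]
    }
  }
  out
}

#' Filter an image through the ganglion kernel bank
#'
#' Performs one discrete 2-D convolution per layer (the kernels are
#' even-symmetric, so convolution and cross-correlation coincide) with
#' zero padding at the borders, and retains the positive responses as
#' spike-candidate coefficients: the ON/OFF channel split carries the two
#' signs, and spike emission times must be positive and value-ordered.
#'
#' @param image 2-d intensity matrix.
#' @param bank a [build_dog_bank()] `dog_bank`.
#' @return a `coefficient_list`: data.frame with columns `layer`, `x`,
#'   `y` (0-based, `x` = column), `value`; attributes `status = "raw"`,
#'   `dim` (image shape).
#' @export
convolve_image <- function(image, bank) {
  stopifnot(is.matrix(image), inherits(bank, "dog_bank"))
  rows <- lapply(seq_along(bank$kernels), function(i) {
    resp <- xcorr2_same(image, bank$kernels[[i]])
    keep <- which(resp > 0, arr.ind = TRUE)
    if (nrow(keep) == 0L)
      return(data.frame(layer = integer(), x = integer(), y = integer(),
                        value = numeric()))
    data.frame(layer = bank$params[[i]]$layer,
               x = keep[, 2] - 1L, y = keep[, 1] - 1L,
               value = resp[keep])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, status = "raw", dim_image = dim(image),
            class = c("coefficient_list", "data.frame"))
}

#' @export
print.coefficient_list <- function(x, ...) {
  cat("Coefficient list (", attr(x, "status"), "): ", nrow(x),
      " entries over ", length(unique(x$layer)), " layers\n", sep = "")
  invisible(x)
}

# 2-D cross-correlation of two kernels over all integer offsets, via FFT
kernel_xcorr_full <- function(ka, kb) {
  ra <- (nrow(ka) - 1L) %/% 2L
  rb <- (nrow(kb) - 1L) %/% 2L
  n <- 2L * (ra + rb) + 1L
  pa <- matrix(0, n, n); pb <- matrix(0, n, n)
  pa[1:nrow(ka), 1:ncol(ka)] <- ka
  pb[1:nrow(kb), 1:ncol(kb)] <- kb
  cc <- Re(stats::fft(stats::fft(pa) * Conj(stats::fft(pb)),
                      inverse = TRUE)) / (n * n)
  # circular shift k aligns ka(w + k + rb - ra) with kb(w); pick rows so
  # that index (ra + rb + 1) is center-to-center offset 0
  s <- -(ra + rb):(ra + rb)
  idx <- ((s + ra - rb) %% n) + 1L
  cc[idx, idx]
}

#' Inter-kernel overlap correlation table
#'
#' For a selected coefficient with kernel `K_a` and a spatially-near
#' coefficient with kernel `K_b` at pixel offset `(dx, dy)`, the overlap
#' correlation is the normalized inner product
#' `Q = <K_a shifted, K_b> / <K_a, K_a>` — the fraction of the selected
#' coefficient's kernel energy that the neighbor's kernel also sees.
#' `Q` is zero whenever the kernel supports do not overlap; the greedy
#' redundancy correction subtracts `m * Q` from each neighbor.
#'
#' @param bank a `dog_bank`.
#' @return a `kernel_correlation_table`: for each ordered layer pair an
#'   offset-indexed matrix, plus the per-pair radius bookkeeping. Query it
#'   with [q_lookup()].
#' @export
kernel_correlations <- function(bank) {
  nl <- length(bank$kernels)
  energies <- vapply(bank$kernels, function(k) sum(k * k), numeric(1))
  tabs <- vector("list", nl * nl)
  dim(tabs) <- c(nl, nl)
  for (a in seq_len(nl)) {
    for (b in seq_len(nl)) {
      tabs[[a, b]] <- kernel_xcorr_full(bank$kernels[[a]],
                                        bank$kernels[[b]]) / energies[a]
    }
  }
  radii <- vapply(bank$params, function(p) p$kernel_radius, integer(1))
  structure(list(tables = tabs, radii = radii),
            class = "kernel_correlation_table")
}

#' Look up overlap correlations
#'
#' @param Q a [kernel_correlations()] table.
#' @param layer_m,layer_c 0-based layers of the selected coefficient and
#'   the neighbor.
#' @param dx,dy neighbor position minus selected position (pixels).
#' @return numeric `Q` values (0 beyond kernel overlap).
#' @export
q_lookup <- function(Q, layer_m, layer_c, dx, dy) {
  n <- max(length(layer_m), length(layer_c), length(dx), length(dy))
  layer_m <- rep_len(layer_m, n); layer_c <- rep_len(layer_c, n)
  dx <- rep_len(dx, n); dy <- rep_len(dy, n)
  out <- numeric(n)
  for (pair in unique(paste(layer_m, layer_c))) {
    sel <- which(paste(layer_m, layer_c) == pair)
    a <- layer_m[sel[1]]; b <- layer_c[sel[1]]
    tab <- Q$tables[[a + 1L, b + 1L]]
    rmax <- Q$radii[a + 1L] + Q$radii[b + 1L]
    ok <- sel[abs(dx[sel]) <= rmax & abs(dy[sel]) <= rmax]
    if (length(ok))
      out[ok] <- tab[cbind(dy[ok] + rmax + 1L, dx[ok] + rmax + 1L)]
  }
  out
}

#' Greedy filter-overlap redundancy correction
#'
#' Repeatedly extracts the globally largest remaining coefficient, appends
#' it to the corrected list, and subtracts `m * Q(m, c)` from every
#' spatially-near remaining coefficient, until none remain. Because the DoG
#' kernels are not orthogonal, a large response at one ganglion cell leaks
#' into its neighbors; this greedy pass removes that shared information so
#' the rank order of the corrected coefficients concentrates the image
#' content in the earliest spikes. Exact value ties are broken toward the
#' lowest `(layer, y, x)` so the procedure is fully deterministic.
#'
#' @param C a raw `coefficient_list` from [convolve_image()].
#' @param Q a [kernel_correlations()] table for the same bank.
#' @param value_floor optional early stop: once the running maximum falls
#'   below this value the remaining coefficients are moved unadjusted. The
#'   default 0 runs the full loop (every coefficient individually
#'   extracted); entry count is preserved either way.
#' @return a `coefficient_list` with `status = "corrected"`, rows in
#'   selection order (values non-increasing at selection time).
#' @export
focal_correct <- function(C, Q, value_floor = 0) {
  stopifnot(inherits(C, "coefficient_list"),
            inherits(Q, "kernel_correlation_table"))
  dims <- attr(C, "dim_image")
  n <- nrow(C)
  if (n <= 1L) {
    out <- C
    attr(out, "status") <- "corrected"
    return(out)
  }
  nl <- length(Q$radii)
  nr <- dims[1]; nc <- dims[2]
  # dense working values: val[y + 1, x + 1, layer + 1]; NA = not a candidate
  val <- array(NA_real_, c(nr, nc, nl))
  val[cbind(C$y + 1L, C$x + 1L, C$layer + 1L)] <- C$value
  active <- !is.na(val)
  val_rank <- val  # selection uses -Inf for inactive
  val_rank[!active] <- -Inf
  out_layer <- integer(n); out_x <- integer(n); out_y <- integer(n)
  out_val <- numeric(n)
  # linear index -> (y, x, layer); column-major order of the array gives
  # y fastest; ties must resolve to lowest (layer, y, x), so rank by a key
  n_left <- n
  k <- 0L
  while (n_left > 0L) {
    # which.max returns the first maximum in column-major order
    # (y, then x, then layer); re-resolve ties to lowest (layer, y, x)
    i <- which.max(val_rank)
    mval <- val_rank[i]
    if (mval == -Inf) break
    ties <- which(val_rank == mval)
    if (length(ties) > 1L) {
      yy <- (ties - 1L) %% nr
      xx <- ((ties - 1L) %/% nr) %% nc
      ll <- (ties - 1L) %/% (nr * nc)
      o <- order(ll, yy, xx)[1L]
      i <- ties[o]
    }
    y0 <- (i - 1L) %% nr
    x0 <- ((i - 1L) %/% nr) %% nc
    l0 <- (i - 1L) %/% (nr * nc)
    k <- k + 1L
    out_layer[k] <- l0; out_x[k] <- x0; out_y[k] <- y0; out_val[k] <- mval
    active[i] <- FALSE
    val_rank[i] <- -Inf
    n_left <- n_left - 1L
    if (value_floor > 0 && mval < value_floor) {
      # early stop: flush the rest unadjusted, highest first
      rest <- which(active)
      if (length(rest)) {
        yy <- (rest - 1L) %% nr
        xx <- ((rest - 1L) %/% nr) %% nc
        ll <- (rest - 1L) %/% (nr * nc)
        o <- order(-val_rank[rest], ll, yy, xx)
        idx <- (k + 1L):(k + length(rest))
        out_layer[idx] <- ll[o]; out_x[idx] <- xx[o]; out_y[idx] <- yy[o]
        out_val[idx] <- val_rank[rest][o]
        k <- k + length(rest)
      }
      break
    }
    # subtract m * Q(m, c) from active neighbors, layer by layer
    for (lb in 0:(nl - 1L)) {
      rmax <- Q$radii[l0 + 1L] + Q$radii[lb + 1L]
      ylo <- max(0L, y0 - rmax); yhi <- min(nr - 1L, y0 + rmax)
      xlo <- max(0L, x0 - rmax); xhi <- min(nc - 1L, x0 + rmax)
      tab <- Q$tables[[l0 + 1L, lb + 1L]]
      sub_act <- active[(ylo + 1L):(yhi + 1L), (xlo + 1L):(xhi + 1L),
                        lb + 1L, drop = FALSE]
      if (!any(sub_act)) next
      qsub <- tab[(ylo - y0 + rmax + 1L):(yhi - y0 + rmax + 1L),
                  (xlo - x0 + rmax + 1L):(xhi - x0 + rmax + 1L),
                  drop = FALSE]
      adj <- mval * qsub
      adj[!sub_act[, , 1L]] <- 0
      sl <- (ylo + 1L):(yhi + 1L)
      sc <- (xlo + 1L):(xhi + 1L)
      val_rank[sl, sc, lb + 1L] <- val_rank[sl, sc, lb + 1L] - adj
    }
  }
  out <- data.frame(layer = out_layer[seq_len(k)], x = out_x[seq_len(k)],
                    y = out_y[seq_len(k)], value = out_val[seq_len(k)])
  structure(out, status = "corrected", dim_image = dims,
            class = c("coefficient_list", "data.frame"))
}

#' Rank-order spike emission
#'
#' The corrected coefficients are sorted by value (descending); the top
#' `top_fraction` of them spike, one spike per model neuron, at uniformly
#' spaced times: rank `k` (0-based) fires at `k * interval_ms`. Only
#' positive-valued coefficients can fire (emission time is value-ordered
#' and each neuron fires at most once — the defining property of a rank
#' order code). A continuous variant, `t = interval_ms * v_max / v`,
#' is available with `timing = "inverse"` since emission time is taken to
#' be inversely proportional to coefficient value.
#'
#' @param M a corrected `coefficient_list`.
#' @param interval_ms spacing between consecutive ranks (default 1 ms).
#' @param top_fraction fraction of coefficients retained (default 0.3, the
#'   "first 30% of the spikes" working point).
#' @param timing `"rank"` (default) or `"inverse"`.
#' @return a [spike_source_arrays()] over `4 * height * width` model
#'   neurons: neuron id `= layer * H * W + y * W + x`.
#' @export
rank_order_spikes <- function(M, interval_ms = 1.0, top_fraction = 0.3,
                              timing = c("rank", "inverse")) {
  timing <- match.arg(timing)
  stopifnot(inherits(M, "coefficient_list"))
  dims <- attr(M, "dim_image")
  nl <- max(4L, if (nrow(M)) max(M$layer) + 1L else 0L)
  n_neurons <- nl * dims[1] * dims[2]
  if (nrow(M) == 0L)
    return(spike_source_arrays(list(), n_neurons = n_neurons,
                               duration_ms = 0))
  o <- order(-M$value, M$layer, M$y, M$x)
  n_keep <- max(1L, floor(nrow(M) * top_fraction + 1e-9))
  sel <- M[o[seq_len(n_keep)], , drop = FALSE]
  sel <- sel[sel$value > 0, , drop = FALSE]
  if (nrow(sel) == 0L)
    return(spike_source_arrays(list(), n_neurons = n_neurons,
                               duration_ms = 0))
  nid <- sel$layer * dims[1] * dims[2] + sel$y * dims[2] + sel$x
  times <- if (timing == "rank") (seq_len(nrow(sel)) - 1) * interval_ms
           else interval_ms * sel$value[1] / sel$value
  spikes <- rep(list(numeric()), n_neurons)
  for (j in seq_len(nrow(sel)))
    spikes[[nid[j] + 1L]] <- times[j]
  spike_source_arrays(spikes, n_neurons = n_neurons,
                      duration_ms = max(times))
}

#' Reconstruct an image from DoG coefficients
#'
#' Stamps each coefficient's kernel at its location, scaled by the
#' coefficient's reconstruction amplitude `value / <K, K>` (the greedy
#' correction subtracts `m * <K_m, K_c> / <K_m, K_m>` from neighbors, i.e.
#' it treats `value / <K, K>` as the amount of kernel present, so the same
#' amplitude is used when stamping back), and sums; optionally rescales
#' the result linearly onto a reference range for comparison with the
#' original. Reconstruction quality before vs after the redundancy
#' correction is the standard check that the correction removed shared
#' (double-counted) information.
#'
#' @param coeffs a `coefficient_list` (raw or corrected).
#' @param bank the `dog_bank` the coefficients came from.
#' @param rescale_to optional numeric range `c(lo, hi)` to map the output
#'   onto (e.g. `c(0, 255)`); `NULL` leaves raw sums.
#' @param include_negative also stamp non-positive corrected entries.
#'   By default they are dropped: only positive coefficients are ever
#'   emitted as spikes, so the default reconstructs what the spike code
#'   transmits (raw lists contain positive entries only, so this has no
#'   effect on them).
#' @return an image matrix of the encoded shape.
#' @export
reconstruct_image <- function(coeffs, bank, rescale_to = NULL,
                              include_negative = FALSE) {
  stopifnot(inherits(coeffs, "coefficient_list"))
  dims <- attr(coeffs, "dim_image")
  if (!include_negative)
    coeffs <- coeffs[coeffs$value > 0, , drop = FALSE]
  nr <- dims[1]; nc <- dims[2]
  radii <- vapply(bank$params, function(p) p$kernel_radius, integer(1))
  energies <- vapply(bank$kernels, function(k) sum(k * k), numeric(1))
  rmax <- max(radii)
  acc <- matrix(0, nr + 2L * rmax, nc + 2L * rmax)
  for (j in seq_len(nrow(coeffs))) {
    l <- coeffs$layer[j] + 1L
    r <- radii[l]
    y0 <- coeffs$y[j] + rmax + 1L   # padded coords
    x0 <- coeffs$x[j] + rmax + 1L
    acc[(y0 - r):(y0 + r), (x0 - r):(x0 + r)] <-
      acc[(y0 - r):(y0 + r), (x0 - r):(x0 + r)] +
      (coeffs$value[j] / energies[l]) * bank$kernels[[l]]
  }
  img <- acc[(rmax + 1L):(rmax + nr), (rmax + 1L):(rmax + nc)]
  if (!is.null(rescale_to)) {
    rng <- range(img)
    if (diff(rng) > 0) {
      img <- (img - rng[1]) / diff(rng) *
        (rescale_to[2] - rescale_to[1]) + rescale_to[1]
    }
  }
  img
}

#' Reconstruction error of a coefficient list
#'
#' Mean-squared error between the original image and the reconstruction,
#' after the best linear (affine) rescaling of the reconstruction onto the
#' image's intensity scale — the rescaling that minimizes the MSE, so the
#' comparison measures shape fidelity, not brightness calibration.
#'
#' @param image the original intensity matrix.
#' @param coeffs a `coefficient_list` (raw or corrected).
#' @param bank the matching `dog_bank`.
#' @return the affine-fit MSE (numeric).
#' @export
reconstruction_mse <- function(image, coeffs, bank) {
  rec <- reconstruct_image(coeffs, bank)
  fit <- stats::lm.fit(cbind(1, as.vector(rec)), as.vector(image))
  mean(fit$residuals^2)
}

#' One-call FoCal encoder
#'
#' Convenience wrapper: bank construction, convolution, overlap correction
#' and rank-order emission in one step.
#'
#' @inheritParams rank_order_spikes
#' @param image intensity matrix.
#' @param bank optional prebuilt `dog_bank` (with matching correlation
#'   table computed internally).
#' @return list with `spikes` ([spike_source_arrays()]), `raw` and
#'   `corrected` coefficient lists, and the `bank`.
#' @export
focal_encode <- function(image, bank = build_dog_bank(), interval_ms = 1.0,
                         top_fraction = 0.3) {
  Q <- kernel_correlations(bank)
  C <- convolve_image(image, bank)
  M <- focal_correct(C, Q)
  list(spikes = rank_order_spikes(M, interval_ms, top_fraction),
       raw = C, corrected = M, bank = bank)
}
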