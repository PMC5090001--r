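# Shared fixtures and independent oracles for the suite.

# small two-layer DoG bank: keeps convolution/correction tests fast while
# exercising cross-layer (different radius) correlations
small_bank <- function() {
  build_dog_bank(list(dog_params(0, 0.8, 1.6, "ON"),
                      dog_params(1, 1.6, 3.2, "OFF")))
}

# brute-force re-scan implementation of the greedy overlap correction:
# re-sorts the full remaining list each iteration and subtracts through
# q_lookup, sharing no code path with focal_correct's dense working array
brute_focal <- function(C, Q) {
  df <- as.data.frame(C)
  out <- df[0, ]
  while (nrow(df)) {
    o <- order(-df$value, df$layer, df$y, df$x)
    m <- df[o[1], ]
    out <- rbind(out, m)
    df <- df[-o[1], , drop = FALSE]
    if (nrow(df)) {
      qv <- q_lookup(Q, m$layer, df$layer, df$x - m$x, df$y - m$y)
      df$value <- df$value - m$value * qv
    }
  }
  rownames(out) <- NULL
  out
}

# dense cross-correlation oracle (zero padding), direct nested loops
brute_xcorr <- function(image, kernel) {
  r <- (nrow(kernel) - 1L) %/% 2L
  out <- matrix(0, nrow(image), ncol(image))
  for (i in seq_len(nrow(image))) {
    for (j in seq_len(ncol(image))) {
      s <- 0
      for (a in -r:r) {
        for (b in -r:r) {
          ii <- i + a; jj <- j + b
          if (ii >= 1 && ii <= nrow(image) && jj >= 1 && jj <= ncol(image))
            s <- s + image[ii, jj] * kernel[a + r + 1, b + r + 1]
        }
      }
      out[i, j] <- s
    }
  }
  out
}

# closed-form constant-current LIF firing rate (Hz)
lif_rate_closed_form <- function(i_nA, p) {
  RI <- p$r_m * i_nA
  den <- RI + p$v_rest - p$v_thresh
  if (den <= 0) return(0)
  1000 / (p$tau_refrac +
            p$tau_m * log((RI + p$v_rest - p$v_reset) / den))
}

# cached fixture digit sets (shared across test files in one run)
.fixture_cache <- new.env(parent = emptyenv())
fixture_digits <- function(n_per_class, classes, seed) {
  key <- paste(n_per_class, paste(classes, collapse = ","), seed)
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- suppressWarnings(
      generate_digits(n_per_class, classes = classes, seed = seed))
  .fixture_cache[[key]]
}
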