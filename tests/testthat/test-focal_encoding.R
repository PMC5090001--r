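test_that("DoG kernels have the right sign, symmetry and near-zero DC", {
  bank <- build_dog_bank()
  for (i in seq_along(bank$kernels)) {
    k <- bank$kernels[[i]]
    ctr <- (nrow(k) + 1) / 2
    if (bank$params[[i]]$center_sign == "ON") expect_gt(k[ctr, ctr], 0)
    else expect_lt(k[ctr, ctr], 0)
    expect_lt(abs(sum(k)), 1e-3)
    expect_equal(k, k[rev(seq_len(nrow(k))), rev(seq_len(ncol(k)))])
  }
  expect_error(dog_params(0, 2, 1, "ON"), "sigma_s > sigma_c")
  expect_error(dog_params(0, 1, 2, "ON", kernel_radius = 3), "radius")
})

test_that("convolution matches a brute-force dense oracle", {
  bank <- small_bank()
  set.seed(31)
  img <- matrix(sample(0:255, 100, TRUE), 10, 10)
  C <- convolve_image(img, bank)
  for (l in 0:1) {
    ref <- brute_xcorr(img, bank$kernels[[l + 1]])
    sub <- C[C$layer == l, ]
    expect_gt(nrow(sub), 0)
    expect_lt(max(abs(sub$value - ref[cbind(sub$y + 1, sub$x + 1)])), 1e-10)
    # only positive responses are retained as spike candidates
    expect_true(all(sub$value > 0))
    expect_equal(nrow(sub), sum(ref > 0))
  }
  # constant image: DoG kills DC away from the borders (zero padding
  # breaks the cancellation inside one kernel radius of the edge)
  flat <- convolve_image(matrix(100, 24, 24), bank)
  interior <- flat[flat$x >= 10 & flat$x <= 13 &
                     flat$y >= 10 & flat$y <= 13, ]
  if (nrow(interior)) expect_lt(max(interior$value), 100 * 1e-2)
  # impulse response reproduces the kernel at the impulse location
  imp <- matrix(0, 11, 11); imp[6, 6] <- 1
  Ci <- convolve_image(imp, bank)
  k0 <- bank$kernels[[1]]
  r0 <- (nrow(k0) - 1) / 2
  s0 <- Ci[Ci$layer == 0, ]
  for (r in seq_len(nrow(s0))) {
    dx <- s0$x[r] - 5; dy <- s0$y[r] - 5
    expect_equal(s0$value[r], k0[dy + r0 + 1, dx + r0 + 1],
                 tolerance = 1e-12)
  }
})

test_that("kernel correlation table equals direct inner products", {
  bank <- small_bank()
  Q <- kernel_correlations(bank)
  expect_equal(q_lookup(Q, 0, 0, 0L, 0L), 1, tolerance = 1e-10)
  expect_equal(q_lookup(Q, 1, 1, 0L, 0L), 1, tolerance = 1e-10)
  # beyond combined radii the supports are disjoint
  expect_identical(q_lookup(Q, 0, 1, 100L, 0L), 0)
  # brute-force inner-product ratio at assorted cross-layer offsets
  ka <- bank$kernels[[1]]; kb <- bank$kernels[[2]]
  ra <- (nrow(ka) - 1) / 2; rb <- (nrow(kb) - 1) / 2
  bf_q <- function(dx, dy) {
    s <- 0
    for (u in -rb:rb) for (v in -rb:rb) {
      uu <- u + dy; vv <- v + dx
      if (abs(uu) <= ra && abs(vv) <= ra)
        s <- s + ka[uu + ra + 1, vv + ra + 1] * kb[u + rb + 1, v + rb + 1]
    }
    s / sum(ka * ka)
  }
  for (off in list(c(0, 0), c(1, 0), c(-2, 3), c(4, -4))) {
    expect_equal(q_lookup(Q, 0, 1, off[1], off[2]), bf_q(off[1], off[2]),
                 tolerance = 1e-10)
  }
  # a genuinely hand-sized 5x5 pair: radius 2 kernels
  tiny <- build_dog_bank(list(dog_params(0, 0.25, 0.5, "ON"),
                              dog_params(1, 0.3, 0.6, "OFF")))
  expect_equal(dim(tiny$kernels[[1]]), c(5L, 5L))
  Qt <- kernel_correlations(tiny)
  ka <- tiny$kernels[[1]]; kb <- tiny$kernels[[2]]
  direct <- sum(ka[2:5, ] * kb[1:4, ]) / sum(ka * ka)  # offset dy=-1
  expect_equal(q_lookup(Qt, 0, 1, 0L, -1L), direct, tolerance = 1e-10)
})

test_that("greedy correction follows the hand-worked two-coefficient case", {
  # singleton: nothing to correct
  bank <- small_bank(); Q <- kernel_correlations(bank)
  img <- matrix(0, 9, 9); img[5, 5] <- 255
  C1 <- convolve_image(img, bank)
  top <- C1[which.max(C1$value), ]
  M1 <- focal_correct(C1[which.max(C1$value), ], Q)
  expect_equal(as.data.frame(M1), as.data.frame(top),
               ignore_attr = TRUE)
  # two fully correlated coefficients (Q = 1): second is suppressed to 0
  C2 <- structure(data.frame(layer = c(0L, 1L), x = c(3L, 3L),
                             y = c(3L, 3L), value = c(10, 10)),
                  status = "raw", dim_image = c(8L, 8L),
                  class = c("coefficient_list", "data.frame"))
  Qhand <- structure(list(
    tables = matrix(list(matrix(1, 1, 1), matrix(1, 1, 1),
                         matrix(1, 1, 1), matrix(1, 1, 1)), 2, 2),
    radii = c(0L, 0L)), class = "kernel_correlation_table")
  M2 <- focal_correct(C2, Qhand)
  expect_equal(M2$value, c(10, 0))
  expect_equal(M2$layer, c(0L, 1L))   # tie broken toward the lower layer
})

test_that("greedy correction equals the brute-force re-scan oracle", {
  bank <- small_bank(); Q <- kernel_correlations(bank)
  for (seed in 1:3) {
    set.seed(seed)
    img <- matrix(sample(0:255, 64, TRUE), 8, 8)
    C <- convolve_image(img, bank)
    M <- focal_correct(C, Q)
    Mo <- brute_focal(C, Q)
    expect_equal(nrow(M), nrow(C))   # every coefficient is moved
    expect_equal(as.data.frame(M), Mo, ignore_attr = TRUE,
                 tolerance = 1e-9)
  }
})

test_that("rank-order emission: one spike per neuron, top fraction, timing", {
  d <- fixture_digits(1, c(1, 2), 4)
  enc <- focal_encode(d$images[[1]])
  expect_true(all(lengths(enc$spikes$spikes) <= 1L))
  n_pos <- sum(enc$corrected$value > 0)
  expect_lte(n_spikes(enc$spikes),
             max(1, floor(nrow(enc$corrected) * 0.3 + 1e-9)))
  # 10 coefficients at fraction 0.3 -> 3 spikes at 0, 1, 2 ms
  C10 <- structure(data.frame(layer = 0L, x = 0:9, y = 0L,
                              value = seq(10, 1)),
                   status = "corrected", dim_image = c(1L, 10L),
                   class = c("coefficient_list", "data.frame"))
  sp <- rank_order_spikes(C10, interval_ms = 1, top_fraction = 0.3)
  expect_equal(n_spikes(sp), 3L)
  expect_equal(sort(unlist(sp$spikes)), c(0, 1, 2))
  # the highest coefficient fires first
  expect_equal(sp$spikes[[1]], 0)
  # empty list -> empty spike set
  C0 <- structure(data.frame(layer = integer(), x = integer(),
                             y = integer(), value = numeric()),
                  status = "corrected", dim_image = c(4L, 4L),
                  class = c("coefficient_list", "data.frame"))
  expect_equal(n_spikes(rank_order_spikes(C0)), 0L)
  # inverse-time variant is ordered the same way
  spi <- rank_order_spikes(C10, timing = "inverse")
  expect_equal(spi$spikes[[1]], 1)   # v_max / v = 1 at the top coefficient
  expect_true(all(diff(sort(unlist(spi$spikes))) > 0))
})

test_that("overlap correction improves reconstruction on every fixture digit", {
  bank <- build_dog_bank()
  Q <- kernel_correlations(bank)
  d <- fixture_digits(2, c(1, 2, 5), 7)
  for (i in seq_along(d$images)) {
    C <- convolve_image(d$images[[i]], bank)
    M <- focal_correct(C, Q)
    expect_lt(reconstruction_mse(d$images[[i]], M, bank),
              reconstruction_mse(d$images[[i]], C, bank))
  }
  # empty list reconstructs to the zero image
  C0 <- structure(data.frame(layer = integer(), x = integer(),
                             y = integer(), value = numeric()),
                  status = "raw", dim_image = c(6L, 6L),
                  class = c("coefficient_list", "data.frame"))
  expect_equal(reconstruct_image(C0, bank), matrix(0, 6, 6))
})

test_that("the encoder is fully deterministic", {
  d <- fixture_digits(1, c(1, 2), 4)
  a <- focal_encode(d$images[[2]])
  b <- focal_encode(d$images[[2]])
  expect_identical(a$corrected, b$corrected)
  expect_identical(a$spikes$spikes, b$spikes$spikes)
})
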