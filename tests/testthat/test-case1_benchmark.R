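test_that("per-digit k-means subclassing: K=1 mean, blobs, determinism", {
  d <- fixture_digits(6, c(1, 2), 5)
  # K = 1: the centroid is the per-digit mean image (row-major order)
  p1 <- kmeans_subclasses(d$images, d$labels, K = 1, seed = 2)
  m1 <- rowMeans(vapply(d$images[d$labels == 1],
                        function(im) as.vector(t(im)), numeric(784)))
  expect_equal(p1$centroids[, 1], m1, tolerance = 1e-12)
  expect_equal(p1$decision_digit, c(1, 2))
  # two well-separated synthetic blobs are recovered exactly: 3x3 patches
  # jittered by one pixel overlap within a blob but not across blobs
  blob <- function(r, c) { m <- matrix(0, 28, 28); m[r:(r + 2), c:(c + 2)] <- 255; m }
  imgs <- c(lapply(1:5, function(i) blob(3 + i %% 2, 3)),
            lapply(1:5, function(i) blob(22, 22 - i %% 2)))
  labs <- rep(7, 10)
  p2 <- kmeans_subclasses(imgs, labs, K = 2, seed = 1)
  expect_equal(length(unique(p2$subclass[1:5])), 1L)
  expect_equal(length(unique(p2$subclass[6:10])), 1L)
  expect_false(p2$subclass[1] == p2$subclass[6])
  # deterministic under the seed
  p3 <- kmeans_subclasses(d$images, d$labels, K = 2, seed = 9)
  p4 <- kmeans_subclasses(d$images, d$labels, K = 2, seed = 9)
  expect_identical(p3$subclass, p4$subclass)
  expect_error(kmeans_subclasses(d$images, d$labels, K = 50, seed = 1),
               "fewer than K")
})

test_that("weak weights convert to one fixed inhibitory value", {
  tw <- template_weights(matrix(c(0.0, 0.5, 0.3, 0.05), 2, 2),
                         decision_digit = c(0, 1), w_max = 0.5)
  # rule application with explicit parameters
  t1 <- weak_to_inhibitory(tw, weak_threshold = 0.1,
                           inhibitory_value = 0.2)
  expect_equal(t1$W, matrix(c(-0.2, 0.5, 0.3, -0.2), 2, 2))
  expect_equal(t1$phase, "testing")
  # threshold 0 changes nothing but the phase
  t0 <- weak_to_inhibitory(tw, weak_threshold = 0)
  expect_equal(t0$W, tw$W)
  # conservation: every sub-threshold entry and only those become negative
  set.seed(4)
  W <- matrix(runif(300), 30, 10)
  twr <- template_weights(W, decision_digit = 0:9, w_max = 1)
  tr <- weak_to_inhibitory(twr, weak_threshold = 0.25)
  expect_equal(sum(tr$W < 0), sum(W < 0.25))
  expect_equal(tr$W[W >= 0.25], W[W >= 0.25])
  # default inhibitory magnitude is the mean of the removed weights
  expect_equal(unique(tr$W[tr$W < 0]), -mean(W[W < 0.25]))
  expect_error(weak_to_inhibitory(tr), "already")
})

test_that("weight scaling preserves sign pattern and phase", {
  tw <- template_weights(matrix(c(-0.2, 0.1), 1, 2), c(0, 1),
                         phase = "testing", w_max = 0.5)
  expect_equal(scale_weights(tw, 1)$W, tw$W)
  s10 <- scale_weights(tw, 10)
  expect_equal(s10$W, tw$W * 10)
  expect_equal(sign(s10$W), sign(tw$W))
  expect_equal(s10$phase, "testing")
})

test_that("STDP training embeds the subclass template in the weights", {
  d <- fixture_digits(8, c(1, 2), 6)
  part <- kmeans_subclasses(d$images, d$labels, K = 1, seed = 6)
  tw <- train_case1(part, d$images, d$labels,
                    protocol = list(per_image_ms = 300,
                                    total_rate_hz = 2000,
                                    teach_rate_hz = 50),
                    dt = 0.1, seed = 6)
  expect_true(all(tw$W >= 0))          # hard floor
  expect_true(all(tw$W <= tw$w_max))
  # trained vector correlates with the subclass centroid
  for (dn in 1:2)
    expect_gt(stats::cor(tw$W[, dn], part$centroids[, dn]), 0.5)
  # no teaching signal: no post spikes, weights stay at initialization
  tw0 <- train_case1(part, d$images, d$labels,
                     protocol = list(per_image_ms = 300,
                                     total_rate_hz = 2000,
                                     teach_rate_hz = 0),
                     dt = 0.1, seed = 6)
  expect_lt(max(abs(tw0$W)), 0.05 * stdp_params()$w_max + 1e-12)
})

test_that("testing protocol classifies a constructed separable case", {
  # two 'digits' that are one-hot at different pixels; identity templates
  img_a <- matrix(0, 4, 4); img_a[1, 1] <- 255
  img_b <- matrix(0, 4, 4); img_b[4, 4] <- 255
  W <- matrix(-0.01, 16, 2)
  W[1, 1] <- 0.1    # row-major pixel 0 excites neuron 1
  W[16, 2] <- 0.1
  tw <- template_weights(W, decision_digit = c(0, 1), phase = "testing",
                         w_max = 0.1)
  res <- test_case1(tw, list(img_a, img_b, img_a), c(0, 1, 0),
                    schedule = presentation_schedule(300, 100, 3),
                    total_rate_hz = 2000, seed = 8)
  expect_equal(res$predictions, c(0, 1, 0))
  expect_equal(res$metrics$accuracy$accuracy_pct, 100)
  # all-silent output is flagged as "no decision" and counted
  Wneg <- template_weights(matrix(-0.1, 16, 2), c(0, 1),
                           phase = "testing", w_max = 0.1)
  res0 <- test_case1(Wneg, list(img_a), 0,
                     schedule = presentation_schedule(200, 50, 1),
                     total_rate_hz = 2000, seed = 8)
  expect_true(is.na(res0$predictions))
  expect_equal(res0$metrics$accuracy$n_no_decision, 1L)
  expect_equal(res0$metrics$accuracy$accuracy_pct, 0)
  # training-phase weights are rejected
  expect_error(test_case1(template_weights(abs(W), c(0, 1)), list(img_a),
                          0), "testing-phase")
})

test_that("dual projections give each input spike 2 x n_dec events", {
  d <- fixture_digits(3, c(1, 2), 5)
  part <- kmeans_subclasses(d$images, d$labels, K = 1, seed = 5)
  tw <- weak_to_inhibitory(centroid_templates(part, w_max = 0.014))
  res <- test_case1(tw, d$images[1:2], d$labels[1:2],
                    schedule = presentation_schedule(200, 50, 2),
                    total_rate_hz = 2000, seed = 2)
  n_in <- sum(lengths(res$record$spikes$`in`))
  n_out <- sum(lengths(res$record$spikes$dec))
  dur_s <- res$record$duration_ms / 1000
  expect_equal(res$metrics$sopbs,
               (n_in * 2 * ncol(tw$W) + n_out) / dur_s)
})
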