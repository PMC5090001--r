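test_that("AEDAT header-only and hand-constructed records decode", {
  # header-only file, zero records
  f <- tempfile(fileext = ".aedat")
  con <- file(f, "wb")
  writeChar("#!AER-DAT2.0\r\n# comment\r\n", con, eos = NULL)
  close(con)
  st <- read_aedat(f)
  expect_equal(nrow(st$events), 0L)
  expect_equal(st$header_lines, c("#!AER-DAT2.0", "# comment"))

  # one hand-encoded DVS128 record: (x=5, y=7, ON) at t=1000 us
  # address word = y<<8 | x<<1 | 1 = 0x070B; timestamp 1000 = 0x3E8
  con <- file(f, "wb")
  writeChar("#!AER-DAT2.0\r\n", con, eos = NULL)
  writeBin(as.raw(c(0x00, 0x00, 0x07, 0x0B, 0x00, 0x00, 0x03, 0xE8)), con)
  close(con)
  st <- read_aedat(f)
  expect_equal(st$events$timestamp_us, 1000)
  expect_equal(st$events$x, 5L)
  expect_equal(st$events$y, 7L)
  expect_equal(st$events$polarity, 1L)

  # same event in the 1.0 dialect (16-bit address)
  con <- file(f, "wb")
  writeChar("#!AER-DAT1.0\r\n", con, eos = NULL)
  writeBin(as.raw(c(0x07, 0x0B, 0x00, 0x00, 0x03, 0xE8)), con)
  close(con)
  st1 <- read_aedat(f)
  expect_equal(st1$events, st$events)
})

test_that("AEDAT write/read round-trips byte-identically in both dialects", {
  st <- generate_toy_aer(2, 60, seed = 3)
  for (ver in c(1L, 2L)) {
    f <- tempfile(fileext = ".aedat")
    write_aedat(st, f, version = ver)
    st2 <- read_aedat(f)
    expect_equal(st2$events, st$events)
    f2 <- tempfile(fileext = ".aedat")
    write_aedat(st2, f2)   # version carried in the preserved header
    expect_identical(readBin(f, "raw", file.size(f)),
                     readBin(f2, "raw", file.size(f2)))
  }
  # record count: header + 3 fixed-size records
  st3 <- aer_stream(data.frame(timestamp_us = c(10, 20, 30), x = 0:2,
                               y = 0L, polarity = 1L))
  f3 <- tempfile(fileext = ".aedat")
  write_aedat(st3, f3, version = 2L)
  expect_equal(file.size(f3) - nchar("#!AER-DAT2.0\r\n"), 3 * 8)
})

test_that("malformed AEDAT input raises informative errors", {
  f <- tempfile(fileext = ".aedat")
  con <- file(f, "wb")
  writeChar("#!AER-DAT2.0\r\n", con, eos = NULL)
  writeBin(as.raw(rep(0, 11)), con)   # 11 bytes: not a multiple of 8
  close(con)
  expect_error(read_aedat(f), "truncated.*byte offset")
  con <- file(f, "wb")
  writeChar("#!AER-DAT9.9\r\n", con, eos = NULL)
  close(con)
  expect_error(read_aedat(f), "supported: 1.0, 2.0")
  # out-of-geometry event refuses to write
  bad <- aer_stream(data.frame(timestamp_us = 1, x = 5L, y = 5L,
                               polarity = 1L), width = 16L, height = 16L)
  bad$events$x <- 99L
  expect_error(write_aedat(bad, tempfile()), "geometry")
})

test_that("32-bit timestamp wrap-around is unwrapped on read", {
  t_big <- c(2^32 - 1500, 2^32 - 500, 2^32 + 800)  # crosses the wrap
  st <- aer_stream(data.frame(timestamp_us = t_big, x = c(1L, 2L, 3L),
                              y = 0L, polarity = 1L))
  f <- tempfile(fileext = ".aedat")
  write_aedat(st, f)                 # stored modulo 2^32
  expect_message(st2 <- read_aedat(f), "wrap")
  expect_equal(diff(st2$events$timestamp_us), diff(t_big))
})

test_that("stream_to_arrays converts, collapses duplicates, conserves", {
  ev <- data.frame(timestamp_us = c(2000, 1000, 3000, 1000, 5000),
                   x = c(0L, 3L, 3L, 3L, 1L), y = c(0L, 2L, 2L, 2L, 0L),
                   polarity = c(1L, 1L, 1L, 1L, 0L))
  st <- aer_stream(ev, width = 8L, height = 8L)
  expect_message(arr <- stream_to_arrays(st, "merge"), "1 duplicate")
  expect_equal(arr$spikes[[1]], 2.0)            # neuron 0 = (0,0)
  expect_equal(arr$spikes[[2 * 8 + 3 + 1]], c(1.0, 3.0))
  expect_equal(n_spikes(arr), nrow(ev) - 1L)    # one duplicate collapsed
  # split conserves the stream's event count
  sp <- suppressMessages(stream_to_arrays(st, "split"))
  expect_equal(n_spikes(sp$on) + n_spikes(sp$off), nrow(ev) - 1L)
  # drop_off keeps only ON events
  expect_equal(n_spikes(suppressMessages(stream_to_arrays(st, "drop_off"))),
               3L)
})

test_that("arrays_to_stream inverts the conversion", {
  st <- generate_toy_aer(1, 40, seed = 9)
  arr <- suppressMessages(stream_to_arrays(st, "merge"))
  st2 <- arrays_to_stream(arr, 128L, 128L)
  expect_equal(nrow(st2$events), n_spikes(arr))
  arr2 <- suppressMessages(stream_to_arrays(st2, "merge"))
  expect_equal(arr2$spikes, arr$spikes)   # duplicate-free: exact inverse
  # unit conversion and the empty case
  one <- spike_source_arrays(c(list(2.5), rep(list(numeric()), 3)),
                             duration_ms = 10)
  expect_equal(arrays_to_stream(one, 2L, 2L)$events$timestamp_us, 2500)
  empty <- spike_source_arrays(rep(list(numeric()), 4), duration_ms = 0)
  expect_equal(nrow(arrays_to_stream(empty, 2L, 2L)$events), 0L)
  expect_error(arrays_to_stream(one, 3L, 3L), "geometry")
})

test_that("NPY spike-array container round-trips at full precision", {
  st <- generate_toy_aer(2, 150, seed = 5)
  arr <- suppressMessages(stream_to_arrays(st, "merge"))
  p <- tempfile(fileext = ".npy")
  write_npy_arrays(arr, p)
  arr2 <- read_npy_arrays(p)
  expect_identical(arr2$spikes, arr$spikes)
  expect_equal(arr2$n_neurons, arr$n_neurons)
  expect_equal(arr2$duration_ms, arr$duration_ms)
  # empty set
  empty <- spike_source_arrays(rep(list(numeric()), 784), duration_ms = 0)
  write_npy_arrays(empty, p)
  e2 <- read_npy_arrays(p)
  expect_equal(e2$n_neurons, 784L)
  expect_equal(n_spikes(e2), 0L)
  # irrational-ish times survive to full double precision
  odd <- spike_source_arrays(list(c(pi, exp(2)), sqrt(c(2, 3, 5))),
                             n_neurons = 784L, duration_ms = 10)
  write_npy_arrays(odd, p)
  expect_identical(read_npy_arrays(p)$spikes[1:2], odd$spikes[1:2])
  # malformed container
  npy_save(1:5, p, dtype = "i4")
  expect_error(read_npy_arrays(p), "malformed")
})

test_that("NPY codec handles vectors, matrices and bad input", {
  p <- tempfile(fileext = ".npy")
  m <- matrix(rnorm(12), 3, 4)
  npy_save(m, p)
  expect_identical(npy_load(p), m)
  v <- rnorm(7)
  npy_save(v, p)
  expect_identical(npy_load(p), v)
  npy_save(c(1, -5, 2^40), p, dtype = "i8")
  expect_equal(npy_load(p), c(1, -5, 2^40))
  writeBin(as.raw(1:20), p)
  expect_error(npy_load(p), "magic")
})
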