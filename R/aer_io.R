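#' Address-event stream container
#'
#' An `aer_stream` holds a time-sorted sequence of address events — the
#' (timestamp, pixel, polarity) tuples emitted by a silicon retina or by an
#' artificial spike encoder — together with the sensor geometry and any
#' preserved jAER header text. Timestamps are integer microseconds; pixel
#' coordinates are 0-based with the origin at the top-left and y increasing
#' downward; polarity is `1` for ON (intensity increase) and `0` for OFF.
#'
#' @param events data.frame with columns `timestamp_us`, `x`, `y`,
#'   `polarity` (0/1). Rows may be unsorted; they are stably sorted by
#'   timestamp.
#' @param width,height sensor geometry in pixels (default 128 x 128, the
#'   resolution of the DVS recordings the AEDAT files in this domain use).
#' @param header_lines character vector of jAER header lines (each starting
#'   with `#`), preserved verbatim on write.
#' @return an object of class `aer_stream`.
#' @seealso [read_aedat()], [write_aedat()], [stream_to_arrays()]
#' @export
aer_stream <- function(events = empty_events(), width = 128L, height = 128L,
                       header_lines = character()) {
  stopifnot(is.data.frame(events),
            all(c("timestamp_us", "x", "y", "polarity") %in% names(events)))
  if (nrow(events)) {
    if (any(events$timestamp_us < 0))
      stop("negative timestamp in AER events")
    if (any(events$x < 0 | events$x >= width |
            events$y < 0 | events$y >= height))
      stop("event coordinates outside the declared ", width, "x", height,
           " geometry")
    if (!all(events$polarity %in% c(0, 1)))
      stop("polarity must be 0 (OFF) or 1 (ON)")
    events <- events[order(events$timestamp_us), , drop = FALSE]
    rownames(events) <- NULL
  }
  structure(list(events = events, width = as.integer(width),
                 height = as.integer(height), header_lines = header_lines),
            class = "aer_stream")
}

empty_events <- function() {
  data.frame(timestamp_us = numeric(), x = integer(), y = integer(),
             polarity = integer())
}

#' @export
print.aer_stream <- function(x, ...) {
  cat("AER stream:", nrow(x$events), "events,", x$width, "x", x$height,
      "geometry\n")
  if (nrow(x$events))
    cat("  time span:", min(x$events$timestamp_us), "-",
        max(x$events$timestamp_us), "us; ON:",
        sum(x$events$polarity == 1), " OFF:",
        sum(x$events$polarity == 0), "\n")
  if (length(x$header_lines))
    cat("  header:", x$header_lines[1], "\n")
  invisible(x)
}

#' Per-neuron spike-time arrays
#'
#' The simulator-facing stimulus representation: one strictly increasing
#' list of spike times (milliseconds) per neuron. Neuron ids are 0-based;
#' list element `i` holds the times of neuron `i - 1`.
#'
#' @param spikes list of numeric vectors of spike times in ms, one per
#'   neuron, each strictly increasing.
#' @param n_neurons number of neurons (defaults to `length(spikes)`).
#' @param duration_ms nominal stimulus duration; all times must lie in
#'   `[0, duration_ms]`. `NA` means unconstrained (taken as the last spike).
#' @param channel optional polarity channel tag: `"ON"`, `"OFF"` or
#'   `"merged"`.
#' @return an object of class `spike_source_arrays`.
#' @export
spike_source_arrays <- function(spikes, n_neurons = length(spikes),
                                duration_ms = NA_real_, channel = "merged") {
  stopifnot(is.list(spikes))
  if (length(spikes) < n_neurons)
    spikes <- c(spikes, rep(list(numeric()), n_neurons - length(spikes)))
  for (i in seq_along(spikes)) {
    s <- spikes[[i]]
    if (length(s)) {
      if (is.unsorted(s, strictly = TRUE))
        stop("spike times of neuron ", i - 1, " are not strictly increasing")
      if (any(s < 0))
        stop("negative spike time for neuron ", i - 1)
      if (!is.na(duration_ms) && any(s > duration_ms))
        stop("spike time beyond duration_ms for neuron ", i - 1)
    }
  }
  if (is.na(duration_ms))
    duration_ms <- if (any(lengths(spikes) > 0))
      max(unlist(spikes)) else 0
  structure(list(spikes = spikes, n_neurons = as.integer(n_neurons),
                 duration_ms = as.numeric(duration_ms), channel = channel),
            class = "spike_source_arrays")
}

#' @export
print.spike_source_arrays <- function(x, ...) {
  n_sp <- sum(lengths(x$spikes))
  cat("Spike source arrays:", x$n_neurons, "neurons,", n_sp, "spikes over",
      x$duration_ms, "ms (", x$channel, ")\n")
  invisible(x)
}

#' Total spike count of a spike-source-array set
#' @param x a `spike_source_arrays` object.
#' @return integer spike count.
#' @export
n_spikes <- function(x) sum(lengths(x$spikes))

# DVS128 address map: 1 polarity bit (bit 0), 7 bits x (1-7), 7 bits y
# (8-14). Exposed so other sensor encodings can be declared.

#' DVS128-style AER address bit-field map
#'
#' Describes how pixel coordinates and polarity are packed into the AEDAT
#' address word. The default is the DVS128 convention: bit 0 polarity
#' (1 = ON), bits 1-7 the x column, bits 8-14 the y row.
#'
#' @param x_shift,x_mask,y_shift,y_mask,pol_shift,pol_mask bit-field
#'   positions and widths (masks applied after shifting).
#' @param pol_on value of the polarity field that denotes an ON event.
#' @return a list of class `aer_address_map`.
#' @export
aer_address_map <- function(x_shift = 1L, x_mask = 0x7FL,
                            y_shift = 8L, y_mask = 0x7FL,
                            pol_shift = 0L, pol_mask = 0x1L, pol_on = 1L) {
  structure(list(x_shift = x_shift, x_mask = x_mask, y_shift = y_shift,
                 y_mask = y_mask, pol_shift = pol_shift, pol_mask = pol_mask,
                 pol_on = pol_on), class = "aer_address_map")
}

decode_address <- function(addr, map) {
  # addr is a double vector holding unsigned words
  fld <- function(shift, mask) floor(addr / 2^shift) %% (mask + 1)
  list(x = as.integer(fld(map$x_shift, map$x_mask)),
       y = as.integer(fld(map$y_shift, map$y_mask)),
       polarity = as.integer(fld(map$pol_shift, map$pol_mask) == map$pol_on))
}

encode_address <- function(x, y, polarity, map) {
  pol_field <- ifelse(polarity == 1L, map$pol_on,
                      (map$pol_on + 1L) %% (map$pol_mask + 1L))
  x * 2^map$x_shift + y * 2^map$y_shift + pol_field * 2^map$pol_shift
}

#' Read a jAER AEDAT file
#'
#' Decodes jAER format 1.0 (`#!AER-DAT1.0`: 16-bit address + 32-bit
#' microsecond timestamp per record, big-endian) and 2.0 (32-bit address +
#' 32-bit timestamp). The version is auto-detected from the header; a file
#' with no `#` header is read as headerless raw records in the format given
#' by `version`. 32-bit timestamp wrap-around is unwrapped by monotone
#' reconstruction and the number of wraps is reported via a message.
#'
#' @param path path to a `.aedat` / `.dat` file.
#' @param width,height sensor geometry for validation (default 128 x 128).
#' @param address_map an [aer_address_map()]; default DVS128.
#' @param version format assumed for headerless files (`1` or `2`).
#' @return an [aer_stream()].
#' @export
read_aedat <- function(path, width = 128L, height = 128L,
                       address_map = aer_address_map(), version = 2L) {
  raw_all <- readBin(path, "raw", file.size(path))
  # header: leading lines starting with '#'
  pos <- 1L
  header_lines <- character()
  while (pos <= length(raw_all) && raw_all[pos] == as.raw(0x23)) {
    nl <- pos
    while (nl <= length(raw_all) && raw_all[nl] != as.raw(0x0A)) nl <- nl + 1L
    line <- rawToChar(raw_all[pos:min(nl, length(raw_all))])
    header_lines <- c(header_lines, sub("\r?\n?$", "", line))
    pos <- nl + 1L
  }
  if (length(header_lines)) {
    vline <- header_lines[grepl("^#!AER-DAT", header_lines)]
    if (length(vline)) {
      vnum <- sub("^#!AER-DAT([0-9.]+).*", "\\1", vline[1])
      version <- switch(vnum, "1.0" = 1L, "2.0" = 2L,
        stop("unknown AEDAT version '", vnum,
             "' (supported: 1.0, 2.0)"))
    }
  }
  body <- if (pos > length(raw_all)) raw() else raw_all[pos:length(raw_all)]
  rec_size <- if (version == 1L) 6L else 8L
  if (length(body) %% rec_size != 0L)
    stop("truncated AEDAT record: ", length(body) %% rec_size,
         " trailing bytes after byte offset ",
         (pos - 1L) + rec_size * (length(body) %/% rec_size),
         " (record size ", rec_size, ")")
  n <- length(body) %/% rec_size
  if (n == 0L)
    return(aer_stream(width = width, height = height,
                      header_lines = header_lines))
  m <- matrix(as.integer(body), nrow = rec_size)
  be_word <- function(rows) {        # big-endian unsigned word as double
    p <- 2^(8 * (length(rows) - 1):0)
    colSums(m[rows, , drop = FALSE] * p)
  }
  if (version == 1L) {
    addr <- be_word(1:2)
    ts <- be_word(3:6)
  } else {
    addr <- be_word(1:4)
    ts <- be_word(5:8)
  }
  # unwrap 32-bit timestamp rollovers
  d <- diff(ts)
  wraps <- which(d < -2^31)
  if (length(wraps)) {
    off <- numeric(length(ts))
    off[wraps + 1L] <- 2^32
    ts <- ts + cumsum(off)
    message(length(wraps), " timestamp wrap(s) unwrapped in ", path)
  }
  dec <- decode_address(addr, address_map)
  ev <- data.frame(timestamp_us = ts, x = dec$x, y = dec$y,
                   polarity = dec$polarity)
  aer_stream(ev, width = width, height = height, header_lines = header_lines)
}

#' Write a jAER AEDAT file
#'
#' Inverse of [read_aedat()]: emits the stream's preserved header (or a
#' fresh `#!AER-DAT` version line) followed by fixed-size big-endian
#' records. Events are validated against the stream geometry before any
#' byte is written.
#'
#' @param stream an [aer_stream()].
#' @param path output path.
#' @param address_map an [aer_address_map()]; must match the reader's.
#' @param version AEDAT dialect to emit (`1` or `2`); ignored when the
#'   stream carries a `#!AER-DAT` header line, which wins.
#' @return `path`, invisibly.
#' @export
write_aedat <- function(stream, path, address_map = aer_address_map(),
                        version = 2L) {
  stopifnot(inherits(stream, "aer_stream"))
  ev <- stream$events
  if (nrow(ev) &&
      (any(ev$x < 0 | ev$x >= stream$width) ||
       any(ev$y < 0 | ev$y >= stream$height)))
    stop("event outside geometry; nothing written")
  header_lines <- stream$header_lines
  vline <- header_lines[grepl("^#!AER-DAT", header_lines)]
  if (length(vline)) {
    version <- switch(sub("^#!AER-DAT([0-9.]+).*", "\\1", vline[1]),
                      "1.0" = 1L, "2.0" = 2L,
                      stop("unknown AEDAT version in stream header"))
  } else {
    header_lines <- c(sprintf("#!AER-DAT%d.0", version), header_lines)
  }
  con <- file(path, "wb")
  on.exit(close(con))
  for (h in header_lines)
    writeChar(paste0(h, "\r\n"), con, eos = NULL)
  if (nrow(ev)) {
    addr <- encode_address(ev$x, ev$y, ev$polarity, address_map)
    ts <- ev$timestamp_us %% 2^32    # re-wrap for storage
    words_be <- function(v, nbytes) {
      sh <- 2^(8 * (nbytes - 1):0)
      m <- vapply(v, function(w) as.integer(floor(w / sh) %% 256),
                  integer(nbytes))
      as.raw(m)
    }
    a_bytes <- words_be(addr, if (version == 1L) 2L else 4L)
    t_bytes <- words_be(ts, 4L)
    rec_size <- if (version == 1L) 6L else 8L
    buf <- raw(rec_size * nrow(ev))
    a_n <- if (version == 1L) 2L else 4L
    idx <- rep(seq(0L, by = rec_size, length.out = nrow(ev)), each = a_n) +
      seq_len(a_n)
    buf[idx] <- a_bytes
    idx <- rep(seq(0L, by = rec_size, length.out = nrow(ev)), each = 4L) +
      a_n + 1:4
    buf[idx] <- t_bytes
    writeBin(buf, con)
  }
  invisible(path)
}

#' Convert an AER stream to per-neuron spike-source arrays
#'
#' Neuron index is row-major over the sensor grid, `y * width + x` (0-based,
#' origin top-left). Timestamps are converted from microseconds to
#' milliseconds. Exact duplicate times on a neuron are collapsed and the
#' collapse count reported via a message.
#'
#' @param stream an [aer_stream()].
#' @param polarity_mode `"merge"` (all events on one channel), `"split"`
#'   (a list with `on` and `off` sets), or `"drop_off"` (ON events only).
#' @return a [spike_source_arrays()], or a list of two for `"split"`.
#' @export
stream_to_arrays <- function(stream,
                             polarity_mode = c("merge", "split", "drop_off")) {
  polarity_mode <- match.arg(polarity_mode)
  stopifnot(inherits(stream, "aer_stream"))
  build <- function(ev, channel) {
    n <- stream$width * stream$height
    spikes <- rep(list(numeric()), n)
    dup <- 0L
    if (nrow(ev)) {
      idx <- ev$y * stream$width + ev$x + 1L
      t_ms <- ev$timestamp_us / 1000
      by_n <- split(t_ms, idx)
      for (key in names(by_n)) {
        ts <- sort(by_n[[key]])
        u <- unique(ts)
        dup <- dup + length(ts) - length(u)
        spikes[[as.integer(key)]] <- u
      }
    }
    if (dup > 0L)
      message(dup, " duplicate spike time(s) collapsed")
    dur <- if (nrow(stream$events))
      max(stream$events$timestamp_us) / 1000 else 0
    spike_source_arrays(spikes, n_neurons = n, duration_ms = dur,
                        channel = channel)
  }
  ev <- stream$events
  switch(polarity_mode,
    merge = build(ev, "merged"),
    drop_off = build(ev[ev$polarity == 1L, , drop = FALSE], "ON"),
    split = list(on = build(ev[ev$polarity == 1L, , drop = FALSE], "ON"),
                 off = build(ev[ev$polarity == 0L, , drop = FALSE], "OFF")))
}

#' Convert spike-source arrays back to an AER stream
#'
#' Inverse of [stream_to_arrays()] (up to duplicate collapse): neuron
#' `i` maps to pixel `(x = i %% width, y = i %/% width)` and times are
#' converted ms to microseconds.
#'
#' @param arrays a [spike_source_arrays()] with `width * height` neurons.
#' @param width,height target sensor geometry.
#' @param polarity polarity assigned to every emitted event (`1` ON /
#'   `0` OFF); per-channel sets should be converted separately.
#' @return an [aer_stream()].
#' @export
arrays_to_stream <- function(arrays, width = 128L, height = 128L,
                             polarity = 1L) {
  stopifnot(inherits(arrays, "spike_source_arrays"))
  if (arrays$n_neurons != width * height)
    stop("n_neurons (", arrays$n_neurons, ") does not match geometry ",
         width, "x", height)
  counts <- lengths(arrays$spikes)
  if (sum(counts) == 0L)
    return(aer_stream(width = width, height = height))
  nid <- rep(seq_along(arrays$spikes) - 1L, counts)
  ev <- data.frame(timestamp_us = round(unlist(arrays$spikes) * 1000),
                   x = nid %% width, y = nid %/% width,
                   polarity = as.integer(polarity))
  aer_stream(ev, width = width, height = height)
}

#' Read / write spike-source arrays as NumPy .npy files
#'
#' The ragged per-neuron lists are stored as an `(n_spikes, 2)` float64
#' C-order array of `(neuron_index, spike_time_ms)` rows in the `.npy` file,
#' with `n_neurons`, `duration_ms` and `channel` in a JSON sidecar sharing
#' the file stem (`X.npy` + `X.json`). This keeps the binary file a plain
#' standard NPY array, readable from any NumPy-speaking tool.
#'
#' @param arrays a [spike_source_arrays()].
#' @param path `.npy` path.
#' @return `read_npy_arrays` returns a [spike_source_arrays()];
#'   `write_npy_arrays` returns `path` invisibly.
#' @export
write_npy_arrays <- function(arrays, path) {
  stopifnot(inherits(arrays, "spike_source_arrays"))
  counts <- lengths(arrays$spikes)
  m <- cbind(rep(seq_along(arrays$spikes) - 1, counts),
             unlist(arrays$spikes, use.names = FALSE))
  if (is.null(dim(m)) || nrow(m) == 0L) m <- matrix(numeric(), 0L, 2L)
  npy_save(m, path, dtype = "f8")
  sidecar <- sub("\\.npy$", ".json", path)
  jsonlite::write_json(list(n_neurons = arrays$n_neurons,
                            duration_ms = arrays$duration_ms,
                            channel = arrays$channel),
                       sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_npy_arrays
#' @export
read_npy_arrays <- function(path) {
  m <- npy_load(path)
  if (is.null(dim(m)) && length(m) == 0L) m <- matrix(numeric(), 0L, 2L)
  if (!is.matrix(m) || ncol(m) != 2L)
    stop("malformed spike-source container: expected an (n, 2) array")
  sidecar <- sub("\\.npy$", ".json", path)
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar) else
    list(n_neurons = if (nrow(m)) max(m[, 1]) + 1 else 0,
         duration_ms = NA, channel = "merged")
  n <- as.integer(meta$n_neurons)
  spikes <- rep(list(numeric()), n)
  if (nrow(m)) {
    by_n <- split(m[, 2], as.integer(m[, 1]))
    for (key in names(by_n))
      spikes[[as.integer(key) + 1L]] <- sort(by_n[[key]])
  }
  spike_source_arrays(spikes, n_neurons = n,
                      duration_ms = as.numeric(meta$duration_ms),
                      channel = as.character(meta$channel))
}
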