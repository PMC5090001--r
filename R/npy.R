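#' Minimal NumPy .npy codec
#'
#' Reads and writes the NumPy binary array container (format version 1.0)
#' for the numeric payloads this package exchanges: little-endian float64
#' (`<f8`) and int32/int64 (`<i4`, `<i8`) vectors and matrices, C-order.
#' This covers the spike-source-array and weight-matrix interchange files;
#' it is not a general NPY implementation (no structured dtypes, no
#' Fortran-order output).
#'
#' @param x numeric vector or matrix to store.
#' @param path file path ending in `.npy`.
#' @param dtype one of `"f8"`, `"i4"`, `"i8"`.
#' @return `npy_save` returns `path` invisibly; `npy_load` returns a numeric
#'   vector (1-d arrays) or matrix (2-d arrays).
#' @examples
#' p <- tempfile(fileext = ".npy")
#' npy_save(matrix(1:6, 2, 3), p)
#' npy_load(p)
#' @export
npy_save <- function(x, path, dtype = "f8") {
  if (!dtype %in% c("f8", "i4", "i8"))
    stop("unsupported dtype '", dtype, "' (supported: f8, i4, i8)")
  if (is.matrix(x)) {
    shape <- sprintf("(%d, %d)", nrow(x), ncol(x))
    payload <- as.vector(t(x))           # C-order: row-major
  } else {
    shape <- sprintf("(%d,)", length(x))
    payload <- as.vector(x)
  }
  header <- sprintf("{'descr': '<%s', 'fortran_order': False, 'shape': %s, }",
                    dtype, shape)
  # pad so that 10 + length(header) is a multiple of 64, terminated by \n
  pad <- 64L - ((10L + nchar(header) + 1L) %% 64L)
  if (pad == 64L) pad <- 0L
  header <- paste0(header, strrep(" ", pad), "\n")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x93, utf8ToInt("NUMPY"), 1L, 0L)), con)
  writeBin(as.raw(c(nchar(header) %% 256L, nchar(header) %/% 256L)), con)
  writeChar(header, con, eos = NULL)
  if (dtype == "f8") {
    writeBin(as.double(payload), con, size = 8L, endian = "little")
  } else if (dtype == "i4") {
    writeBin(as.integer(payload), con, size = 4L, endian = "little")
  } else {
    # i8 written via double mantissa; exact for |x| < 2^53
    lo <- payload %% 2^32
    hi <- floor(payload / 2^32)
    buf <- raw(8L * length(payload))
    for (k in seq_along(payload)) {
      w <- c(lo[k] %% 2^8, lo[k] %/% 2^8 %% 2^8, lo[k] %/% 2^16 %% 2^8,
             lo[k] %/% 2^24 %% 2^8,
             hi[k] %% 2^8, hi[k] %/% 2^8 %% 2^8, hi[k] %/% 2^16 %% 2^8,
             hi[k] %/% 2^24 %% 2^8)
      buf[(8L * (k - 1L) + 1L):(8L * k)] <- as.raw(w)
    }
    writeBin(buf, con)
  }
  invisible(path)
}

#' @rdname npy_save
#' @export
npy_load <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 6L)
  if (length(magic) < 6L ||
      !identical(magic, as.raw(c(0x93, utf8ToInt("NUMPY")))))
    stop("not an NPY file: bad magic in ", path)
  ver <- readBin(con, "integer", 2L, size = 1L, signed = FALSE)
  if (ver[1] != 1L)
    stop("unsupported NPY format version ", ver[1], ".", ver[2],
         " (supported: 1.0)")
  hlen <- readBin(con, "integer", 2L, size = 1L, signed = FALSE)
  hlen <- hlen[1] + 256L * hlen[2]
  header <- rawToChar(readBin(con, "raw", hlen))
  descr <- sub(".*'descr':\\s*'([^']+)'.*", "\\1", header)
  fortran <- grepl("'fortran_order':\\s*True", header)
  shape_s <- sub(".*'shape':\\s*\\(([^)]*)\\).*", "\\1", header)
  dims <- as.integer(strsplit(gsub("\\s", "", shape_s), ",")[[1]])
  dims <- dims[!is.na(dims)]
  n <- if (length(dims) == 0L) 1L else prod(dims)
  x <- switch(descr,
    "<f8" = readBin(con, "double", n, size = 8L, endian = "little"),
    "<i4" = as.double(readBin(con, "integer", n, size = 4L,
                              endian = "little")),
    "<i8" = {
      b <- readBin(con, "raw", 8L * n)
      m <- matrix(as.integer(b), nrow = 8L)
      lo <- colSums(m[1:4, , drop = FALSE] * 2^(8 * (0:3)))
      hi <- colSums(m[5:8, , drop = FALSE] * 2^(8 * (0:3)))
      hi <- ifelse(hi >= 2^31, hi - 2^32, hi)  # sign in the high word
      lo + hi * 2^32
    },
    stop("unsupported NPY dtype '", descr, "' in ", path)
  )
  if (length(x) < n)
    stop("malformed NPY container: expected ", n, " elements, got ",
         length(x), " in ", path)
  if (length(dims) == 2L) {
    x <- if (fortran) matrix(x, dims[1], dims[2])
         else t(matrix(x, dims[2], dims[1]))
  } else if (length(dims) > 2L) {
    stop("NPY arrays with >2 dimensions are not supported")
  }
  x
}
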