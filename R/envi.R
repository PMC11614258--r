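# ENVI cube I/O: text header (.hdr) + flat binary, interleaves bil/bip/bsq.
# Data types follow the ENVI convention: 1 = uint8, 2 = int16, 3 = int32,
# 4 = float32, 5 = float64, 12 = uint16.

envi_dtypes <- list(
  `1`  = list(what = "integer", size = 1L, signed = FALSE),
  `2`  = list(what = "integer", size = 2L, signed = TRUE),
  `3`  = list(what = "integer", size = 4L, signed = TRUE),
  `4`  = list(what = "double",  size = 4L, signed = TRUE),
  `5`  = list(what = "double",  size = 8L, signed = TRUE),
  `12` = list(what = "integer", size = 2L, signed = FALSE)
)

parse_envi_header <- function(header_path) {
  lines <- readLines(header_path, warn = FALSE)
  fields <- list()
  i <- 1L
  while (i <= length(lines)) {
    ln <- lines[[i]]
    if (!grepl("=", ln)) { i <- i + 1L; next }
    key <- tolower(trimws(sub("=.*$", "", ln)))
    val <- trimws(sub("^[^=]*=", "", ln))
    if (startsWith(val, "{")) {
      while (!grepl("\\}", val) && i < length(lines)) {
        i <- i + 1L
        val <- paste(val, trimws(lines[[i]]))
      }
      val <- gsub("[{}]", "", val)
    }
    fields[[key]] <- trimws(val)
    i <- i + 1L
  }
  fields
}

header_int <- function(fields, key) {
  if (is.null(fields[[key]])) {
    abort(sprintf("ENVI header is missing required field '%s'", key),
          class = "avicube_error_format")
  }
  v <- suppressWarnings(as.integer(fields[[key]]))
  if (is.na(v)) {
    abort(sprintf("ENVI header field '%s' is not an integer: '%s'",
                  key, fields[[key]]), class = "avicube_error_format")
  }
  v
}

find_envi_binary <- function(header_path, interleave) {
  stem <- sub("\\.hdr$", "", header_path, ignore.case = TRUE)
  cand <- c(stem, paste0(stem, c(paste0(".", interleave),
                                 ".raw", ".img", ".dat", ".bil", ".bip", ".bsq")))
  cand <- cand[file.exists(cand) & cand != header_path]
  if (!length(cand)) {
    abort(sprintf("no binary companion found for '%s'", header_path),
          class = "avicube_error_format")
  }
  cand[[1]]
}

#' Read an ENVI hyperspectral cube
#'
#' Parses the text header, then decodes the companion binary in its declared
#' interleave (`bil`, `bip` or `bsq`) into the in-memory
#' `(line, sample, band)` layout. Wavelengths in micrometre headers are
#' converted to nm. The binary's byte count must match the header exactly.
#'
#' @param header_path Path to the `.hdr` text header. The binary is looked
#'   up next to it (same stem, common extensions).
#' @return A [hypercube].
#' @export
read_envi <- function(header_path) {
  if (!file.exists(header_path)) {
    abort(sprintf("header not found: %s", header_path),
          class = "avicube_error_io")
  }
  f <- parse_envi_header(header_path)
  samples <- header_int(f, "samples")
  lines_n <- header_int(f, "lines")
  bands <- header_int(f, "bands")
  if (is.null(f[["interleave"]])) {
    abort("ENVI header is missing required field 'interleave'",
          class = "avicube_error_format")
  }
  interleave <- tolower(f[["interleave"]])
  if (!interleave %in% c("bil", "bip", "bsq")) {
    abort(sprintf("unsupported interleave '%s'", interleave),
          class = "avicube_error_format")
  }
  dtype <- envi_dtypes[[as.character(header_int(f, "data type"))]]
  if (is.null(dtype)) {
    abort(sprintf("unsupported ENVI data type %s", f[["data type"]]),
          class = "avicube_error_format")
  }
  if (is.null(f[["wavelength"]])) {
    abort("ENVI header is missing required field 'wavelength'",
          class = "avicube_error_format")
  }
  wl <- as.numeric(strsplit(f[["wavelength"]], ",")[[1]])
  units <- tolower(f[["wavelength units"]] %||% "nanometers")
  if (grepl("micro|um|µm", units)) wl <- wl * 1000
  if (length(wl) != bands) {
    abort(sprintf("header declares %d bands but %d wavelengths",
                  bands, length(wl)), class = "avicube_error_format")
  }
  offset <- if (!is.null(f[["header offset"]])) header_int(f, "header offset") else 0L
  endian <- if (!is.null(f[["byte order"]]) && header_int(f, "byte order") == 1L)
    "big" else "little"

  bin_path <- find_envi_binary(header_path, interleave)
  n <- as.double(samples) * lines_n * bands
  expected <- offset + n * dtype$size
  actual <- file.size(bin_path)
  if (!isTRUE(actual == expected)) {
    abort(sprintf(
      "binary '%s' has %.0f bytes; header implies %.0f (corrupt or wrong interleave/type)",
      bin_path, actual, expected), class = "avicube_error_corrupt")
  }
  con <- file(bin_path, "rb")
  on.exit(close(con))
  if (offset > 0) readBin(con, "raw", n = offset)
  v <- readBin(con, what = dtype$what, n = n, size = dtype$size,
               signed = dtype$signed, endian = endian)
  arr <- switch(interleave,
    bsq = aperm(array(v, dim = c(samples, lines_n, bands)), c(2, 1, 3)),
    bil = aperm(array(v, dim = c(samples, bands, lines_n)), c(3, 1, 2)),
    bip = aperm(array(v, dim = c(bands, samples, lines_n)), c(3, 2, 1)))
  meta <- f[setdiff(names(f), c("samples", "lines", "bands", "interleave",
                                "data type", "wavelength", "header offset",
                                "byte order"))]
  hypercube(arr, wl, meta = meta)
}

#' Write a cube to ENVI header + binary
#'
#' The inverse of [read_envi()]: lossless round-trips are guaranteed for all
#' three interleaves when `data_type = 5` (float64) and exact for float32
#' data written with the default `data_type = 4`.
#'
#' @param cube A [hypercube].
#' @param header_path Output `.hdr` path; the binary is written next to it
#'   as `<stem>.<interleave>`.
#' @param interleave One of `"bil"` (default), `"bip"`, `"bsq"`.
#' @param data_type ENVI data type code: 4 (float32, default) or 5 (float64).
#' @return Invisibly, the binary path.
#' @export
write_envi <- function(cube, header_path, interleave = "bil", data_type = 4) {
  stopifnot(inherits(cube, "hypercube"))
  interleave <- match.arg(interleave, c("bil", "bip", "bsq"))
  if (!as.character(data_type) %in% c("4", "5")) {
    abort("writer supports data_type 4 (float32) or 5 (float64)",
          class = "avicube_error_format")
  }
  d <- dim(cube$data)
  dtype <- envi_dtypes[[as.character(data_type)]]
  stem <- sub("\\.hdr$", "", header_path, ignore.case = TRUE)
  bin_path <- paste0(stem, ".", interleave)

  hdr <- c(
    "ENVI",
    sprintf("samples = %d", d[2]),
    sprintf("lines = %d", d[1]),
    sprintf("bands = %d", d[3]),
    "header offset = 0",
    "file type = ENVI Standard",
    sprintf("data type = %d", as.integer(data_type)),
    sprintf("interleave = %s", interleave),
    "byte order = 0",
    "wavelength units = Nanometers",
    if (length(cube$meta))
      sprintf("%s = %s", names(cube$meta), unlist(cube$meta)),
    sprintf("wavelength = {%s}",
            paste(format(cube$wavelengths, trim = TRUE, scientific = FALSE,
                         digits = 12), collapse = ", ")))
  tryCatch(writeLines(hdr, header_path),
           error = function(e) abort(sprintf("cannot write '%s'", header_path),
                                     class = "avicube_error_io"))
  arr <- switch(interleave,
    bsq = aperm(cube$data, c(2, 1, 3)),
    bil = aperm(cube$data, c(2, 3, 1)),
    bip = aperm(cube$data, c(3, 2, 1)))
  con <- file(bin_path, "wb")
  on.exit(close(con))
  writeBin(as.double(as.vector(arr)), con, size = dtype$size,
           endian = "little")
  invisible(bin_path)
}
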