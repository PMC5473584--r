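#' @title Codec registry and binary record layout
#'
#' @description
#' Every custom-encoded MMTF column is stored as a binary record: a 12-byte
#' header of three 4-byte signed big-endian integers -- codec type, data
#' length (the number of *decoded* values) and a codec parameter (e.g. a
#' fixed-point divisor or a string width) -- followed by the big-endian
#' payload. The registry maps the 15 numbered codec strategies of the MMTF
#' format specification v1.0 to compositions of the primitives in
#' `codec-core`.
#'
#' @name codec-registry
NULL

# ---- big-endian byte packing -------------------------------------------
# Manual two's complement packing: R's writeBin cannot represent INT32_MIN
# (it is the integer NA), and readBin misreads it, so bytes are assembled
# arithmetically from doubles.

.pack_ints <- function(x, width) {
  if (length(x) == 0L) return(raw(0))
  off <- 2^(8 * width)
  v <- ifelse(x < 0, x + off, x)
  pow <- 256^((width - 1L):0)
  m <- vapply(pow, function(p) (v %/% p) %% 256, numeric(length(v)))
  if (is.null(dim(m))) m <- matrix(m, nrow = 1L)
  as.raw(as.vector(t(m)))
}

.unpack_ints <- function(bytes, width, signed = TRUE) {
  if (length(bytes) == 0L) return(numeric(0))
  if (length(bytes) %% width != 0L) {
    stop("mmtf format error: payload length is not a multiple of the element width", call. = FALSE)
  }
  u <- as.integer(bytes)
  m <- matrix(u, nrow = width)
  pow <- 256^((width - 1L):0)
  v <- colSums(m * pow)
  if (signed) {
    half <- 2^(8 * width - 1L)
    v <- ifelse(v >= half, v - 2^(8 * width), v)
  }
  v
}

.pack_floats <- function(x) {
  writeBin(as.numeric(x), raw(), size = 4L, endian = "big")
}

.unpack_floats <- function(bytes) {
  if (length(bytes) %% 4L != 0L) {
    stop("mmtf format error: float payload length is not a multiple of 4", call. = FALSE)
  }
  readBin(bytes, "numeric", n = length(bytes) %/% 4L, size = 4L, endian = "big")
}

.chars_to_ints <- function(chars) {
  vapply(chars, function(s) {
    if (is.na(s) || !nzchar(s)) 0 else as.numeric(utf8ToInt(substr(s, 1L, 1L)))
  }, numeric(1), USE.NAMES = FALSE)
}

.ints_to_chars <- function(ints) {
  vapply(ints, function(i) if (i == 0) "" else intToUtf8(i), character(1))
}

.pack_strings <- function(strings, width) {
  if (length(strings) == 0L) return(raw(0))
  out <- raw(length(strings) * width)
  for (i in seq_along(strings)) {
    b <- charToRaw(strings[i])
    if (length(b) > width) {
      stop(sprintf("mmtf range error: string '%s' exceeds fixed width %d", strings[i], width), call. = FALSE)
    }
    if (length(b) > 0L) out[((i - 1L) * width + 1L):((i - 1L) * width + length(b))] <- b
  }
  out
}

.unpack_strings <- function(bytes, width) {
  if (length(bytes) == 0L) return(character(0))
  if (length(bytes) %% width != 0L) {
    stop("mmtf format error: string payload length is not a multiple of the field width", call. = FALSE)
  }
  n <- length(bytes) %/% width
  vapply(seq_len(n), function(i) {
    b <- bytes[((i - 1L) * width + 1L):(i * width)]
    b <- b[b != as.raw(0L)]
    rawToChar(b)
  }, character(1))
}

# ---- codec table --------------------------------------------------------
# Each entry: kind of decoded column, payload element width, encode to a
# numeric element stream, decode back given the codec parameter.

.codec_table <- list(
  `1`  = list(name = "float32_passthrough",        kind = "float",  width = 4L),
  `2`  = list(name = "int8_passthrough",           kind = "int",    width = 1L),
  `3`  = list(name = "int16_passthrough",          kind = "int",    width = 2L),
  `4`  = list(name = "int32_passthrough",          kind = "int",    width = 4L),
  `5`  = list(name = "string_fixed_width",         kind = "string", width = NA_integer_),
  `6`  = list(name = "rle_char",                   kind = "char",   width = 4L),
  `7`  = list(name = "rle_int32",                  kind = "int",    width = 4L),
  `8`  = list(name = "delta_rle_int32",            kind = "int",    width = 4L),
  `9`  = list(name = "fixedpoint_rle_float",       kind = "float",  width = 4L),
  `10` = list(name = "fixedpoint_delta_rix16",     kind = "float",  width = 2L),
  `11` = list(name = "fixedpoint_int16",           kind = "float",  width = 2L),
  `12` = list(name = "fixedpoint_rix16",           kind = "float",  width = 2L),
  `13` = list(name = "fixedpoint_rix8",            kind = "float",  width = 1L),
  `14` = list(name = "rix16_int32",                kind = "int",    width = 2L),
  `15` = list(name = "rix8_int32",                 kind = "int",    width = 1L)
)

.codec_info <- function(codec_type) {
  info <- .codec_table[[as.character(codec_type)]]
  if (is.null(info)) {
    stop(sprintf("mmtf unknown-codec error: codec type %s is not registered", codec_type), call. = FALSE)
  }
  info
}

.check_int_range <- function(x, width, codec) {
  lim <- 2^(8 * width - 1L)
  if (length(x) > 0L && (max(x) >= lim || min(x) < -lim)) {
    stop(sprintf("mmtf range error: encoded value outside signed %d-bit range for codec %d",
                 8L * width, codec), call. = FALSE)
  }
  x
}

#' Construct a codec record header
#'
#' @param codec_type integer codec identifier (1-15).
#' @param data_length number of decoded values.
#' @param codec_parameter strategy-specific integer (divisor, string width);
#'   0 when unused.
#' @return an object of class `mmtf_codec_header`.
#' @export
codec_header <- function(codec_type, data_length, codec_parameter = 0L) {
  stopifnot(data_length >= 0)
  structure(list(codec_type = as.integer(codec_type),
                 data_length = as.numeric(data_length),
                 codec_parameter = as.integer(codec_parameter)),
            class = "mmtf_codec_header")
}

#' Pack an encoded element stream into a binary record
#'
#' Emits the 12-byte big-endian header followed by the payload at the
#' codec's element width.
#'
#' @param header an [codec_header()] object.
#' @param encoded_values numeric element stream (or character vector for the
#'   string codec) already transformed by the codec's primitive pipeline.
#' @return raw vector, `12 + element_width * element_count` bytes.
#' @export
pack_record <- function(header, encoded_values) {
  stopifnot(inherits(header, "mmtf_codec_header"))
  info <- .codec_info(header$codec_type)
  payload <- switch(info$kind,
    float = if (header$codec_type == 1L) .pack_floats(encoded_values)
            else .pack_ints(.check_int_range(encoded_values, info$width, header$codec_type), info$width),
    int    = .pack_ints(.check_int_range(encoded_values, info$width, header$codec_type), info$width),
    char   = .pack_ints(encoded_values, info$width),
    string = .pack_strings(encoded_values, header$codec_parameter)
  )
  c(.pack_ints(c(header$codec_type, header$data_length, header$codec_parameter), 4L), payload)
}

#' Unpack a binary record into header and element stream
#'
#' @param bytes raw vector holding one encoded record.
#' @return list with elements `header` (an `mmtf_codec_header`) and `values`
#'   (the raw element stream, before the primitive pipeline is inverted).
#' @export
unpack_record <- function(bytes) {
  if (!is.raw(bytes) || length(bytes) < 12L) {
    stop("mmtf truncation error: encoded record shorter than the 12-byte header", call. = FALSE)
  }
  h <- .unpack_ints(bytes[1:12], 4L)
  if (h[2L] < 0) stop("mmtf format error: negative data length in record header", call. = FALSE)
  header <- codec_header(h[1L], h[2L], h[3L])
  info <- .codec_info(header$codec_type)
  payload <- bytes[-(1:12)]
  values <- switch(info$kind,
    float  = if (header$codec_type == 1L) .unpack_floats(payload) else .unpack_ints(payload, info$width),
    int    = .unpack_ints(payload, info$width),
    char   = .unpack_ints(payload, info$width),
    string = .unpack_strings(payload, header$codec_parameter)
  )
  list(header = header, values = values)
}

#' Encode a column into a complete binary record
#'
#' Applies the registered primitive pipeline for `codec_type` (for example,
#' coordinates under codec 10: fixed-point integer encoding, delta encoding,
#' recursive indexing into 16-bit integers) and packs the result behind its
#' 12-byte header.
#'
#' @param values numeric, character (single chars for char codecs, strings
#'   for codec 5) column.
#' @param codec_type integer codec identifier (1-15).
#' @param codec_parameter divisor for fixed-point codecs, field width for
#'   codec 5; ignored otherwise.
#' @return raw vector holding the full record.
#' @export
encode_column <- function(values, codec_type, codec_parameter = 0L) {
  info <- .codec_info(codec_type)
  n <- length(values)
  if (info$kind %in% c("float", "int")) {
    if (!is.numeric(values)) stop("mmtf type error: numeric column required for this codec", call. = FALSE)
  } else if (!is.character(values)) {
    stop("mmtf type error: character column required for this codec", call. = FALSE)
  }
  param <- as.integer(codec_parameter)
  enc <- switch(as.character(codec_type),
    `1`  = values,
    `2`  = .check_int32(values, "int8 column"),
    `3`  = values,
    `4`  = .check_int32(values, "int32 column"),
    `5`  = { if (param <= 0L) param <- 4L; values },
    `6`  = rle_encode(.chars_to_ints(values)),
    `7`  = rle_encode(values),
    `8`  = rle_encode(delta_encode(values)),
    `9`  = rle_encode(integer_encode(values, param)),
    `10` = recursive_index_encode(delta_encode(integer_encode(values, param)), 16L),
    `11` = integer_encode(values, param),
    `12` = recursive_index_encode(integer_encode(values, param), 16L),
    `13` = recursive_index_encode(integer_encode(values, param), 8L),
    `14` = recursive_index_encode(values, 16L),
    `15` = recursive_index_encode(values, 8L)
  )
  pack_record(codec_header(codec_type, n, param), enc)
}

#' Decode a binary record into its column
#'
#' Exact inverse of [encode_column()] for lossless codecs; within half a
#' quantum (`1 / (2 * divisor)`) for the fixed-point codecs.
#'
#' @param record raw vector holding one encoded record.
#' @return the decoded column (numeric or character), with attributes
#'   `codec_type` and `codec_parameter`.
#' @export
decode_column <- function(record) {
  rec <- unpack_record(record)
  h <- rec$header
  v <- rec$values
  param <- h$codec_parameter
  out <- switch(as.character(h$codec_type),
    `1`  = v,
    `2`  = v,
    `3`  = v,
    `4`  = v,
    `5`  = v,
    `6`  = .ints_to_chars(rle_decode(v)),
    `7`  = rle_decode(v),
    `8`  = delta_decode(rle_decode(v)),
    `9`  = integer_decode(rle_decode(v), param),
    `10` = integer_decode(delta_decode(recursive_index_decode(v, 16L)), param),
    `11` = integer_decode(v, param),
    `12` = integer_decode(recursive_index_decode(v, 16L), param),
    `13` = integer_decode(recursive_index_decode(v, 8L), param),
    `14` = recursive_index_decode(v, 16L),
    `15` = recursive_index_decode(v, 8L)
  )
  if (length(out) != h$data_length) {
    stop(sprintf("mmtf format error: codec %d record decoded to %d values but header declares %.0f",
                 h$codec_type, length(out), h$data_length), call. = FALSE)
  }
  attr(out, "codec_type") <- h$codec_type
  attr(out, "codec_parameter") <- param
  out
}
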