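# Minimal MessagePack (version 5) encoder/decoder.
#
# The container format stores the document as a MessagePack map; no
# MessagePack library ships with the R stack this package targets, so the
# subset needed here (nil, booleans, integers, float32/float64, str, bin,
# array, map) is implemented directly. All multi-byte values are big-endian
# as the wire format mandates.
#
# Mapping between R values and wire types:
#   NULL                -> nil
#   logical scalar      -> bool
#   integral double/int -> smallest int representation
#   other double        -> float64
#   character scalar    -> str
#   raw vector          -> bin
#   unnamed list        -> array
#   named list          -> map (keys are the names, as str)
# Atomic vectors of length != 1 must be wrapped with as.list() by the caller;
# the container layer does this for all array-valued fields so that a
# one-element list still serializes as an array.

.mp_uint_bytes <- function(x, width) .pack_ints(x, width)

mp_pack <- function(x) {
  if (is.null(x)) return(as.raw(0xc0))
  if (is.raw(x)) {
    n <- length(x)
    if (n < 256) return(c(as.raw(c(0xc4, n)), x))
    if (n < 65536) return(c(as.raw(0xc5), .mp_uint_bytes(n, 2L), x))
    return(c(as.raw(0xc6), .mp_uint_bytes(n, 4L), x))
  }
  if (is.list(x)) {
    nm <- names(x)
    if (!is.null(nm) && all(nzchar(nm))) {
      n <- length(x)
      head <- if (n < 16) as.raw(bitwOr(0x80L, n))
              else if (n < 65536) c(as.raw(0xde), .mp_uint_bytes(n, 2L))
              else c(as.raw(0xdf), .mp_uint_bytes(n, 4L))
      body <- lapply(seq_len(n), function(i) c(mp_pack(nm[i]), mp_pack(x[[i]])))
      return(c(head, unlist(body, use.names = FALSE)))
    }
    n <- length(x)
    head <- if (n < 16) as.raw(bitwOr(0x90L, n))
            else if (n < 65536) c(as.raw(0xdc), .mp_uint_bytes(n, 2L))
            else c(as.raw(0xdd), .mp_uint_bytes(n, 4L))
    body <- lapply(x, mp_pack)
    return(c(head, unlist(body, use.names = FALSE)))
  }
  if (length(x) != 1L) {
    stop("mmtf serialization error: atomic vector of length != 1 must be wrapped in a list", call. = FALSE)
  }
  if (is.logical(x)) {
    if (is.na(x)) return(as.raw(0xc0))
    return(as.raw(if (x) 0xc3 else 0xc2))
  }
  if (is.character(x)) {
    if (is.na(x)) return(as.raw(0xc0))
    b <- charToRaw(enc2utf8(x))
    n <- length(b)
    head <- if (n < 32) as.raw(bitwOr(0xa0L, n))
            else if (n < 256) as.raw(c(0xd9, n))
            else if (n < 65536) c(as.raw(0xda), .mp_uint_bytes(n, 2L))
            else c(as.raw(0xdb), .mp_uint_bytes(n, 4L))
    return(c(head, b))
  }
  if (is.numeric(x)) {
    if (is.na(x)) return(as.raw(0xc0))
    if (is.finite(x) && x == floor(x) && abs(x) < 2^53) {
      v <- as.numeric(x)
      if (v >= 0) {
        if (v < 128) return(as.raw(v))
        if (v < 256) return(c(as.raw(0xcc), as.raw(v)))
        if (v < 65536) return(c(as.raw(0xcd), .mp_uint_bytes(v, 2L)))
        if (v < 2^32) return(c(as.raw(0xce), .mp_uint_bytes(v, 4L)))
        return(c(as.raw(0xcf), .mp_uint_bytes(v, 8L)))
      }
      if (v >= -32) return(as.raw(256 + v))
      if (v >= -128) return(c(as.raw(0xd0), .pack_ints(v, 1L)))
      if (v >= -32768) return(c(as.raw(0xd1), .pack_ints(v, 2L)))
      if (v >= -2^31) return(c(as.raw(0xd2), .pack_ints(v, 4L)))
      return(c(as.raw(0xd3), .pack_ints(v, 8L)))
    }
    return(c(as.raw(0xcb), writeBin(as.numeric(x), raw(), size = 8L, endian = "big")))
  }
  stop(sprintf("mmtf serialization error: cannot serialize object of class %s", class(x)[1L]), call. = FALSE)
}

# Decoder: returns list(value=, pos=) internally; mp_unpack returns the value.
.mp_read <- function(bytes, pos) {
  if (pos > length(bytes)) stop("mmtf format error: truncated MessagePack stream", call. = FALSE)
  b <- as.integer(bytes[pos])
  pos <- pos + 1L

  take <- function(n) {
    if (n == 0L) return(raw(0))
    if (pos + n - 1L > length(bytes)) stop("mmtf format error: truncated MessagePack stream", call. = FALSE)
    out <- bytes[pos:(pos + n - 1L)]
    pos <<- pos + n
    out
  }
  read_uint <- function(w) .unpack_ints(take(w), w, signed = FALSE)
  read_int <- function(w) .unpack_ints(take(w), w, signed = TRUE)

  read_array <- function(n) {
    out <- vector("list", n)
    for (i in seq_len(n)) {
      r <- .mp_read(bytes, pos)
      out[i] <- list(r$value)  # [[<- would drop a NULL value
      pos <<- r$pos
    }
    out
  }
  read_map <- function(n) {
    out <- vector("list", n)
    nms <- character(n)
    for (i in seq_len(n)) {
      k <- .mp_read(bytes, pos); pos <<- k$pos
      v <- .mp_read(bytes, pos); pos <<- v$pos
      nms[i] <- as.character(k$value)
      out[i] <- list(v$value)
    }
    names(out) <- nms
    out
  }

  value <-
    if (b < 0x80) b
    else if (b >= 0xe0) b - 256L
    else if (b >= 0x80 && b <= 0x8f) read_map(b - 0x80L)
    else if (b >= 0x90 && b <= 0x9f) read_array(b - 0x90L)
    else if (b >= 0xa0 && b <= 0xbf) rawToChar(take(b - 0xa0L))
    else switch(sprintf("%02x", b),
      "c0" = NULL,
      "c2" = FALSE,
      "c3" = TRUE,
      "c4" = take(read_uint(1L)),
      "c5" = take(read_uint(2L)),
      "c6" = take(read_uint(4L)),
      "ca" = readBin(take(4L), "numeric", n = 1L, size = 4L, endian = "big"),
      "cb" = readBin(take(8L), "numeric", n = 1L, size = 8L, endian = "big"),
      "cc" = read_uint(1L),
      "cd" = read_uint(2L),
      "ce" = read_uint(4L),
      "cf" = read_uint(8L),
      "d0" = read_int(1L),
      "d1" = read_int(2L),
      "d2" = read_int(4L),
      "d3" = read_int(8L),
      "d9" = rawToChar(take(read_uint(1L))),
      "da" = rawToChar(take(read_uint(2L))),
      "db" = rawToChar(take(read_uint(4L))),
      "dc" = read_array(read_uint(2L)),
      "dd" = read_array(read_uint(4L)),
      "de" = read_map(read_uint(2L)),
      "df" = read_map(read_uint(4L)),
      stop(sprintf("mmtf format error: unsupported MessagePack type byte 0x%02x", b), call. = FALSE)
    )
  list(value = value, pos = pos)
}

mp_unpack <- function(bytes) {
  if (!is.raw(bytes) || length(bytes) == 0L) {
    stop("mmtf format error: not a MessagePack stream", call. = FALSE)
  }
  r <- .mp_read(bytes, 1L)
  if (r$pos != length(bytes) + 1L) {
    stop("mmtf format error: trailing bytes after MessagePack value", call. = FALSE)
  }
  r$value
}
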