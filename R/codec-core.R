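#' @title Columnar codec primitives
#'
#' @description
#' The primitive, composable transforms used by the MMTF columnar codecs:
#' fixed-point integer encoding, delta encoding, run-length encoding and
#' recursive indexing, together with their exact inverses. All functions
#' operate on plain numeric vectors holding integer values; doubles are used
#' as the carrier type so that intermediate sums near the 32-bit boundary do
#' not overflow R's native integer type. Every encoder checks the signed
#' 32-bit range explicitly.
#'
#' @name codec-core
NULL

.INT32_MAX <- 2147483647
.INT32_MIN <- -2147483648

# Range guard shared by the integer-column primitives.
.check_int32 <- function(x, what) {
  bad <- which(x > .INT32_MAX | x < .INT32_MIN)
  if (length(bad) > 0L) {
    stop(sprintf("mmtf range error: %s overflows the signed 32-bit range at index %d (value %.0f)",
                 what, bad[1L], x[bad[1L]]), call. = FALSE)
  }
  invisible(x)
}

#' Fixed-point integer encoding of real-valued columns
#'
#' Multiplies each value by a power-of-ten divisor and rounds to the nearest
#' integer, half away from zero, making fixed-precision reals losslessly
#' representable as integers (e.g. coordinates at 0.001 A with divisor 1000,
#' temperature factors at 0.01 with divisor 100).
#'
#' Exact decimal `.5` cases are resolved away from zero. Because binary
#' doubles cannot represent most decimal fractions exactly, the scaled value
#' is first rounded at the 6th decimal so that inputs written with up to six
#' decimal digits behave as their decimal reading (e.g. `1.0005 * 1000`
#' encodes to `1001`, not `1000`).
#'
#' @param reals numeric vector.
#' @param divisor positive integer scale factor.
#' @return numeric vector of integer values, same length as `reals`.
#' @examples
#' integer_encode(c(1.000, -12.345), 1000)
#' integer_decode(integer_encode(1.52, 100), 100)
#' @export
integer_encode <- function(reals, divisor) {
  stopifnot(is.numeric(reals), length(divisor) == 1L, divisor >= 1)
  if (length(reals) == 0L) return(numeric(0))
  if (any(!is.finite(reals))) stop("mmtf range error: non-finite value in fixed-point input", call. = FALSE)
  scaled <- round(abs(reals) * divisor, 6)
  out <- sign(reals) * floor(scaled + 0.5)
  out[reals == 0] <- 0
  .check_int32(out, "fixed-point encoded value")
  out
}

#' Inverse of [integer_encode()]
#'
#' @param ints numeric vector of integer values.
#' @param divisor positive integer scale factor.
#' @return numeric vector `ints / divisor`.
#' @export
integer_decode <- function(ints, divisor) {
  stopifnot(is.numeric(ints), length(divisor) == 1L, divisor >= 1)
  ints / divisor
}

#' Delta encoding of integer columns
#'
#' Stores the first value verbatim and every subsequent value as the
#' difference from its predecessor, shrinking the dynamic range of slowly
#' varying columns such as quantized atom coordinates.
#'
#' @param ints numeric vector of integer values.
#' @return numeric vector of the same length.
#' @export
delta_encode <- function(ints) {
  stopifnot(is.numeric(ints))
  if (length(ints) == 0L) return(numeric(0))
  out <- c(ints[1L], diff(ints))
  .check_int32(out, "delta")
  out
}

#' Inverse of [delta_encode()] (prefix sum)
#'
#' @param deltas numeric vector of integer deltas.
#' @return numeric vector of cumulative sums.
#' @export
delta_decode <- function(deltas) {
  stopifnot(is.numeric(deltas))
  if (length(deltas) == 0L) return(numeric(0))
  out <- cumsum(deltas)
  .check_int32(out, "prefix sum")
  out
}

#' Run-length encoding of integer columns
#'
#' Collapses maximal runs of identical values into `(value, count)` pairs,
#' returned as a flat even-length vector. Occupancy columns, which are almost
#' always constant 1.0 in crystal structures, collapse to a single pair.
#'
#' @param ints numeric vector of integer values.
#' @return flat numeric vector alternating value, count.
#' @export
rle_encode <- function(ints) {
  stopifnot(is.numeric(ints))
  n <- length(ints)
  if (n == 0L) return(numeric(0))
  starts <- c(TRUE, ints[-1L] != ints[-n])
  vals <- ints[starts]
  counts <- diff(c(which(starts), n + 1L))
  as.numeric(rbind(vals, counts))
}

#' Inverse of [rle_encode()]
#'
#' @param pairs flat even-length numeric vector of (value, count) pairs.
#' @return expanded numeric vector.
#' @export
rle_decode <- function(pairs) {
  stopifnot(is.numeric(pairs))
  if (length(pairs) == 0L) return(numeric(0))
  if (length(pairs) %% 2L != 0L) {
    stop("mmtf format error: run-length payload has odd length", call. = FALSE)
  }
  vals <- pairs[seq(1L, length(pairs), by = 2L)]
  counts <- pairs[seq(2L, length(pairs), by = 2L)]
  if (any(counts < 1 | counts != floor(counts))) {
    stop("mmtf format error: run-length count must be a positive integer", call. = FALSE)
  }
  rep(vals, counts)
}

.rix_bounds <- function(width) {
  switch(as.character(width),
    "16" = c(-32768, 32767),
    "8"  = c(-128, 127),
    stop("recursive indexing supports widths 16 and 8", call. = FALSE)
  )
}

#' Recursive index encoding into a small signed-integer alphabet
#'
#' Values inside the open interval between the width's bounds are emitted
#' verbatim. A value at or beyond a bound is decomposed into a run of
#' saturated boundary values (32,767 or -32,768 for 16-bit) followed by one
#' non-boundary remainder -- possibly an explicit 0 -- whose sum restores the
#' original value. The remainder doubles as the decoder's stop signal, which
#' is why exact multiples of a bound still carry a trailing 0.
#'
#' @param ints numeric vector of integer values.
#' @param width target width in bits, 16 (default) or 8.
#' @return numeric vector of values within the signed `width`-bit range.
#' @examples
#' recursive_index_encode(c(32867, 100))  # 32767, 100, 100
#' recursive_index_decode(c(32767, 100))  # 32867
#' @export
recursive_index_encode <- function(ints, width = 16L) {
  stopifnot(is.numeric(ints))
  .check_int32(ints, "recursive-index input")
  b <- .rix_bounds(width)
  lo <- b[1L]; up <- b[2L]
  inside <- ints < up & ints > lo
  if (all(inside)) return(as.numeric(ints))
  pieces <- lapply(seq_along(ints), function(i) {
    v <- ints[i]
    if (v < up && v > lo) return(v)
    if (v > 0) {
      k <- v %/% up
      c(rep(up, k), v - k * up)
    } else {
      k <- (-v) %/% (-lo)
      c(rep(lo, k), v - k * lo)
    }
  })
  unlist(pieces, use.names = FALSE)
}

#' Inverse of [recursive_index_encode()]
#'
#' Scans left to right, accumulating while the current element equals a
#' boundary value and closing each group at the first non-boundary element.
#'
#' @param small numeric vector of signed `width`-bit values.
#' @param width source width in bits, 16 (default) or 8.
#' @return numeric vector of reassembled values.
#' @export
recursive_index_decode <- function(small, width = 16L) {
  stopifnot(is.numeric(small))
  if (length(small) == 0L) return(numeric(0))
  b <- .rix_bounds(width)
  boundary <- small == b[1L] | small == b[2L]
  if (boundary[length(small)]) {
    stop("mmtf format error: recursive-index stream ends inside a continued group", call. = FALSE)
  }
  ends <- which(!boundary)
  cs <- cumsum(small)
  out <- cs[ends] - c(0, cs[ends[-length(ends)]])
  .check_int32(out, "recursive-index group sum")
  out
}
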