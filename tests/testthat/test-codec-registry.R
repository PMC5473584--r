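# Binary record layout and the 15-strategy codec table.

test_that("records carry a 12-byte big-endian header", {
  rec <- pack_record(codec_header(4L, 1L, 0L), 1)
  expect_length(rec, 16L)                      # 12-byte header + one int32
  expect_equal(as.integer(rec[1:12]),
               c(0, 0, 0, 4, 0, 0, 0, 1, 0, 0, 0, 0))
  empty <- pack_record(codec_header(4L, 0L, 0L), numeric(0))
  expect_length(empty, 12L)

  u <- unpack_record(rec)
  expect_equal(u$header$codec_type, 4L)
  expect_equal(u$header$data_length, 1)
  expect_equal(u$values, 1)
  expect_error(unpack_record(as.raw(1:5)), "truncation")
  expect_error(pack_record(codec_header(99L, 0L), numeric(0)), "unknown-codec")
  # corrupted payload length
  bad <- c(rec[1:12], rec[13:14])
  expect_error(unpack_record(bad), "multiple of the element width")
})

test_that("encoded records are byte-identical to the reference implementations", {
  # hex strings frozen from the Python reference codecs (mmtf) and
  # MessagePack-independent byte layout checks
  expect_equal(hex_bytes(encode_column(c(1.0, 1.003, 1.005, 34.867), 10L, 1000L)),
               "0000000a00000004000003e803e8000300027fff0447")
  expect_equal(hex_bytes(encode_column(1:10, 8L)),
               "000000080000000a00000000000000010000000a")
  expect_equal(hex_bytes(encode_column(c(rep(1, 5), rep(0.5, 3)), 9L, 100L)),
               "00000009000000080000006400000064000000050000003200000003")
  expect_equal(hex_bytes(encode_column(c("A", "A", "B", "", ""), 6L)),
               "000000060000000500000000000000410000000200000042000000010000000000000002")
  expect_equal(hex_bytes(encode_column(c("A", "B", "CD"), 5L, 4L)),
               "000000050000000300000004410000004200000043440000")
  expect_equal(hex_bytes(encode_column(c(1, -1, 70000), 4L)),
               "00000004000000030000000000000001ffffffff00011170")
  expect_equal(hex_bytes(encode_column(c(1, -1, 7), 2L)),
               "00000002000000030000000001ff07")
})

test_that("coordinate codec reproduces columns within half a quantum", {
  set.seed(5)
  x <- runif(500, -120, 120)
  dec <- decode_column(encode_column(x, 10L, 1000L))
  expect_lte(max(abs(dec - x)), 0.0005)
  # worked example: 2,000 constant occupancies collapse to one pair
  rec <- encode_column(rep(1.0, 2000), 9L, 100L)
  u <- unpack_record(rec)
  expect_equal(u$values, c(100, 2000))
  expect_equal(decode_column(rec), rep(1.0, 2000), ignore_attr = TRUE)
  # serial numbers under delta + run-length: one run of 2,000 unit deltas
  ser <- unpack_record(encode_column(1:2000, 8L))
  expect_equal(ser$values, c(1, 2000))
  expect_equal(decode_column(encode_column(1:2000, 8L)), as.numeric(1:2000),
               ignore_attr = TRUE)
})

test_that("every registered codec round-trips on randomized columns", {
  set.seed(99)
  gen <- list(
    `1` = function(n) sample(seq(-100, 100, by = 0.25), n, TRUE),  # float32-exact   # float32-exact values
    `2` = function(n) sample(-128:127, n, TRUE),
    `3` = function(n) sample(-32768:32767, n, TRUE),
    `4` = function(n) random_int_column(n, 2e9),
    `5` = function(n) vapply(seq_len(n), function(i)
      paste(sample(LETTERS, sample(1:4, 1)), collapse = ""), character(1)),
    `6` = function(n) sample(c("", "A", "B"), n, TRUE),
    `7` = function(n) sample(0:3, n, TRUE),
    `8` = function(n) cumsum(sample(0:2, n, TRUE)),
    `9` = function(n) sample(c(1, 0.5, 0.25), n, TRUE),
    `10` = function(n) round(cumsum(rnorm(n, 0, 2)), 3),
    `11` = function(n) round(runif(n, -30, 30), 2),
    `12` = function(n) round(runif(n, -300, 300), 1),
    `13` = function(n) round(runif(n, -30, 30), 1),
    `14` = function(n) random_int_column(n, 1e5),
    `15` = function(n) random_int_column(n, 300)
  )
  param <- c(`1` = 0, `2` = 0, `3` = 0, `4` = 0, `5` = 4, `6` = 0, `7` = 0,
             `8` = 0, `9` = 100, `10` = 1000, `11` = 100, `12` = 10,
             `13` = 10, `14` = 0, `15` = 0)
  for (codec in names(gen)) {
    for (rep_i in 1:20) {
      n <- sample(0:80, 1)
      x <- gen[[codec]](n)
      rec <- encode_column(x, as.integer(codec), param[[codec]])
      dec <- decode_column(rec)
      attributes(dec) <- NULL
      if (is.numeric(x)) x <- as.numeric(x)
      expect_equal(dec, x, tolerance = 1e-12,
                   info = sprintf("codec %s, n=%d", codec, n))
      # header data length always equals the decoded length
      expect_equal(unpack_record(rec)$header$data_length, length(x))
    }
  }
})

test_that("type and range mismatches are rejected", {
  expect_error(encode_column(c("a"), 4L), "type error")
  expect_error(encode_column(c(1, 2), 6L), "type error")
  expect_error(encode_column(1e10, 4L), "range error")
  expect_error(encode_column(70000, 3L), "range error")
  expect_error(encode_column("TOOLONG", 5L, 4L), "exceeds fixed width")
})
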