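# Primitive transforms: fixed-point, delta, run-length, recursive indexing.

test_that("fixed-point integer encoding applies the stated factors and rounding", {
  expect_equal(integer_encode(1.000, 1000), 1000)
  expect_equal(integer_encode(1.00, 100), 100)
  expect_equal(integer_encode(0.0, 1000), 0)
  # half-away-from-zero at the decimal reading of the input
  expect_equal(integer_encode(1.0005, 1000), 1001)
  expect_equal(integer_encode(-1.0005, 1000), -1001)
  expect_equal(integer_encode(c(12.3456, -0.015), 1000), c(12346, -15))
  # inverse
  expect_equal(integer_decode(1000, 1000), 1.0)
  expect_equal(integer_decode(100, 100), 1.0)
  expect_equal(integer_decode(-12345, 1000), -12.345)
  expect_error(integer_encode(1e7, 1000), "range error.*index 1")
  expect_error(integer_encode(NaN, 10), "range error")
})

test_that("fixed-point encoding is lossless on the divisor grid and half-quantum bounded off it", {
  set.seed(101)
  for (divisor in c(10, 100, 1000)) {
    on_grid <- round(runif(300, -500, 500) * divisor) / divisor
    expect_equal(integer_decode(integer_encode(on_grid, divisor), divisor), on_grid)
    off_grid <- runif(300, -500, 500)
    err <- abs(integer_decode(integer_encode(off_grid, divisor), divisor) - off_grid)
    expect_lte(max(err), 1 / (2 * divisor) + 1e-9)
  }
})

test_that("delta encoding stores first value then differences", {
  expect_equal(delta_encode(c(1000, 1003, 1005)), c(1000, 3, 2))
  expect_equal(delta_encode(5), 5)
  expect_equal(delta_encode(numeric(0)), numeric(0))
  expect_equal(delta_encode(1:2000), c(1, rep(1, 1999)))
  expect_equal(delta_decode(c(1000, 3, 2)), c(1000, 1003, 1005))
  expect_equal(delta_decode(numeric(0)), numeric(0))
  expect_error(delta_decode(c(2e9, 2e9)), "range error")
})

test_that("delta round-trips against the prefix-sum oracle", {
  set.seed(7)
  for (i in 1:50) {
    x <- random_int_column(sample(0:200, 1))
    d <- delta_encode(x)
    expect_equal(delta_decode(d), x)
    expect_equal(delta_decode(d), oracle_prefix_sum(d))
    if (length(d) > 0L) expect_equal(sum(d), x[length(x)])
  }
})

test_that("run-length encoding emits maximal (value, count) pairs", {
  expect_equal(rle_encode(rep(100, 2000)), c(100, 2000))
  expect_equal(rle_encode(numeric(0)), numeric(0))
  expect_equal(rle_encode(c(1, 1, 2)), c(1, 2, 2, 1))
  expect_equal(rle_decode(c(1, 2000)), rep(1, 2000))
  expect_equal(rle_decode(c(7, 1)), 7)
  expect_error(rle_decode(c(1, 2, 3)), "odd length")
  expect_error(rle_decode(c(1, 0)), "positive integer")
})

test_that("run-length invariants hold on random columns", {
  set.seed(11)
  for (i in 1:50) {
    x <- sample(0:4, sample(0:300, 1), replace = TRUE)
    p <- rle_encode(x)
    expect_equal(rle_decode(p), x)
    expect_equal(rle_decode(p), oracle_rle_expand(p))
    if (length(p) > 0L) {
      counts <- p[seq(2, length(p), 2)]
      vals <- p[seq(1, length(p), 2)]
      expect_equal(sum(counts), length(x))
      if (length(vals) > 1L) expect_true(all(vals[-1] != vals[-length(vals)]))
    }
  }
})

test_that("recursive indexing decomposes out-of-range values into saturated runs", {
  expect_equal(recursive_index_encode(32867), c(32767, 100))
  expect_equal(recursive_index_encode(100), 100)
  # an exact boundary needs the explicit 0 terminator
  expect_equal(recursive_index_encode(32767), c(32767, 0))
  expect_equal(recursive_index_encode(-40000), c(-32768, -7232))
  expect_equal(recursive_index_encode(-32768), c(-32768, 0))
  # 1,000,000 = 30 * 32,767 + 16,990: saturated run, then the remainder
  expect_equal(recursive_index_encode(1000000), c(rep(32767, 30), 16990))
  expect_equal(recursive_index_encode(-1000000)[1], -32768)
  expect_equal(recursive_index_decode(c(32767, 100)), 32867)
  expect_equal(recursive_index_decode(c(5, -3)), c(5, -3))
  expect_error(recursive_index_decode(c(100, 32767)), "ends inside a continued group")
  # 8-bit variant
  expect_equal(recursive_index_encode(130, width = 8L), c(127, 3))
  expect_equal(recursive_index_decode(c(127, 3), width = 8L), 130)
})

test_that("recursive indexing round-trips over a dense value grid", {
  grid <- c(seq(-1e6, 1e6, by = 7919), -32769, -32768, -32767, -1, 0, 1,
            32766, 32767, 32768, 65534, 65535, -65536)
  enc <- recursive_index_encode(grid)
  expect_true(all(enc >= -32768 & enc <= 32767))
  expect_equal(recursive_index_decode(enc), grid)
  expect_equal(oracle_rix_decode(enc), grid)
  # per-element groups sum back individually
  for (v in c(32767, 65534, -32768, -100000, 0, 42)) {
    e <- recursive_index_encode(v)
    expect_equal(sum(e), v)
    # elements strictly inside the open interval never continue a group
    if (length(e) > 1L) expect_true(all(e[-length(e)] %in% c(32767, -32768)))
  }
})

test_that("all primitives round-trip on randomized columns", {
  set.seed(42)
  for (i in 1:100) {
    x <- random_int_column(sample(0:100, 1), lim = 5e5)
    expect_identical(delta_decode(delta_encode(x)), x)
    expect_identical(rle_decode(rle_encode(x)), x)
    expect_identical(recursive_index_decode(recursive_index_encode(x)), x)
    expect_identical(recursive_index_decode(recursive_index_encode(x, 8L), 8L), x)
  }
})
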