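test_that("popcount_block counts whole blocks", {
  expect_equal(popcount_block(rep(0L, 64)), 0)
  expect_equal(popcount_block(rep(1L, 512)), 512)
  # value 0b1011: bits set at positions 0, 1, 3
  expect_equal(popcount_block(c(1L, 1L, 0L, 1L, rep(0L, 60))), 3)
  expect_equal(popcount_block(packed_bits(rep(1L, 64))$words), 64)
})

test_that("mask tables satisfy their bit-level invariants", {
  tb <- make_mask_table(64)
  for (j in 0:128) {
    expected <- if (j < 64) as.integer(0:63 >= j) else as.integer(0:63 < j - 64)
    if (!identical(mask_bits(tb, j), expected))
      fail(sprintf("w=64 mask %d wrong", j))
  }
  succeed()
  # boundary masks: pair start, pair boundary, pair end
  expect_equal(sum(mask_bits(tb, 0)), 64)
  expect_equal(sum(mask_bits(tb, 64)), 0)
  expect_equal(sum(mask_bits(tb, 128)), 64)

  tb512 <- make_mask_table(512)
  for (j in c(0, 7, 511, 512, 513, 700, 1024)) {
    expected <- if (j < 512) as.integer(0:511 >= j)
    else as.integer(0:511 < j - 512)
    expect_identical(mask_bits(tb512, j), expected)
  }
  expect_error(make_mask_table(128), class = "bitrank_config_error")
  expect_error(mask_bits(tb, 129), class = "bitrank_range_error")
})

test_that("mask and shift strategies agree with a bit loop, w = 64", {
  tb <- make_mask_table(64)
  set.seed(11)
  for (rep in 1:25) {
    bits <- sample(0:1, 64, replace = TRUE)
    brute <- vapply(0:128, function(j) {
      if (j < 64) sum(bits[(j + 1):64]) else sum(bits[seq_len(j - 64)])
    }, 0)
    mc <- vapply(0:128, function(j) masked_count(bits, tb, j), 0L)
    sc <- vapply(0:128, function(j) shifted_count(bits, j), 0L)
    expect_equal(mc, brute)
    expect_equal(sc, brute)
  }
})

test_that("mask and shift strategies agree with a bit loop, w = 512", {
  tb <- make_mask_table(512)
  set.seed(12)
  for (rep in 1:5) {
    bits <- sample(0:1, 512, replace = TRUE)
    brute <- vapply(0:1024, function(j) {
      if (j < 512) sum(bits[(j + 1):512]) else sum(bits[seq_len(j - 512)])
    }, 0)
    mc <- vapply(0:1024, function(j) masked_count(bits, tb, j), 0L)
    sc <- vapply(0:1024, function(j) shifted_count(bits, j), 0L)
    expect_equal(mc, brute)
    expect_equal(sc, brute)
  }
})

test_that("suffix and within-block prefix counts are complementary", {
  tb <- make_mask_table(64)
  set.seed(13)
  bits <- sample(0:1, 64, replace = TRUE)
  total <- sum(bits)
  for (j in 0:63) {
    prefix_in_left <- sum(bits[seq_len(j)])
    expect_equal(masked_count(bits, tb, j) + prefix_in_left, total)
  }
})

test_that("boundary offsets behave as documented", {
  tb <- make_mask_table(64)
  ones <- rep(1L, 64)
  expect_equal(masked_count(ones, tb, 10), 54)   # left suffix
  expect_equal(masked_count(ones, tb, 74), 10)   # right prefix
  expect_equal(masked_count(ones, tb, 64), 0)    # pair boundary
  expect_equal(shifted_count(rep(0L, 64), 37), 0)
  one_bit <- replace(rep(0L, 64), 23, 1L)        # position 22
  expect_equal(shifted_count(one_bit, 22), 1)
  expect_equal(shifted_count(one_bit, 23), 0)
  expect_equal(shifted_count(one_bit, 64 + 22), 0)
  expect_equal(shifted_count(one_bit, 64 + 23), 1)
  expect_error(masked_count(ones, tb, 129), class = "bitrank_range_error")
  expect_error(shifted_count(ones, 70, side = "left"),
               class = "bitrank_range_error")
})
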