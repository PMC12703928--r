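# Directory entries are re-derived here with plain R prefix sums over the
# raw bits, independently of the C++ builder.

r_block_prefix <- function(bits, n_padded, w1) {
  padded <- c(bits, rep(0L, n_padded - length(bits)))
  nb <- n_padded / w1
  pc <- vapply(seq_len(nb), function(j)
    sum(padded[((j - 1) * w1 + 1):(j * w1)]), 0)
  c(0, cumsum(pc))  # P[j+1] = ones in blocks 0..j-1 (0-based)
}

test_that("directory entries equal brute-force prefix/postfix sums", {
  for (setup in list(list(w1 = 64L, w0 = 256L, n = 1000L, d = 0.5),
                     list(w1 = 512L, w0 = 1024L, n = 3000L, d = 0.2))) {
    bits <- generate_bits(setup$n, setup$d, seed = setup$n)
    for (paired in c(FALSE, TRUE)) {
      cfg <- rank_config(setup$w1, setup$w0, paired = paired)
      v <- rank_bv(bits, cfg)
      P <- r_block_prefix(bits, v$n_padded, setup$w1)
      bpsb <- setup$w0 / setup$w1
      nb <- v$n_padded / setup$w1
      if (!paired) {
        expect_equal(v$L0, P[seq(1, nb, by = bpsb)])
        expect_equal(v$L1, vapply(seq_len(nb) - 1, function(j)
          P[j + 1] - P[(j %/% bpsb) * bpsb + 1], 0))
      } else {
        pairs <- seq_len(nb / bpsb / 2) - 1
        expect_equal(v$L0, P[(2 * pairs + 1) * bpsb + 1])
        expect_equal(v$L1, vapply(seq_len(nb / 2) - 1, function(q) {
          s <- (2 * q) %/% bpsb
          if (s %% 2 == 1) P[2 * q + 2] - P[s * bpsb + 1]
          else P[(s + 1) * bpsb + 1] - P[2 * q + 2]
        }, 0))
      }
      # single-layer counters
      cfg1 <- rank_config(setup$w1, setup$w0, paired = paired, layers = 1L)
      v1 <- rank_bv(bits, cfg1)
      P1 <- r_block_prefix(bits, v1$n_padded, setup$w1)
      if (!paired) expect_equal(v1$L0, P1[seq_len(length(P1) - 1)])
      else expect_equal(v1$L0, P1[seq(2, length(P1) - 1, by = 2)])
    }
  }
})

test_that("rank agrees with the oracle exhaustively at small n", {
  for (n in c(0L, 1L, 65L, 129L, 300L)) {
    bits <- generate_bits(n, 0.4, seed = n + 1L)
    oc <- as.numeric(oracle_rank_bits(bits, 0:n))
    for (w0 in c(256L, 65536L)) {
      for (cfg in bv_config_grid(64L, w0)) {
        expect_equal(rank_query(rank_bv(bits, cfg), 0:n), oc)
      }
    }
  }
  bits <- generate_bits(2600L, 0.6, seed = 99L)
  oc <- as.numeric(oracle_rank_bits(bits, 0:2600))
  for (w0 in c(1024L, 65536L)) {
    for (cfg in bv_config_grid(512L, w0)) {
      expect_equal(rank_query(rank_bv(bits, cfg), 0:2600), oc)
    }
  }
})

test_that("degenerate vectors behave", {
  v0 <- rank_bv(integer(0))
  expect_equal(length(v0$L0), 0)
  expect_equal(rank_query(v0, 0), 0)
  zeros <- rank_bv(rep(0L, 5000), rank_config(512))
  expect_equal(rank_query(zeros, c(0, 1, 2500, 5000)), c(0, 0, 0, 0))
  ones <- rank_bv(rep(1L, 5000), rank_config(512, paired = TRUE))
  expect_equal(rank_query(ones, c(0, 1, 2500, 5000)), c(0, 1, 2500, 5000))
  # all-ones spanning one superblock pair: L0[0] counts the left superblock
  cfgp <- rank_config(64, paired = TRUE)
  vp <- rank_bv(rep(1L, 2 * 65536), cfgp)
  expect_equal(vp$L0[1], 65536)
})

test_that("rank takes unit steps matching the bits", {
  bits <- generate_bits(2000L, 0.5, seed = 21L)
  for (cfg in list(rank_config(64, 256), rank_config(64, 256, paired = TRUE),
                   rank_config(512, 1024, paired = TRUE))) {
    v <- rank_bv(bits, cfg)
    r <- rank_query(v, 0:2000)
    expect_equal(diff(r), as.numeric(bits))
    expect_true(all(diff(r) >= 0))
  }
})

test_that("paired directories store half the entries", {
  for (n in c(2 * 65536L, 4 * 65536L, 100000L)) {
    bits <- generate_bits(n, 0.5, seed = n %% 1000L)
    np <- rank_bv(bits, rank_config(64))
    p <- rank_bv(bits, rank_config(64, paired = TRUE))
    expect_equal(length(p$L1), ceiling(length(np$L1) / 2))
    expect_equal(length(p$L0), ceiling(length(np$L0) / 2))
  }
})

test_that("L1 entries stay below 2^16 even for all-ones input", {
  ones <- rep(1L, 2 * 65536)
  for (paired in c(FALSE, TRUE)) {
    v <- rank_bv(ones, rank_config(64, paired = paired))
    expect_lte(max(v$L1), 65536 - 64)
  }
})

test_that("out-of-range queries and invalid bits error", {
  v <- rank_bv(c(1L, 0L, 1L))
  expect_error(rank_query(v, -1), class = "bitrank_range_error")
  expect_error(rank_query(v, 4), class = "bitrank_range_error")
  expect_error(packed_bits(c(0L, 2L)))
})
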