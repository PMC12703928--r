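# Closed-form accounting must equal both the entry counts of a real build
# and the byte size of its serialized payload.

expect_storage_consistent <- function(x, closed_form) {
  measured <- storage_bits(x)
  expect_equal(measured$total_bits, closed_form$total_bits)
  expect_equal(measured$l0_entries, closed_form$l0_entries)
  expect_equal(measured$l1_entries, closed_form$l1_entries)
  tmp <- tempfile(fileext = ".idx")
  on.exit(unlink(tmp))
  write_index(x, tmp)
  expect_equal(8 * (file.size(tmp) - index_header_bytes(x)),
               measured$total_bits)
}

test_that("bit-vector accounting matches real serialized builds", {
  n <- 10000L
  bits <- generate_bits(n, 0.5, seed = 51)
  for (blk in c(64L, 512L)) for (paired in c(FALSE, TRUE)) {
    cfg <- rank_config(blk, paired = paired)
    expect_storage_consistent(rank_bv(bits, cfg), storage_bits_bv(cfg, n))
  }
  # single-layer layouts account one 64-bit counter per block (pair)
  cfg1 <- rank_config(64, layers = 1, paired = TRUE)
  expect_storage_consistent(rank_bv(bits, cfg1), storage_bits_bv(cfg1, n))
})

test_that("string accounting matches real serialized builds", {
  n <- 10000L
  for (sigma in c(4L, 21L)) {
    txt <- generate_text(n, sigma, seed = 52L + sigma)
    for (kind in c("mbv", "fbv", "pfbv")) for (blk in c(64L, 512L)) {
      x <- string_rank(txt, kind = kind, alphabet = alphabet(sigma),
                       block_bits = blk)
      expect_storage_consistent(
        x, storage_bits_string(kind, n, sigma, block_bits = blk))
    }
  }
})

test_that("derived report fields are recomputable from the components", {
  rep <- storage_bits_string("pfbv", 1e9, 4, block_bits = 512)
  expect_equal(rep$total_bits, rep$payload_bits + rep$dir_bits)
  expect_equal(rep$dir_bits, 64 * rep$l0_entries + 16 * rep$l1_entries)
  expect_equal(rep$bits_per_char,
               bitrank:::round_away(rep$total_bits / rep$n, 3))
  # rounding is half away from zero
  expect_equal(bitrank:::round_away(2.0645, 3), 2.065)
  expect_equal(bitrank:::round_away(12.549, 1), 12.5)
})

test_that("report grids have the documented shape", {
  t1 <- bv_overhead_table(2^20)
  expect_equal(nrow(t1), 4)
  t2 <- string_space_table(1e6, sigmas = c(4, 16))
  expect_equal(dim(t2), c(5, 3))
  expect_true(all(t2$sigma_16 > t2$sigma_4))
})
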