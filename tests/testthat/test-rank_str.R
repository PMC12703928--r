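test_that("alphabets validate and size their code bits", {
  expect_equal(dna_alphabet()$code_bits, 2)
  expect_equal(alphabet(5)$code_bits, 3)
  expect_equal(alphabet(2)$code_bits, 1)
  expect_equal(alphabet(256)$code_bits, 8)
  expect_error(alphabet(1), class = "bitrank_alphabet_error")
  expect_error(alphabet(300), class = "bitrank_alphabet_error")
  expect_error(alphabet(c("A", "A")), class = "bitrank_alphabet_error")
})

test_that("flattened planes scatter the code bits", {
  ft <- encode_text(toy_string, dna_alphabet())
  # plane 0 marks C (01) and T (11); plane 1 marks G (10) and T (11)
  expect_equal(which(get_bits(structure(
    list(n = 8, words = ft$planes[[1]]), class = "packed_bits")) == 1) - 1,
    c(0, 4, 6))
  expect_equal(which(get_bits(structure(
    list(n = 8, words = ft$planes[[2]]), class = "packed_bits")) == 1) - 1,
    c(3, 4, 7))
  # binary alphabet: the single plane is the symbol sequence itself
  ft2 <- encode_text(c(1L, 0L, 1L, 1L), alphabet(2))
  expect_equal(bitrank:::cpp_unpack_bits(ft2$planes[[1]], 4), c(1L, 0L, 1L, 1L))
  # empty text still has k planes
  ft0 <- encode_text(integer(0), alphabet(4))
  expect_length(ft0$planes, 2)
  expect_equal(ft0$n, 0)
  expect_error(encode_text(c(0L, 4L), alphabet(4)),
               class = "bitrank_alphabet_error")
})

test_that("word reconstruction marks exactly the symbol positions", {
  ft <- encode_text(toy_string, dna_alphabet())
  pos_of <- function(sym) which(unpack_word(
    reconstruct_word(ft, sym, 0)) == 1) - 1
  expect_equal(pos_of("C"), c(0, 6))
  expect_equal(pos_of("A"), c(1, 2, 5))
  expect_equal(pos_of("G"), c(3, 7))
  expect_equal(pos_of("T"), 4)
  # complemented padding beyond n never shows up
  expect_equal(sum(vapply(0:3, function(cc) sum(unpack_word(
    reconstruct_word(ft, cc, 1))), 0)), 0)
  # power-of-two alphabet: codes partition every full word
  txt <- generate_text(64, 4, seed = 5)
  ftp <- encode_text(txt, alphabet(4))
  expect_equal(sum(vapply(0:3, function(cc) sum(unpack_word(
    reconstruct_word(ftp, cc, 0))), 0)), 64)
})

test_that("the worked DNA example ranks correctly in every layout", {
  for (kind in c("mbv", "fbv", "pfbv")) for (blk in c(64L, 512L)) {
    s <- string_rank(toy_string, kind = kind, block_bits = blk)
    expect_equal(rank_query(s, 8, "C"), 2)
    expect_equal(rank_query(s, 0:8, "A"),
                 as.numeric(oracle_rank_text(toy_codes, 0:8, 0L)))
    expect_equal(access_symbol(s, 0:7), toy_codes)
    expect_equal(access_symbol(s, 0, as_char = TRUE), "C")
    expect_equal(access_symbol(s, 3, as_char = TRUE), "G")
  }
})

test_that("string rank matches the scanning oracle on random texts", {
  n <- 20000L
  for (sigma in c(4L, 5L, 16L)) {
    txt <- generate_text(n, sigma, seed = sigma)
    ii <- probe_positions(n, rank_config(64), extra = 120, seed = sigma)
    expected <- lapply(0:(sigma - 1), function(cc)
      as.numeric(oracle_rank_text(txt, ii, cc)))
    for (kind in c("mbv", "fbv", "pfbv")) for (blk in c(64L, 512L)) {
      s <- string_rank(txt, kind = kind, block_bits = blk,
                       strategy = if (blk == 64L) "mask" else "shift")
      for (cc in 0:(sigma - 1))
        expect_equal(rank_query(s, ii, cc), expected[[cc + 1]])
    }
  }
})

test_that("ranks over all symbols sum to the prefix length", {
  n <- 10000L
  for (sigma in c(5L, 21L)) {
    txt <- generate_text(n, sigma, seed = 100L + sigma)
    ii <- c(0, 17, 5000, 9999, 10000)
    for (kind in c("mbv", "fbv", "pfbv")) {
      s <- string_rank(txt, kind = kind)
      tot <- Reduce(`+`, lapply(0:(sigma - 1),
                                function(cc) rank_query(s, ii, cc)))
      expect_equal(tot, as.numeric(ii))
    }
  }
})

test_that("string ranks take unit steps at the stored symbols", {
  txt <- generate_text(3000L, 4L, seed = 8)
  s <- string_rank(txt, kind = "pfbv")
  for (cc in 0:3) {
    r <- rank_query(s, 0:3000, cc)
    expect_equal(diff(r), as.numeric(txt == cc))
  }
})

test_that("access round-trips and validates its range", {
  txt <- generate_text(5000L, 21L, seed = 14)
  for (kind in c("mbv", "fbv", "pfbv")) {
    s <- string_rank(txt, kind = kind)
    expect_equal(access_symbol(s, 0:4999), txt)
  }
  s <- string_rank(txt, kind = "fbv")
  expect_error(access_symbol(s, 5000), class = "bitrank_range_error")
  expect_error(rank_query(s, 5001, 0L), class = "bitrank_range_error")
  expect_error(rank_query(s, 10, 21L), class = "bitrank_alphabet_error")
  expect_error(rank_query(s, 10, "Z"), class = "bitrank_alphabet_error")
})

test_that("empty and single-symbol texts work", {
  s <- string_rank(integer(0), kind = "fbv", alphabet = alphabet(4))
  expect_equal(rank_query(s, 0, 2L), 0)
  s2 <- string_rank("G", kind = "pfbv")
  expect_equal(rank_query(s2, 1, "G"), 1)
  expect_equal(rank_query(s2, 1, "A"), 0)
})
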