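#' Build a bit vector with rank support
#'
#' Packs the input bits, zero-pads them to a whole number of superblocks
#' (or superblock pairs, when `config$paired`), and constructs the L0/L1
#' prefix-sum directories in a single pass.
#'
#' In the two-layer paired layout, L0 holds one 64-bit absolute count per
#' superblock pair (the prefix through the end of the pair's *left*
#' superblock) and L1 one 16-bit relative count per block pair: entries in
#' a right superblock are prefix counts from the superblock start through
#' the pair's left block, entries in a left superblock are postfix counts
#' from the pair's right block to the end of the superblock.
#'
#' @param x A logical or 0/1 vector, or a [packed_bits()] object.
#' @param config A [rank_config()].
#' @return An object of class `rank_bv`.
#' @examples
#' v <- rank_bv(rep(c(1, 0), 500), rank_config(64, paired = TRUE))
#' rank_query(v, c(0, 10, 1000))
#' @export
rank_bv <- function(x, config = rank_config()) {
  stopifnot(inherits(config, "rank_config"))
  pb <- packed_bits(x)
  np <- padded_length(config, pb$n)
  words <- pad_words(pb$words, np)
  d <- cpp_build_bv(words, np, config$block_bits, config$superblock_bits,
                    config$paired, config$layers)
  structure(list(n = pb$n, n_padded = np, words = words, config = config,
                 L0 = d$L0, L1 = d$L1, ones = d$ones),
            class = "rank_bv")
}

#' @export
print.rank_bv <- function(x, ...) {
  cat(sprintf("<rank_bv> n = %g (%g ones), %d/%d %s, %d layer(s), %s\n",
              x$n, x$ones, x$config$block_bits, x$config$superblock_bits,
              if (x$config$paired) "paired" else "non-paired",
              x$config$layers, x$config$strategy))
  cat(sprintf("  |L0| = %d, |L1| = %d\n", length(x$L0), length(x$L1)))
  invisible(x)
}

#' Rank query
#'
#' `rank_query(x, i)` returns the number of set bits among the first `i`
#' positions (`i` in `[0, n]`, 0-based prefix length convention, so
#' `rank_query(x, 0) == 0` and `rank_query(x, n)` is the total count).
#' For string structures, `rank_query(x, i, symbol)` counts occurrences of
#' one symbol among the first `i` characters.
#'
#' @param x A `rank_bv` or `string_rank` structure.
#' @param i Vector of prefix lengths in `[0, n]`.
#' @param ... Further arguments passed to methods.
#' @return Numeric vector of counts, one per element of `i`.
#' @export
rank_query <- function(x, i, ...) UseMethod("rank_query")

#' @rdname rank_query
#' @export
rank_query.rank_bv <- function(x, i, ...) {
  if (!is.numeric(i)) abort_range("positions must be numeric")
  if (length(i) && (anyNA(i) || min(i) < 0 || max(i) > x$n))
    abort_range(sprintf("rank positions must lie in [0, %g]", x$n))
  cpp_rank_bv(x$words, x$n, x$n_padded, x$L0, x$L1, x$ones,
              x$config$block_bits, x$config$superblock_bits,
              x$config$paired, x$config$layers,
              if (x$config$strategy == "mask") 0L else 1L,
              as.numeric(i))
}

#' @export
length.rank_bv <- function(x) x$n
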