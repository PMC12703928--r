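#' Packed bit storage
#'
#' Packs a 0/1 vector into 64-bit machine words with little-endian bit order:
#' bit `j` of the vector is bit `j %% 64` of word `j %/% 64`.  Trailing bits
#' beyond `length(x)` are zero.
#'
#' @param x A logical or 0/1 integer vector, or an existing `packed_bits`
#'   object (returned unchanged).
#' @return An object of class `packed_bits` with fields `n` (number of
#'   stored positions) and `words` (raw vector, 8 bytes per word).
#' @examples
#' pb <- packed_bits(c(1, 0, 1, 1))
#' popcount_bits(pb)
#' @export
packed_bits <- function(x) {
  if (inherits(x, "packed_bits")) return(x)
  if (is.logical(x)) x <- as.integer(x)
  if (!is.numeric(x)) abort_format("bits must be a logical or 0/1 vector")
  n <- length(x)
  words <- cpp_pack_bits(as.integer(x), n)
  structure(list(n = n, words = words), class = "packed_bits")
}

#' @export
length.packed_bits <- function(x) x$n

#' @export
print.packed_bits <- function(x, ...) {
  cat(sprintf("<packed_bits> n = %d, %d words, %g ones\n", x$n,
              length(x$words) / 8, cpp_popcount_raw(x$words)))
  invisible(x)
}

#' Bits stored in a packed vector
#'
#' @param x A `packed_bits` object.
#' @param i Optional 0-based positions; default all.
#' @return Integer vector of 0/1 values.
#' @export
get_bits <- function(x, i = NULL) {
  x <- packed_bits(x)
  if (is.null(i)) return(cpp_unpack_bits(x$words, x$n))
  if (any(i < 0 | i >= x$n)) abort_range("bit position out of range")
  cpp_get_bits(x$words, as.numeric(i))
}

#' Total popcount of a packed bit vector
#'
#' @param x A `packed_bits` object or 0/1 vector.
#' @return Number of set bits.
#' @export
popcount_bits <- function(x) cpp_popcount_raw(packed_bits(x)$words)

# Extend the raw word buffer with zero bytes to cover n_padded bits.
pad_words <- function(words, n_padded) {
  need <- as.integer(ceiling(n_padded / 64) * 8)
  if (length(words) >= need) return(words)
  c(words, raw(need - length(words)))
}
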