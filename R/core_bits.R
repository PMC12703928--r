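#' Popcount of a single block
#'
#' A block is `w` in \{64, 512\} consecutive bits.  For 512-bit blocks the
#' count is the sum of eight 64-bit word popcounts.
#'
#' @param block A raw vector of `w/8` bytes, or a 0/1 vector of length `w`.
#' @return Number of set bits in the block.
#' @export
popcount_block <- function(block) {
  cpp_popcount_raw(as_block_raw(block))
}

as_block_raw <- function(block) {
  if (is.raw(block)) {
    if (!length(block) %in% c(8L, 64L))
      abort_config("a raw block must have 8 or 64 bytes (w = 64 or 512)")
    return(block)
  }
  w <- length(block)
  if (!w %in% c(64L, 512L))
    abort_config("a block must span 64 or 512 bits")
  packed_bits(block)$words
}

#' Precomputed mask table for mask-and-count
#'
#' Builds the `2w + 1` masks indexed by a query's offset within a block
#' pair.  Index `j < w` selects the suffix `j..w-1` of a left block; index
#' `j >= w` selects the first `j - w` bits of a right block; `mask[w]` is
#' all-zero (a query exactly at the pair boundary contributes nothing).
#'
#' @param w Block width in bits, 64 or 512.
#' @return An object of class `mask_table`.
#' @export
make_mask_table <- function(w) {
  if (!is.numeric(w) || length(w) != 1 || !(w %in% c(64, 512)))
    abort_config("mask tables are only defined for block widths 64 and 512")
  structure(list(w = as.integer(w), masks = cpp_make_mask_table(as.integer(w))),
            class = "mask_table")
}

#' @export
print.mask_table <- function(x, ...) {
  cat(sprintf("<mask_table> w = %d, %d masks\n", x$w, 2L * x$w + 1L))
  invisible(x)
}

#' Extract one mask from a mask table
#'
#' @param table A `mask_table`.
#' @param j Mask index in `[0, 2w]`.
#' @return Integer 0/1 vector of length `w`.
#' @export
mask_bits <- function(table, j) {
  stopifnot(inherits(table, "mask_table"))
  if (j < 0 || j > 2 * table$w) abort_range("mask index out of [0, 2w]")
  bytes <- table$w / 8
  cpp_unpack_bits(table$masks[(j * bytes + 1):((j + 1) * bytes)], table$w)
}

#' Count block bits by masking
#'
#' Computes `popcount(block AND mask[pair_pos])`.  For `pair_pos < w` this
#' is the suffix count of a left block from offset `pair_pos`; for
#' `pair_pos >= w` the count of the first `pair_pos - w` bits of a right
#' block.
#'
#' @param block Raw (`w/8` bytes) or 0/1 vector of length `w`.
#' @param table A `mask_table` of matching width.
#' @param pair_pos Offset within the block pair, in `[0, 2w]`.
#' @return The masked popcount.
#' @export
masked_count <- function(block, table, pair_pos) {
  stopifnot(inherits(table, "mask_table"))
  blk <- as_block_raw(block)
  if (length(blk) * 8L != table$w)
    abort_config("block width does not match mask table width")
  if (pair_pos < 0 || pair_pos > 2 * table$w)
    abort_range("pair_pos out of [0, 2w]")
  cpp_masked_count(blk, table$masks, as.integer(pair_pos), table$w)
}

#' Count block bits by shifting
#'
#' Same contract as [masked_count()], implemented by shifting unwanted bits
#' out of the block instead of masking them; the two strategies agree on all
#' inputs.
#'
#' @param block Raw (`w/8` bytes) or 0/1 vector of length `w`.
#' @param pair_pos Offset within the block pair, in `[0, 2w]`.
#' @param side `"auto"` infers left/right from `pair_pos`; `"left"` /
#'   `"right"` assert which member of the pair the block is.
#' @return The shifted popcount.
#' @export
shifted_count <- function(block, pair_pos, side = c("auto", "left", "right")) {
  side <- match.arg(side)
  blk <- as_block_raw(block)
  w <- length(blk) * 8L
  if (pair_pos < 0 || pair_pos > 2 * w) abort_range("pair_pos out of [0, 2w]")
  if (side == "left" && pair_pos > w)
    abort_range("left-block offsets lie in [0, w]")
  if (side == "right" && pair_pos < w)
    abort_range("right-block offsets lie in [w, 2w]")
  cpp_shifted_count(blk, as.integer(pair_pos), w)
}
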