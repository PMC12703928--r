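#' Rank directory configuration
#'
#' Describes the layout of a rank support structure: block width `w1`,
#' superblock width `w0`, number of directory layers, whether blocks (and
#' superblocks) are paired, and the block-counting strategy.
#'
#' The superblock width must be a multiple of the block width (and of twice
#' the block width for paired two-layer layouts, so that every block pair
#' lies inside one superblock).  `superblock_bits` may not exceed 65,536:
#' L1 entries are 16-bit relative counts and their maximum value is
#' `w0 - w1`.
#'
#' @param block_bits Block width `w1` in bits; 64 or 512.
#' @param superblock_bits Superblock width `w0` in bits; default 65,536.
#' @param paired Store one directory entry per block (superblock) pair?
#' @param layers 1 (blocks only, 64-bit counters; pedagogical) or 2
#'   (the space-efficient L0/L1 layout).
#' @param strategy Block counting strategy, `"mask"` or `"shift"`.
#' @return An object of class `rank_config`.
#' @examples
#' rank_config(512, paired = TRUE)
#' @export
rank_config <- function(block_bits = 64L, superblock_bits = 65536L,
                        paired = FALSE, layers = 2L,
                        strategy = c("mask", "shift")) {
  strategy <- match.arg(strategy)
  if (!block_bits %in% c(64, 512))
    abort_config("block_bits must be 64 or 512")
  if (!layers %in% c(1, 2)) abort_config("layers must be 1 or 2")
  w1 <- as.integer(block_bits)
  w0 <- as.integer(superblock_bits)
  if (layers == 2L) {
    if (w0 <= w1 || w0 %% w1 != 0)
      abort_config("superblock_bits must be a proper multiple of block_bits")
    if (isTRUE(paired) && w0 %% (2L * w1) != 0)
      abort_config("paired layouts need superblock_bits divisible by 2*block_bits")
    if (w0 > 65536L)
      abort_config("superblock_bits may not exceed 65536 (16-bit L1 entries)")
  }
  structure(list(block_bits = w1, superblock_bits = w0,
                 paired = isTRUE(paired), layers = as.integer(layers),
                 strategy = strategy),
            class = "rank_config")
}

#' @export
print.rank_config <- function(x, ...) {
  cat(sprintf("<rank_config> %d/%s, %d layer(s), %s, strategy = %s\n",
              x$block_bits,
              if (x$superblock_bits == 65536L) "64k" else x$superblock_bits,
              x$layers, if (x$paired) "paired" else "non-paired", x$strategy))
  invisible(x)
}

# Span the zero-padded bit layer must cover: whole superblocks (or
# superblock pairs) for two layers, whole blocks (or block pairs) for one.
padded_length <- function(config, n) {
  unit <- if (config$layers == 2L) config$superblock_bits else config$block_bits
  if (config$paired) unit <- 2 * unit
  ceiling(n / unit) * unit
}

#' Decompose a query position into directory indices
#'
#' Returns the block, L1 and L0 indices for prefix length `i`, together
#' with the offset within the block pair and which pair member (and
#' superblock member) the position falls in.  Mainly useful for inspecting
#' and testing the layouts.
#'
#' @param i Query prefix length.
#' @param config A [rank_config()].
#' @return A list with `i_b`, `i_l1`, `i_l0`, `pos`, `block_side`,
#'   `superblock_side`.
#' @export
query_cursor <- function(i, config) {
  w1 <- config$block_bits
  w0 <- config$superblock_bits
  i_b <- i %/% w1
  if (config$paired) {
    i_l1 <- i %/% (2 * w1)
    i_l0 <- if (config$layers == 2L) i %/% (2 * w0) else i %/% (2 * w1)
    pos <- i - i_l1 * 2 * w1
  } else {
    i_l1 <- i %/% w1
    i_l0 <- if (config$layers == 2L) i %/% w0 else i %/% w1
    pos <- i - i_b * w1
  }
  list(i_b = i_b, i_l1 = i_l1, i_l0 = i_l0, pos = pos,
       block_side = if (config$paired && pos < w1) "left" else "right",
       superblock_side = if (config$paired && (i %/% w0) %% 2 == 0)
         "left" else "right")
}
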