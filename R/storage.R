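# Exact stored-bit accounting.  Every quantity is a bit count of what is
# (or would be) serialized: the zero-padded bit layer / planes, 16 bits per
# L1 entry, 64 bits per L0 entry.  Derived figures follow the reporting
# conventions of the space tables: overhead percent to one decimal,
# bits per character to three decimals, rounding half away from zero.

round_away <- function(x, digits) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

storage_report <- function(kind, n, sigma, config, payload_bits, l0_entries,
                           l1_entries) {
  dir_bits <- 64 * l0_entries + 16 * l1_entries
  total <- payload_bits + dir_bits
  structure(list(
    kind = kind, n = n, sigma = sigma,
    block_bits = config$block_bits, superblock_bits = config$superblock_bits,
    paired = config$paired, layers = config$layers,
    payload_bits = payload_bits,
    l0_entries = l0_entries, l0_bits = 64 * l0_entries,
    l1_entries = l1_entries, l1_bits = 16 * l1_entries,
    dir_bits = dir_bits, total_bits = total,
    overhead_percent = if (n > 0) round_away(100 * dir_bits / n, 1) else NA_real_,
    bits_per_char = if (n > 0) round_away(total / n, 3) else NA_real_
  ), class = "storage_report")
}

#' @export
print.storage_report <- function(x, ...) {
  cat(sprintf("<storage_report> %s, n = %g%s, %d/%d %s\n", x$kind, x$n,
              if (is.na(x$sigma)) "" else sprintf(", sigma = %d", x$sigma),
              x$block_bits, x$superblock_bits,
              if (x$paired) "paired" else "non-paired"))
  cat(sprintf("  payload %g bits, L0 %g bits (%g entries), L1 %g bits (%g entries)\n",
              x$payload_bits, x$l0_bits, x$l0_entries, x$l1_bits,
              x$l1_entries))
  cat(sprintf("  total %g bits; overhead %.1f%%; %.3f bits/char\n",
              x$total_bits, x$overhead_percent, x$bits_per_char))
  invisible(x)
}

# Directory entry counts implied by a config at length n (closed form,
# identical to what a real build materializes).
dir_entry_counts <- function(config, n) {
  w1 <- config$block_bits
  w0 <- config$superblock_bits
  np <- padded_length(config, n)
  if (config$layers == 2L) {
    if (config$paired) {
      list(n_padded = np, l0 = np / (2 * w0), l1 = np / (2 * w1))
    } else {
      list(n_padded = np, l0 = np / w0, l1 = np / w1)
    }
  } else {
    # single layer: one 64-bit counter per block or per block pair
    list(n_padded = np, l0 = np / (if (config$paired) 2 * w1 else w1), l1 = 0)
  }
}

#' Storage accounting
#'
#' Reports the exact number of stored bits of a built structure, split into
#' the payload (padded bit layer or bit planes) and the L0/L1 directories,
#' together with the derived overhead percent (directory bits over `n`) and
#' bits per character (total bits over `n`).
#'
#' @param x A `rank_bv` or `string_rank` object.
#' @param ... Unused.
#' @return A `storage_report`.
#' @export
storage_bits <- function(x, ...) UseMethod("storage_bits")

#' @rdname storage_bits
#' @export
storage_bits.rank_bv <- function(x, ...) {
  storage_report("bv", x$n, NA_integer_, x$config,
                 payload_bits = length(x$words) * 8,
                 l0_entries = length(x$L0), l1_entries = length(x$L1))
}

#' @rdname storage_bits
#' @export
storage_bits.string_rank <- function(x, ...) {
  if (x$kind == "mbv") {
    payload <- sum(vapply(x$bvs, function(v) length(v$words) * 8, 0))
    l0 <- sum(vapply(x$bvs, function(v) length(v$L0), 0L))
    l1 <- sum(vapply(x$bvs, function(v) length(v$L1), 0L))
  } else {
    payload <- sum(vapply(x$planes, function(p) length(p) * 8, 0))
    l0 <- sum(vapply(x$dirs, function(d) length(d$L0), 0L))
    l1 <- sum(vapply(x$dirs, function(d) length(d$L1), 0L))
  }
  storage_report(x$kind, x$n, x$alphabet$sigma, x$config,
                 payload_bits = payload, l0_entries = l0, l1_entries = l1)
}

#' Closed-form storage accounting for a bit vector layout
#'
#' Computes, without building anything, the exact stored size of a rank
#' bit vector of length `n` under `config` (padding included).  Equals
#' `storage_bits(rank_bv(...))` of a real build at the same `n`.
#'
#' @param config A [rank_config()].
#' @param n Bit vector length.
#' @return A `storage_report`.
#' @examples
#' storage_bits_bv(rank_config(512, paired = TRUE), 2^30)$overhead_percent
#' @export
storage_bits_bv <- function(config, n) {
  stopifnot(inherits(config, "rank_config"))
  e <- dir_entry_counts(config, n)
  storage_report("bv", n, NA_integer_, config, payload_bits = e$n_padded,
                 l0_entries = e$l0, l1_entries = e$l1)
}

#' Closed-form storage accounting for a string-rank layout
#'
#' Exact stored size of a string structure of `n` symbols over an alphabet
#' of size `sigma`: `sigma` padded indicator bit vectors (mBV) or
#' `ceiling(log2(sigma))` padded bit planes (fBV/pfBV), plus one L0/L1
#' directory per symbol.  Equals the measured size of a real build.
#'
#' @param kind `"mbv"`, `"fbv"` or `"pfbv"`.
#' @param n Text length in symbols.
#' @param sigma Alphabet size in `[2, 256]`.
#' @param block_bits,superblock_bits Directory geometry; see
#'   [rank_config()].  `pfbv` pairs blocks and superblocks, the other two
#'   kinds do not.
#' @return A `storage_report`.
#' @examples
#' storage_bits_string("pfbv", 1e9, 4, block_bits = 512)$bits_per_char
#' @export
storage_bits_string <- function(kind = c("mbv", "fbv", "pfbv"), n, sigma,
                                block_bits = 64L, superblock_bits = 65536L) {
  kind <- match.arg(kind)
  if (sigma < 2 || sigma > 256) abort_alphabet("sigma must lie in [2, 256]")
  config <- rank_config(block_bits, superblock_bits, paired = kind == "pfbv")
  e <- dir_entry_counts(config, n)
  k <- max(1, ceiling(log2(sigma)))
  payload <- if (kind == "mbv") sigma * e$n_padded else k * e$n_padded
  storage_report(kind, n, as.integer(sigma), config, payload_bits = payload,
                 l0_entries = sigma * e$l0, l1_entries = sigma * e$l1)
}

#' Space-overhead column of the bit-vector layouts
#'
#' Overhead percent (directory bits over `n`, one decimal) for the four
#' two-layer bit-vector configurations at a given length.
#'
#' @param n Bit vector length; default `2^30`.
#' @return A data frame with columns `implementation` and
#'   `overhead_percent`.
#' @export
bv_overhead_table <- function(n = 2^30) {
  rows <- list(
    c("64/64k", 64, FALSE), c("512/64k", 512, FALSE),
    c("Paired 64/64k", 64, TRUE), c("Paired 512/64k", 512, TRUE))
  data.frame(
    implementation = vapply(rows, `[[`, "", 1),
    overhead_percent = vapply(rows, function(r) {
      cfg <- rank_config(as.integer(r[[2]]), paired = as.logical(r[[3]]))
      storage_bits_bv(cfg, n)$overhead_percent
    }, 0))
}

#' Bits-per-character grid of the string layouts
#'
#' Bits per character (three decimals) for mBV, fBV and pfBV at 64- and
#' 512-bit block widths over a set of alphabet sizes.
#'
#' @param n Text length; default `1e9`.
#' @param sigmas Alphabet sizes; default `c(4, 5, 16, 21, 255)`.
#' @return A data frame, one row per structure, one column per sigma.
#' @export
string_space_table <- function(n = 1e9, sigmas = c(4, 5, 16, 21, 255)) {
  rows <- list(
    c("mBV 64/64k", "mbv", 64), c("fBV 64/64k", "fbv", 64),
    c("fBV 512/64k", "fbv", 512), c("pfBV 64/64k", "pfbv", 64),
    c("pfBV 512/64k", "pfbv", 512))
  out <- data.frame(implementation = vapply(rows, `[[`, "", 1))
  for (s in sigmas) {
    out[[paste0("sigma_", s)]] <- vapply(rows, function(r) {
      storage_bits_string(r[[2]], n, s,
                          block_bits = as.integer(r[[3]]))$bits_per_char
    }, 0)
  }
  out
}
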