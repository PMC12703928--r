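#' Alphabets for string rank structures
#'
#' An alphabet maps external characters to internal 0-based codes.  Codes
#' are the 0-based ranks of the supplied letters; `code_bits` is
#' \eqn{\lceil \log_2 \sigma \rceil}, the number of bit planes a flattened
#' representation needs.
#'
#' @param x Either a character vector of distinct single characters, or a
#'   single number giving the alphabet size (symbols are then the integer
#'   codes `0..sigma-1` with no character mapping).
#' @return An object of class `alphabet` with fields `sigma`, `code_bits`
#'   and `chars` (possibly `NULL`).
#' @examples
#' dna_alphabet()
#' alphabet(21)
#' @export
alphabet <- function(x) {
  if (is.character(x)) {
    if (any(nchar(x) != 1) || anyDuplicated(x))
      abort_alphabet("alphabet letters must be distinct single characters")
    sigma <- length(x)
    chars <- x
  } else if (is.numeric(x) && length(x) == 1) {
    sigma <- as.integer(x)
    chars <- NULL
  } else {
    abort_alphabet("supply letters or an alphabet size")
  }
  if (sigma < 2 || sigma > 256)
    abort_alphabet("alphabet size must lie in [2, 256]")
  structure(list(sigma = sigma,
                 code_bits = max(1L, as.integer(ceiling(log2(sigma)))),
                 chars = chars),
            class = "alphabet")
}

#' @rdname alphabet
#' @details `dna_alphabet()` is the canonical DNA mapping A=0 (binary 00),
#'   C=1 (01), G=2 (10), T=3 (11): reconstructing the positions of C from
#'   two planes takes `~b1 & b0`.
#' @export
dna_alphabet <- function() alphabet(c("A", "C", "G", "T"))

#' @export
print.alphabet <- function(x, ...) {
  cat(sprintf("<alphabet> sigma = %d, %d code bit(s)%s\n", x$sigma,
              x$code_bits,
              if (is.null(x$chars)) "" else
                paste0(": ", paste(x$chars, collapse = ""))))
  invisible(x)
}

default_code_alphabet <- function(x) {
  alphabet(max(2, if (length(x)) max(x, na.rm = TRUE) + 1 else 2))
}

# Resolve external symbols (characters or codes) to 0-based codes.
resolve_codes <- function(x, alph) {
  if (is.character(x)) {
    if (is.null(alph$chars))
      abort_alphabet("this alphabet has no character mapping")
    chars <- if (length(x) == 1 && nchar(x) != 1)
      strsplit(x, "")[[1]] else x
    codes <- match(chars, alph$chars) - 1L
    if (anyNA(codes)) {
      bad <- unique(chars[is.na(codes)])
      abort_alphabet(sprintf("character(s) not in alphabet: %s",
                             paste(bad, collapse = ", ")))
    }
    return(codes)
  }
  codes <- as.integer(x)
  if (length(codes) && (anyNA(codes) || min(codes) < 0 ||
                        max(codes) >= alph$sigma))
    abort_alphabet(sprintf("symbol codes must lie in [0, %d)", alph$sigma))
  codes
}

#' Flatten a text into bit planes
#'
#' Scatters the `code_bits` bits of every symbol code over `code_bits`
#' packed bit planes: bit `t` of plane `t` at position `j` is bit `t` of
#' `code(s_j)`.  Planes are zero-padded to the superblock (or superblock
#' pair) span of `config`.
#'
#' @param x Symbol codes (0-based integers) or a character string resolved
#'   through `alphabet`.
#' @param alphabet An [alphabet()].
#' @param config A two-layer [rank_config()].
#' @return An object of class `flattened_text`.
#' @export
encode_text <- function(x, alphabet, config = rank_config()) {
  stopifnot(inherits(alphabet, "alphabet"), inherits(config, "rank_config"))
  codes <- resolve_codes(x, alphabet)
  n <- length(codes)
  np <- padded_length(config, n)
  planes <- cpp_encode_planes(codes, alphabet$code_bits, np)
  structure(list(n = n, n_padded = np, k = alphabet$code_bits,
                 alphabet = alphabet, planes = planes),
            class = "flattened_text")
}

#' @export
print.flattened_text <- function(x, ...) {
  cat(sprintf("<flattened_text> n = %g, %d plane(s), padded to %g bits\n",
              x$n, x$k, x$n_padded))
  invisible(x)
}

#' Reconstruct an indicator word from bit planes
#'
#' ANDs, for every plane `t`, the plane word (when bit `t` of the code is
#' 1) or its bitwise complement (when it is 0).  Bit `j` of the result is 1
#' iff the symbol at position `64*word_index + j` equals `code`; positions
#' at or beyond the text length are forced to 0 so complemented padding
#' never counts.
#'
#' @param x A `flattened_text` or a flattened `string_rank`.
#' @param code Symbol (0-based code, or a character for mapped alphabets).
#' @param word_index 0-based 64-bit word index within the padded span.
#' @return A raw vector of 8 bytes (the word, little-endian).
#' @export
reconstruct_word <- function(x, code, word_index) {
  if (inherits(x, "string_rank")) {
    if (x$kind == "mbv")
      abort_format("mBV structures store explicit bit vectors; nothing to reconstruct")
    planes <- x$planes; k <- x$alphabet$code_bits; n <- x$n
    alph <- x$alphabet
  } else if (inherits(x, "flattened_text")) {
    planes <- x$planes; k <- x$k; n <- x$n; alph <- x$alphabet
  } else {
    abort_format("expected a flattened_text or string_rank")
  }
  code <- resolve_codes(code, alph)
  if (length(code) != 1) abort_alphabet("one symbol at a time")
  cpp_reconstruct_word(planes, k, code, word_index, n)
}

#' Build a string with rank support
#'
#' Three layouts are available.  `"mbv"` stores one full indicator bit
#' vector with rank support per symbol.  `"fbv"` stores only
#' `ceiling(log2(sigma))` flattened bit planes plus one non-paired
#' two-layer directory per symbol; indicator words are reconstructed on
#' the fly during queries.  `"pfbv"` is the same with paired blocks and
#' superblocks, halving directory space.
#'
#' @param x A character string, a character vector of single letters, or a
#'   vector of 0-based integer codes.
#' @param kind `"fbv"`, `"pfbv"` or `"mbv"`.
#' @param alphabet An [alphabet()]; defaults to [dna_alphabet()] for
#'   character input and to `alphabet(max(x) + 1)` (at least 2) for codes.
#' @param block_bits Block width, 64 or 512.
#' @param superblock_bits Superblock width; default 65,536.
#' @param strategy Block counting strategy, `"mask"` or `"shift"`.
#' @return An object of class `string_rank`.
#' @examples
#' s <- string_rank("CAAGTACG", kind = "pfbv")
#' rank_query(s, 8, "C")
#' @export
string_rank <- function(x, kind = c("fbv", "pfbv", "mbv"), alphabet = NULL,
                        block_bits = 64L, superblock_bits = 65536L,
                        strategy = c("mask", "shift")) {
  kind <- match.arg(kind)
  strategy <- match.arg(strategy)
  if (is.null(alphabet)) {
    alphabet <- if (is.character(x)) dna_alphabet()
    else default_code_alphabet(x)
  }
  stopifnot(inherits(alphabet, "alphabet"))
  codes <- resolve_codes(x, alphabet)
  n <- length(codes)
  config <- rank_config(block_bits, superblock_bits, paired = kind == "pfbv",
                        layers = 2L, strategy = strategy)
  obj <- list(kind = kind, n = n, alphabet = alphabet, config = config)
  if (kind == "mbv") {
    obj$bvs <- lapply(seq_len(alphabet$sigma) - 1L, function(cc)
      rank_bv(as.integer(codes == cc), config))
  } else {
    np <- padded_length(config, n)
    obj$n_padded <- np
    obj$planes <- cpp_encode_planes(codes, alphabet$code_bits, np)
    obj$dirs <- cpp_build_str_dirs(codes, alphabet$sigma, np,
                                   config$block_bits,
                                   config$superblock_bits, config$paired)
  }
  structure(obj, class = "string_rank")
}

#' @export
print.string_rank <- function(x, ...) {
  cat(sprintf("<string_rank> %s, n = %g, sigma = %d, %d/%d, strategy = %s\n",
              x$kind, x$n, x$alphabet$sigma, x$config$block_bits,
              x$config$superblock_bits, x$config$strategy))
  invisible(x)
}

#' @export
length.string_rank <- function(x) x$n

#' @param symbol Symbol to count: a 0-based code, or a character for
#'   alphabets with a character mapping.
#' @rdname rank_query
#' @export
rank_query.string_rank <- function(x, i, symbol, ...) {
  if (missing(symbol)) abort_usage("string rank needs a symbol")
  code <- resolve_codes(symbol, x$alphabet)
  if (length(code) != 1) abort_alphabet("one symbol at a time")
  if (!is.numeric(i)) abort_range("positions must be numeric")
  if (length(i) && (anyNA(i) || min(i) < 0 || max(i) > x$n))
    abort_range(sprintf("rank positions must lie in [0, %g]", x$n))
  if (x$kind == "mbv")
    return(rank_query(x$bvs[[code + 1L]], i))
  d <- x$dirs[[code + 1L]]
  cpp_rank_flat(x$planes, x$alphabet$code_bits, x$n, x$n_padded,
                d$L0, d$L1, d$ones, code, x$config$block_bits,
                x$config$superblock_bits, x$config$paired,
                if (x$config$strategy == "mask") 0L else 1L,
                as.numeric(i))
}

#' Symbol at a position
#'
#' Reassembles the symbol code stored at 0-based position `i` from the bit
#' planes (fBV/pfBV) or the indicator vectors (mBV).
#'
#' @param x A `string_rank`.
#' @param i Vector of 0-based positions in `[0, n)`.
#' @param as_char Return mapped characters instead of codes, when the
#'   alphabet has a character mapping.
#' @return Integer codes, or characters if `as_char`.
#' @export
access_symbol <- function(x, i, as_char = FALSE) {
  stopifnot(inherits(x, "string_rank"))
  if (length(i) && (anyNA(i) || min(i) < 0 || max(i) >= x$n))
    abort_range(sprintf("positions must lie in [0, %g)", x$n))
  if (x$kind == "mbv") {
    codes <- integer(length(i))
    hit <- rep(FALSE, length(i))
    for (cc in seq_len(x$alphabet$sigma) - 1L) {
      b <- cpp_get_bits(x$bvs[[cc + 1L]]$words, as.numeric(i)) == 1L
      codes[b] <- cc
      hit <- hit | b
    }
    stopifnot(all(hit))
  } else {
    codes <- cpp_access_planes(x$planes, x$alphabet$code_bits, as.numeric(i))
  }
  if (as_char) {
    if (is.null(x$alphabet$chars))
      abort_alphabet("this alphabet has no character mapping")
    return(x$alphabet$chars[codes + 1L])
  }
  codes
}
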