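# Versioned little-endian index container.
#
# Header: magic "BITRANK1" (8) | type u8 | w1 u32 | w0 u32 | paired u8 |
# layers u8 | strategy u8 | reserved u8 | n u64 | sigma u16 | k u8 |
# chars_len u16 | chars bytes.
# Payload (lengths derivable from header): bit words / planes, then L0
# entries as u64 and L1 entries as u16.  The payload byte count times 8 is
# exactly the total of the storage accounting; per-symbol totals (`ones`)
# are recomputed on load.

MAGIC <- charToRaw("BITRANK1")
TYPE_CODES <- c(bv = 1L, mbv = 2L, fbv = 3L, pfbv = 4L)

# little-endian byte helpers; exact for values < 2^53
le_bytes <- function(v, nbytes) {
  v <- as.numeric(v)
  out <- matrix(0, nrow = nbytes, ncol = length(v))
  for (b in seq_len(nbytes)) {
    out[b, ] <- v %% 256
    v <- v %/% 256
  }
  as.raw(out)
}

le_value <- function(r, nbytes) {
  m <- matrix(as.numeric(r), nrow = nbytes)
  as.numeric(crossprod(2^(8 * (seq_len(nbytes) - 1)), m))
}

serialize_header <- function(type, config, n, sigma = 0L, k = 0L,
                             chars = NULL) {
  ch <- if (is.null(chars)) raw(0) else charToRaw(paste(chars, collapse = ""))
  c(MAGIC,
    le_bytes(TYPE_CODES[[type]], 1),
    le_bytes(config$block_bits, 4),
    le_bytes(config$superblock_bits, 4),
    le_bytes(as.integer(config$paired), 1),
    le_bytes(config$layers, 1),
    le_bytes(if (config$strategy == "mask") 0 else 1, 1),
    le_bytes(0, 1),
    le_bytes(n, 8),
    le_bytes(sigma, 2),
    le_bytes(k, 1),
    le_bytes(length(ch), 2),
    ch)
}

serialize_dir <- function(L0, L1) {
  c(if (length(L0)) le_bytes(L0, 8) else raw(0),
    if (length(L1)) le_bytes(L1, 2) else raw(0))
}

#' Header size of the serialized form of an index
#'
#' Everything past the header is payload: the padded bit layer / planes
#' plus the packed L0 (64-bit) and L1 (16-bit) directory entries.  The
#' payload byte count times eight equals `storage_bits(x)$total_bits`.
#'
#' @param x A `rank_bv` or `string_rank`.
#' @return Header length in bytes.
#' @export
index_header_bytes <- function(x) {
  chars <- if (inherits(x, "string_rank")) x$alphabet$chars else NULL
  34L + if (is.null(chars)) 0L else length(chars)
}

#' Serialize an index to a file
#'
#' Writes the versioned little-endian container; [read_index()] restores a
#' bit-exact equivalent structure.
#'
#' @param x A `rank_bv` or `string_rank`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_index <- function(x, path) {
  if (inherits(x, "rank_bv")) {
    out <- c(serialize_header("bv", x$config, x$n),
             x$words, serialize_dir(x$L0, x$L1))
  } else if (inherits(x, "string_rank")) {
    hdr <- serialize_header(x$kind, x$config, x$n, x$alphabet$sigma,
                            x$alphabet$code_bits, x$alphabet$chars)
    if (x$kind == "mbv") {
      body <- lapply(x$bvs, function(v) c(v$words, serialize_dir(v$L0, v$L1)))
    } else {
      body <- c(x$planes,
                lapply(x$dirs, function(d) serialize_dir(d$L0, d$L1)))
    }
    out <- c(hdr, do.call(c, body))
  } else {
    abort_format("can only serialize rank_bv or string_rank objects")
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(out, con)
  invisible(path)
}

#' Read a serialized index
#'
#' @param path File written by [write_index()].
#' @return A `rank_bv` or `string_rank` object.
#' @export
read_index <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("no such index file: %s", path))
  buf <- readBin(path, "raw", n = file.size(path))
  if (length(buf) < 34 || !identical(buf[1:8], MAGIC))
    abort_format("not a bitrank index file (bad magic)")
  take <- local({
    off <- 8L
    function(nb) {
      if (nb == 0) return(raw(0))
      if (off + nb > length(buf)) abort_format("truncated index file")
      r <- buf[(off + 1L):(off + nb)]
      off <<- off + as.integer(nb)
      r
    }
  })
  type <- names(TYPE_CODES)[le_value(take(1), 1)]
  w1 <- le_value(take(4), 4)
  w0 <- le_value(take(4), 4)
  paired <- le_value(take(1), 1) == 1
  layers <- le_value(take(1), 1)
  strategy <- if (le_value(take(1), 1) == 0) "mask" else "shift"
  take(1)  # reserved
  n <- le_value(take(8), 8)
  sigma <- le_value(take(2), 2)
  k <- le_value(take(1), 1)
  chars_len <- le_value(take(2), 2)
  chars <- if (chars_len > 0) strsplit(rawToChar(take(chars_len)), "")[[1]]
  config <- rank_config(w1, w0, paired = paired, layers = layers,
                        strategy = strategy)
  ent <- dir_entry_counts(config, n)
  read_dir <- function() {
    L0 <- le_value(take(8 * ent$l0), 8)
    L1 <- if (ent$l1 > 0) le_value(take(2 * ent$l1), 2) else numeric(0)
    list(L0 = L0, L1 = L1)
  }
  if (type == "bv") {
    words <- take(ent$n_padded / 8)
    d <- read_dir()
    return(structure(list(n = n, n_padded = ent$n_padded, words = words,
                          config = config, L0 = d$L0, L1 = d$L1,
                          ones = cpp_popcount_raw(words)),
                     class = "rank_bv"))
  }
  alph <- if (!is.null(chars)) alphabet(chars) else alphabet(sigma)
  obj <- list(kind = type, n = n, alphabet = alph, config = config)
  if (type == "mbv") {
    obj$bvs <- lapply(seq_len(sigma), function(j) {
      words <- take(ent$n_padded / 8)
      d <- read_dir()
      structure(list(n = n, n_padded = ent$n_padded, words = words,
                     config = config, L0 = d$L0, L1 = d$L1,
                     ones = cpp_popcount_raw(words)),
                class = "rank_bv")
    })
  } else {
    obj$n_padded <- ent$n_padded
    obj$planes <- lapply(seq_len(k), function(j) take(ent$n_padded / 8))
    ones <- cpp_tabulate_planes(obj$planes, k, sigma, n)
    obj$dirs <- lapply(seq_len(sigma), function(j) {
      d <- read_dir()
      list(L0 = d$L0, L1 = d$L1, ones = ones[j])
    })
  }
  structure(obj, class = "string_rank")
}
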