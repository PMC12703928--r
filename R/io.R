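#' Read a FASTA file as symbol codes
#'
#' Reads all records with `Biostrings`, concatenates them, uppercases, and
#' maps characters through the alphabet.  Under the default policy any
#' character outside the alphabet is an error naming the offending
#' character; `policy = "extra"` extends the alphabet by one catch-all
#' symbol (`"?"`) and maps every unknown character to it.
#'
#' @param path FASTA file.
#' @param alph Target [alphabet()] with a character mapping; default DNA.
#' @param policy `"error"` or `"extra"`.
#' @return A list with `codes` (0-based integer vector) and `alphabet`.
#' @export
read_fasta_codes <- function(path, alph = dna_alphabet(),
                             policy = c("error", "extra")) {
  policy <- match.arg(policy)
  if (!file.exists(path)) abort_io(sprintf("no such file: %s", path))
  seqs <- tryCatch(Biostrings::readBStringSet(path),
                   error = function(e) abort_io(
                     sprintf("cannot parse FASTA %s: %s", path,
                             conditionMessage(e))))
  txt <- paste(toupper(as.character(seqs)), collapse = "")
  if (nchar(txt) == 0) abort_format("empty input")
  chars <- strsplit(txt, "")[[1]]
  if (policy == "extra") {
    extra <- setdiff(unique(chars), alph$chars)
    if (length(extra) > 0) {
      alph <- alphabet(c(alph$chars, "?"))
      chars[chars %in% extra] <- "?"
    }
  }
  codes <- match(chars, alph$chars) - 1L
  if (anyNA(codes)) {
    bad <- unique(chars[is.na(codes)])
    abort_alphabet(sprintf("character(s) not in alphabet: %s",
                           paste(bad, collapse = ", ")))
  }
  list(codes = codes, alphabet = alph)
}

#' Read a raw byte file as symbol codes
#'
#' Every byte value is one symbol.  The alphabet is either supplied or
#' inferred as `alphabet(max byte value + 1)`.
#'
#' @param path Input file.
#' @param alph Optional [alphabet()].
#' @return A list with `codes` and `alphabet`.
#' @export
read_raw_codes <- function(path, alph = NULL) {
  if (!file.exists(path)) abort_io(sprintf("no such file: %s", path))
  bytes <- readBin(path, "raw", n = file.size(path))
  if (length(bytes) == 0) abort_format("empty input")
  codes <- as.integer(bytes)
  if (is.null(alph)) alph <- default_code_alphabet(codes)
  if (max(codes) >= alph$sigma)
    abort_alphabet("byte value exceeds alphabet size")
  list(codes = codes, alphabet = alph)
}

#' Read a raw binary file as a packed bit vector
#'
#' The file bytes are interpreted as the little-endian packed bit layer;
#' `n` defaults to 8 times the file size.
#'
#' @param path Input file.
#' @param n Optional number of valid bits (at most `8 * file size`).
#' @return A `packed_bits` object.
#' @export
read_raw_bits <- function(path, n = NULL) {
  if (!file.exists(path)) abort_io(sprintf("no such file: %s", path))
  bytes <- readBin(path, "raw", n = file.size(path))
  if (length(bytes) == 0) abort_format("empty input")
  nbits <- 8 * length(bytes)
  if (is.null(n)) n <- nbits
  if (n > nbits) abort_format("n exceeds the number of bits in the file")
  # re-pack through the unpacked form so trailing bits beyond n are zeroed
  packed_bits(cpp_unpack_bits(bytes, n))
}
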