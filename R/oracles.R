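# Brute-force oracles and seeded synthetic generators.  The oracles are
# deliberately plain linear scans over R vectors, independent of the packed
# word machinery they are used to check.

#' Linear-scan rank oracle for bit vectors
#'
#' @param bits A 0/1 (or logical) vector.
#' @param i Vector of prefix lengths in `[0, length(bits)]`.
#' @return Prefix sums computed by direct summation.
#' @export
oracle_rank_bits <- function(bits, i) {
  bits <- as.integer(bits)
  if (length(i) && (anyNA(i) || min(i) < 0 || max(i) > length(bits)))
    abort_range("oracle positions must lie in [0, n]")
  c(0, cumsum(bits))[i + 1]
}

#' Linear-scan rank oracle for texts
#'
#' @param codes Integer symbol codes.
#' @param i Vector of prefix lengths in `[0, length(codes)]`.
#' @param code The symbol code to count.
#' @return Occurrence counts computed by direct scanning.
#' @export
oracle_rank_text <- function(codes, i, code) {
  if (length(i) && (anyNA(i) || min(i) < 0 || max(i) > length(codes)))
    abort_range("oracle positions must lie in [0, n]")
  c(0, cumsum(codes == code))[i + 1]
}

#' Seeded fixture specification
#'
#' Identical specs produce identical output: generation always runs under
#' R's Mersenne-Twister with the given seed and restores the caller's RNG
#' state afterwards.
#'
#' @param seed RNG seed (integer).
#' @param n Output length.
#' @param density For bit vectors: probability of a 1.
#' @param sigma For texts: alphabet size (symbols uniform over `0..sigma-1`).
#' @return An object of class `fixture_spec`.
#' @export
fixture_spec <- function(seed, n, density = NULL, sigma = NULL) {
  if (is.null(density) == is.null(sigma))
    abort_usage("give exactly one of density (bits) or sigma (text)")
  structure(list(seed = as.integer(seed), n = n, density = density,
                 sigma = sigma), class = "fixture_spec")
}

with_fixed_rng <- function(seed, expr) {
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  expr
}

#' Generate a deterministic random fixture
#'
#' @param spec A [fixture_spec()].
#' @return A 0/1 integer vector (bit spec) or 0-based code vector (text
#'   spec).
#' @examples
#' generate(fixture_spec(1, 10, density = 0.5))
#' @export
generate <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  if (!is.null(spec$density)) generate_bits(spec$n, spec$density, spec$seed)
  else generate_text(spec$n, spec$sigma, spec$seed)
}

#' @rdname generate
#' @param n Length.
#' @param density Probability of a 1.
#' @param seed RNG seed.
#' @importFrom stats runif
#' @export
generate_bits <- function(n, density = 0.5, seed = 1L) {
  with_fixed_rng(seed, as.integer(runif(n) < density))
}

#' @rdname generate
#' @param sigma Alphabet size; symbols are uniform over `0..sigma-1`.
#' @export
generate_text <- function(n, sigma, seed = 1L) {
  with_fixed_rng(seed, sample.int(as.integer(sigma), n, replace = TRUE) - 1L)
}
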