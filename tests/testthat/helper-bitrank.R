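# Shared fixtures and helpers, all generated in code.

# the worked DNA example: C=01, A=00, G=10, T=11 (A=0, C=1, G=2, T=3)
toy_string <- "CAAGTACG"
toy_codes <- c(1L, 0L, 0L, 2L, 3L, 0L, 1L, 2L)

# every layout/strategy combination at a given geometry
bv_config_grid <- function(block_bits = c(64L, 512L),
                           superblock_bits = 65536L) {
  g <- expand.grid(block = block_bits, paired = c(FALSE, TRUE),
                   layers = c(1L, 2L), strategy = c("mask", "shift"),
                   stringsAsFactors = FALSE)
  lapply(seq_len(nrow(g)), function(r)
    rank_config(g$block[r], superblock_bits, paired = g$paired[r],
                layers = g$layers[r], strategy = g$strategy[r]))
}

# positions worth probing: both ends plus block/superblock seams
probe_positions <- function(n, config, extra = 250, seed = 1) {
  w1 <- config$block_bits
  w0 <- config$superblock_bits
  seams <- c(0, 1, n, w1, 2 * w1, w0, 2 * w0)
  seams <- c(seams, seams - 1, seams + 1)
  seams <- unique(seams[seams >= 0 & seams <= n])
  sampled <- with_seed(seed, sort(sample(0:n, min(extra, n + 1))))
  unique(c(seams, sampled))
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

unpack_word <- function(raw8) bitrank:::cpp_unpack_bits(raw8, 64)
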