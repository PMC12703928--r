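#' Informational rank-query timing
#'
#' Times repeated rank queries at seeded random positions under both block
#' counting strategies and cross-checks that they return identical counts.
#' Timings depend on the host CPU, compiler and cache state; they are
#' reported for orientation only and are not reproducible across machines.
#'
#' @param x A `rank_bv` or `string_rank`.
#' @param queries Number of query positions; 0 gives an empty report.
#' @param seed Seed for the query positions (and symbols).
#' @param reps How often the whole query batch is repeated per timing.
#' @return A data frame with one row per strategy: query count, elapsed
#'   seconds and mean ns per rank call.
#' @export
bench_rank <- function(x, queries = 10000L, seed = 1L, reps = 5L) {
  empty <- data.frame(strategy = character(0), queries = integer(0),
                      elapsed_s = numeric(0), ns_per_rank = numeric(0))
  if (queries <= 0) return(empty)
  pos <- with_fixed_rng(seed, floor(runif(queries) * (x$n + 1)))
  is_str <- inherits(x, "string_rank")
  syms <- if (is_str)
    with_fixed_rng(seed + 1L, sample.int(x$alphabet$sigma, queries,
                                         replace = TRUE) - 1L)
  run <- function(strategy) {
    y <- x
    y$config$strategy <- strategy
    if (is_str && y$kind == "mbv")
      y$bvs <- lapply(y$bvs, function(v) {
        v$config$strategy <- strategy
        v
      })
    do_batch <- function() {
      if (!is_str) return(rank_query(y, pos))
      out <- numeric(queries)
      for (cc in unique(syms)) {
        sel <- syms == cc
        out[sel] <- rank_query(y, pos[sel], cc)
      }
      out
    }
    t <- system.time(for (r in seq_len(reps)) res <- do_batch())["elapsed"]
    list(res = res, elapsed = unname(t))
  }
  m <- run("mask")
  s <- run("shift")
  if (!identical(m$res, s$res))
    stop("mask and shift strategies disagree; this is a bug")
  data.frame(strategy = c("mask", "shift"),
             queries = queries,
             elapsed_s = c(m$elapsed, s$elapsed),
             ns_per_rank = c(m$elapsed, s$elapsed) / (queries * reps) * 1e9)
}
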