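---
title: "Rank support with paired-block directories: model, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rank support with paired-block directories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bitrank)
```

## The problem

`rank(i)` on a bit vector counts the set bits among the first `i`
positions; `rank(i, c)` on a string counts occurrences of symbol `c` among
the first `i` characters.  String rank is the inner loop of
Burrows–Wheeler-based full-text indexes (FM-indexes), where every step of a
backward search performs two rank calls on the transformed text — so both
the memory taken by the support structure and the cost of a single query
matter at genome scale.

`bitrank` implements the classical block/superblock solution and two
refinements: *paired-block* directories that halve the directory space,
and *flattened bit planes* that replace per-symbol bit vectors with
$\lceil \log_2 \sigma \rceil$ shared planes.

## The directory model

The bit layer is grouped into blocks of $w_1$ bits and superblocks of
$w_0$ bits ($w_0$ a multiple of $w_1$).  Two arrays are stored:

* **L0** — one 64-bit absolute count per superblock: ones before the
  superblock starts.
* **L1** — one 16-bit relative count per block: ones from the enclosing
  superblock's start to the block's start.

A query decomposes `i` into a superblock, a block and an in-block offset:

$$rank(i) = L0[\lfloor i/w_0\rfloor] + L1[\lfloor i/w_1\rfloor] +
pc(b[\lfloor i/w_1\rfloor]_{:i \bmod w_1})$$

where $pc$ is a popcount of the leading bits of one block.

### Paired blocks

The paired layout stores one directory entry per *pair* of blocks and per
pair of superblocks — half the entries.  The stored values change meaning:

* `L0[p]` holds the absolute count through the end of the pair's **left**
  superblock (i.e. up to where the right superblock starts).
* `L1[q]` for a block pair inside a **right** superblock holds the prefix
  count from the superblock start through the pair's left block; inside a
  **left** superblock it holds the *postfix* count from the pair's right
  block to the end of that superblock.

Evaluation then adds or subtracts depending on which member of each pair
the query falls in:

$$rank(i) = L0[i_{l0}] \pm L1[i_{l1}] \pm pc(\cdot)$$

with `+L1` iff `i` lies in a right superblock, and the block term a
*prefix* count of the right block (added) or a *suffix* count of the left
block from the query offset (subtracted).  Every combination was validated
exhaustively against a linear-scan oracle; the suffix/prefix bookkeeping is
where off-by-one bugs live, and the oracle — not the figures — is the
authority the tests rely on.

A note on the evaluation formula: the two-layer paired definition can be
written so tersely that the absolute L0 term is easy to drop.  The
implementation always evaluates `L0[i_l0] ± L1[i_l1] ± pc`, which is the
only form consistent with the stored prefix/postfix definitions above.

### Mask-and-count vs. shift-and-count

The block term needs "ones in a prefix" or "ones in a suffix" of one
block.  *Shift-and-count* shifts the unwanted bits out and popcounts;
paired layouts need a left/right case split, i.e. a branch.
*Mask-and-count* instead ANDs the block with one of $2 w_1 + 1$
precomputed masks indexed by the offset within the block pair: indices
$[0, w_1)$ are left-block suffix masks, $[w_1, 2w_1]$ right-block prefix
masks, and index $w_1$ is all-zero (a query exactly at the pair boundary
contributes nothing).  Both strategies are implemented portably at the
64-bit-word level (a 512-bit block is eight words, masked wordwise and
summed); SIMD intrinsics are out of scope.  The two strategies are
required to agree pointwise and are cross-checked on every benchmark run.
Mask tables are built once per width and cached, never per query.

## Strings

* **mBV** — one full indicator bit vector (with its own directory) per
  symbol: $\sigma \cdot n$ payload bits, fastest, largest.
* **fBV** — only $k = \lceil \log_2 \sigma \rceil$ bit planes are stored;
  plane $t$ holds bit $t$ of every symbol's code.  The indicator word for
  symbol $c$ is reconstructed on demand as the AND over planes (taking the
  complement where the code bit is 0).  Each symbol still gets its own
  L0/L1 directory, built over the *virtual* indicator vector.
* **pfBV** — fBV with paired directories.

Complemented planes turn padding into phantom ones, so reconstruction
forces all bits at positions ≥ `n` to zero; directories are built from the
true symbol counts, so padded tail blocks contribute nothing.  This
validity masking matters precisely in the paired layouts, where a query in
a left block counts a *suffix* that can reach into the padding.

The canonical DNA mapping is A=00, C=01, G=10, T=11 — the assignment under
which `~b1 & b0` marks the C positions.  Alphabets up to σ = 256 are
supported (8 planes).

## Storage accounting and padding

Every reported size is an exact stored-bit count: payload (padded bit
layer or planes) + 16 bits per L1 entry + 64 bits per L0 entry.  The bit
layer is zero-padded to a whole number of superblocks (non-paired) or
superblock pairs (paired), so every left member has a right partner and
every pair has a directory entry; the accounting includes that padding.
With $w_0 = 65{,}536$ the non-paired two-layer directory costs
$16 \cdot w_0/w_1 + 64$ bits per superblock — 25.10% of `n` for
$w_1 = 64$ and 3.22% for $w_1 = 512$; pairing halves both (12.55% and
1.61%).  These closed-form figures are tested to equal the byte size of
real serialized builds (file minus the fixed header) at $n = 10^4$ and
$10^6$.

One consequence of pair-padding: the paired layout stores
$\lceil |L1_{\text{nonpaired}}|/2 \rceil$ entries only when the non-paired
span has an even superblock count; an odd count rounds up to a whole extra
pair.  The halving property is therefore asserted at even-count lengths.

Two reporting conventions are fixed package-wide: overhead percent to one
decimal, bits per character to three decimals, both rounded half away from
zero.  Under this accounting the paired 64/64k overhead is 12.549 → 12.5%,
and the mBV σ=255 grid cell is 319.003 bits/char (the unpadded ratio would
be 318.999); both are printed by the package as computed.

## Counter widths and limits

L1 entries are 16-bit: the largest relative count is $w_0 - w_1 = 65{,}472$
for the default superblock, which is also why `superblock_bits` is capped
at 65,536.  L0 entries are 64-bit, so vector length is unconstrained in
practice.  The builder asserts the L1 bound on every construction.
Single-layer layouts (one 64-bit counter per block or pair) exist for
pedagogy and testing and are excluded from the space figures.

## What the synthetic generator does and does not establish

`generate_bits()`/`generate_text()` produce i.i.d. uniform bits (given
density) and symbols (uniform over σ) under a fixed Mersenne–Twister seed,
restoring the caller's RNG state.  This matches the random-text setting
the space and correctness claims are stated in — rank directories are
content-oblivious, so uniformity is not a weakness for correctness
testing, and stored size depends only on `n`, σ and the geometry, not on
content.  What uniform texts do *not* emulate: repeat structure, skewed
symbol frequencies, GC bias.  A green suite therefore establishes
correctness and exact storage for arbitrary content, but says nothing
about compressed-bit-vector opportunities (out of scope) or cache behavior
on real genomes (timing is explicitly informational).

## Numerical and degenerate-input choices

* `rank_query(x, i)` uses the prefix-length convention `i ∈ [0, n]`;
  `i = 0` returns 0 and `i = n` the total.  Counts are returned as
  doubles (exact up to $2^{53}$); R has no 64-bit integer.
* `n = 0` builds empty directories; queries other than `i = 0` error.
* A query at an exact padded-span boundary (only possible when
  `n == padded span`) short-circuits to the total instead of reading one
  directory entry past the end.
* Serialization is a versioned little-endian container; L0/L1 values are
  written as 8- and 2-byte integers through exact double↔byte conversion.

## Limitations

No `select` support, no compressed bit layers, no more than two layers, no
SIMD intrinsics, and no FM-index on top (BWT construction and backward
search are applications, not part of this package).  Benchmark output
(`bench_rank`, `rank_cli bench`) is hardware-dependent and deliberately
excluded from any correctness or acceptance claim.
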