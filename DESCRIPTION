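Package: bitrank
Title: Rank Support for Bit Vectors and Strings with Paired-Block
    Directories
Version: 1.0.0
Authors@R:
    person("Repo", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Succinct rank-query support structures for bit vectors and
    for strings over fixed alphabets (2 to 256 symbols).  Implements
    block/superblock prefix-sum directories in four layouts (one or two
    layers, paired or non-paired blocks), two block-counting strategies
    (mask-and-count and shift-and-count), and three string layouts:
    one indicator bit vector per symbol (mBV), flattened bit planes with
    on-the-fly word reconstruction (fBV), and its paired-block variant
    (pfBV).  Includes exact closed-form storage accounting (overhead
    percent, bits per character), a versioned little-endian index
    serialization, seeded synthetic generators and brute-force oracles
    for testing, and a command-line interface for building indexes,
    querying ranks, reporting space, and informational timing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    jsonlite,
    Rcpp,
    stats
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
SystemRequirements: C++17
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
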