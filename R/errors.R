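# Condition helpers.  Distinct classes let the CLI map failures to distinct
# exit codes (usage = 2, I/O = 3, data/range/alphabet/config = 4).

abort_with <- function(class, msg, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "bitrank_error"), call = call))
}

abort_usage <- function(msg) abort_with("bitrank_usage_error", msg)
abort_io <- function(msg) abort_with("bitrank_io_error", msg)
abort_config <- function(msg) abort_with("bitrank_config_error", msg)
abort_range <- function(msg) abort_with("bitrank_range_error", msg)
abort_alphabet <- function(msg) abort_with("bitrank_alphabet_error", msg)
abort_format <- function(msg) abort_with("bitrank_format_error", msg)
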