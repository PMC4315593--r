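# Structured error helpers. Every user-facing failure mode carries a
# condition class so callers (and the CLI) can map it to an exit code.

abort_sharkid <- function(msg, class, call. = FALSE) {
  stop(structure(
    class = c(class, "sharkid_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

abort_parse <- function(msg) abort_sharkid(msg, "sharkid_parse_error")
abort_domain <- function(msg) abort_sharkid(msg, "sharkid_domain_error")
abort_coord <- function(msg) abort_sharkid(msg, "sharkid_coord_error")
abort_input <- function(msg) abort_sharkid(msg, "sharkid_input_error")
abort_inseparable <- function(msg) abort_sharkid(msg, "sharkid_inseparable_error")
abort_degenerate <- function(msg) abort_sharkid(msg, "sharkid_key_degeneracy_error")
abort_lookup <- function(msg) abort_sharkid(msg, "sharkid_lookup_error")
abort_noinfo <- function(msg) abort_sharkid(msg, "sharkid_no_information_error")
abort_trim <- function(msg) abort_sharkid(msg, "sharkid_trim_error")
abort_config <- function(msg) abort_sharkid(msg, "sharkid_config_error")
abort_usage <- function(msg) abort_sharkid(msg, "sharkid_usage_error")
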