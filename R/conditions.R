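# Classed conditions so callers (and tests) can distinguish failure modes:
#   grn_config_error      - bad arguments / configuration
#   grn_parse_error       - malformed input file
#   grn_validation_error  - a table violates a documented invariant
#   grn_empty_analysis_error - an analysis retained nothing to analyse
#   grn_degenerate_test_error - a test statistic is undefined on the data

grn_stop <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "grn_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

grn_config_error <- function(msg, ...) grn_stop("grn_config_error", msg, ...)
grn_parse_error <- function(msg, ...) grn_stop("grn_parse_error", msg, ...)
grn_validation_error <- function(msg, ...) grn_stop("grn_validation_error", msg, ...)
grn_empty_analysis_error <- function(msg, ...) grn_stop("grn_empty_analysis_error", msg, ...)
grn_degenerate_test_error <- function(msg, ...) grn_stop("grn_degenerate_test_error", msg, ...)

`%||%` <- function(x, y) if (is.null(x)) y else x
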