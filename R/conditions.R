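# Classed error conditions used across the package so callers (and the CLI,
# which maps them to exit codes) can distinguish failure modes.

cxr_abort <- function(msg, class) {
  stop(structure(class = c(class, "cxrseg_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

abort_config <- function(msg) cxr_abort(msg, "cxrseg_config_error")
abort_validation <- function(msg) cxr_abort(msg, "cxrseg_validation_error")
abort_shape <- function(msg) cxr_abort(msg, "cxrseg_shape_error")
abort_data <- function(msg) cxr_abort(msg, "cxrseg_data_error")
abort_io <- function(msg) cxr_abort(msg, "cxrseg_io_error")

check_finite <- function(x, what = "input") {
  if (!all(is.finite(x))) abort_validation(paste(what, "contains non-finite values"))
  invisible(x)
}
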