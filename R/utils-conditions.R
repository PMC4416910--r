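# Classed conditions so that callers (and the CLI exit-code mapping) can
# tell usage problems, bad input files, violated mathematical preconditions
# and internal consistency failures apart.

.stopUsage <- function(msg, ...) {
  stop(structure(
    class = c("dxlinkUsageError", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

.stopFormat <- function(msg, ...) {
  stop(structure(
    class = c("dxlinkFormatError", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

.stopPrecondition <- function(msg, ...) {
  stop(structure(
    class = c("dxlinkPreconditionError", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

.stopInternal <- function(msg, ...) {
  stop(structure(
    class = c("dxlinkInternalError", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}
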