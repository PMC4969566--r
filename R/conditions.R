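# Structured error conditions. Each class maps onto one CLI exit code so the
# command-line wrappers can translate failures without string matching.

stop_io <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("iekappa_io_error", "iekappa_error")))
}

stop_param <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("iekappa_param_error", "iekappa_error")))
}

stop_degenerate <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("iekappa_degenerate_error", "iekappa_error")))
}

#' Exit code associated with a condition
#'
#' Maps the package's error classes onto the CLI exit-code convention:
#' 2 for I/O failures, 3 for invalid parameters, 4 for degenerate data,
#' 1 for anything else.
#'
#' @param cond A condition object.
#' @return An integer exit code.
#' @export
exit_code_for <- function(cond) {
  if (inherits(cond, "iekappa_io_error")) return(2L)
  if (inherits(cond, "iekappa_param_error")) return(3L)
  if (inherits(cond, "iekappa_degenerate_error")) return(4L)
  1L
}
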