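# Classed error conditions used across the package.
#
# Every error raised by ephysio carries the class "ephysio_error" plus a
# specific subclass ("ephysio_dimension_error", "ephysio_shape_error", ...)
# so that callers and tests can discriminate failure modes with
# tryCatch()/expect_error(class = ...).

ephys_abort <- function(msg, class) {
  stop(errorCondition(msg,
                      class = c(paste0("ephysio_", class, "_error"),
                                "ephysio_error", "error", "condition")))
}

#' @keywords internal
assert_that <- function(ok, msg, class = "validation") {
  if (!isTRUE(ok)) ephys_abort(msg, class)
  invisible(TRUE)
}
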