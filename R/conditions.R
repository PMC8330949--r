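#' @keywords internal
#' @noRd
strab_error <- function(message, class, stage = NULL, ...) {
  if (!is.null(stage)) {
    message <- sprintf("[stage: %s] %s", stage, message)
  }
  stop(structure(
    class = c(class, "strabscreen_error", "error", "condition"),
    list(message = message, call = sys.call(-1), stage = stage, ...)
  ))
}

#' Re-raise a stage error with the pipeline stage name attached
#' @keywords internal
#' @noRd
with_stage <- function(stage, expr) {
  withCallingHandlers(
    expr,
    strabscreen_error = function(e) {
      if (is.null(e$stage)) {
        e$stage <- stage
        e$message <- sprintf("[stage: %s] %s", stage, conditionMessage(e))
        stop(e)
      }
    }
  )
}

# Exit codes for the command-line interface
EXIT_OK <- 0L
EXIT_USAGE <- 2L
EXIT_EXTRACTION <- 3L
EXIT_IRIS <- 4L
EXIT_IO <- 5L
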