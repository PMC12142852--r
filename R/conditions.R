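#' Typed error helpers
#'
#' Every failure mode the workflow distinguishes gets its own condition class
#' (`magbroker_error_<type>`), so callers (the orchestrator, the CLI, tests)
#' can branch on the kind of failure rather than on message text. Transport
#' errors are the only retriable class.
#'
#' @param type short class suffix, e.g. `"conflict"`, `"format"`,
#'   `"unresolved"`, `"transport"`.
#' @param message human-readable message.
#' @param ... additional condition fields (e.g. `alias`, `locus`).
#' @keywords internal
#' @noRd
stop_magbroker <- function(type, message, ...) {
  rlang::abort(
    message,
    class = c(paste0("magbroker_error_", type), "magbroker_error"),
    ...
  )
}

is_magbroker_error <- function(cnd, type) {
  inherits(cnd, paste0("magbroker_error_", type))
}
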