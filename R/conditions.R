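# Structured error conditions. Every error raised by the package carries a
# machine-readable class of the form "erfusion_<code>_error" plus the common
# superclass "erfusion_error", so callers (and the CLI) can dispatch on the
# failure kind rather than parse messages.
#
# Codes in use:
#   validation  - malformed beliefs, weights, tables or trees
#   conflict    - complete conflict between evidence bodies (division by zero
#                 in the normalizing factor)
#   io          - unreadable/unwritable files or unsupported formats
#   dispatch    - unknown algorithm tag
#   degenerate  - internal states that should be unreachable (e.g. all
#                 residual mass on the weight remainder at finalization)

er_abort <- function(code, message, ...) {
  cond <- structure(
    class = c(paste0("erfusion_", code, "_error"), "erfusion_error",
              "error", "condition"),
    list(message = message, call = sys.call(-1), code = code, ...)
  )
  stop(cond)
}

#' Machine-readable error code of a condition
#'
#' Returns the short code (`"validation"`, `"conflict"`, `"io"`,
#' `"dispatch"`, `"degenerate"`) attached to an error raised by this
#' package, or `NA_character_` for foreign conditions.
#'
#' @param cond A condition object.
#' @return A single character string or `NA`.
#' @export
er_error_code <- function(cond) {
  if (inherits(cond, "erfusion_error")) cond$code else NA_character_
}
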