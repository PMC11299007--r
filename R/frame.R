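#' Frame of discernment
#'
#' A frame of discernment is the ordered, exhaustive set of mutually
#' exclusive propositions (evaluation grades) against which an object is
#' assessed -- for example disease labels in a diagnostic consultation, or
#' the grades Excellent/Good/Average/Poor/Worst in a quality survey.
#' Proposition order is significant and preserved end-to-end: it defines the
#' column order of every degrees-of-belief matrix and of every fused result.
#'
#' Only singleton propositions plus the whole frame are modelled; belief on
#' other proper subsets of the frame is out of scope.
#'
#' @param propositions Character vector of unique, non-empty proposition
#'   labels, length >= 1.
#' @return An object of class `er_frame` with elements `propositions` and
#'   `N` (the number of propositions).
#' @examples
#' er_frame(c("Cold", "Common pneumonia", "COVID-19"))
#' @export
er_frame <- function(propositions) {
  if (inherits(propositions, "er_frame")) return(propositions)
  propositions <- as.character(propositions)
  if (length(propositions) < 1L)
    er_abort("validation", "a frame needs at least one proposition")
  if (anyNA(propositions) || any(!nzchar(trimws(propositions))))
    er_abort("validation", "proposition labels must be non-empty strings")
  if (anyDuplicated(propositions)) {
    dup <- unique(propositions[duplicated(propositions)])
    er_abort("validation",
             sprintf("duplicate proposition labels: %s",
                     paste(dup, collapse = ", ")))
  }
  structure(list(propositions = propositions, N = length(propositions)),
            class = "er_frame")
}

#' @export
print.er_frame <- function(x, ...) {
  cat(sprintf("<er_frame: %d propositions>\n", x$N))
  cat(" ", paste(x$propositions, collapse = " | "), "\n")
  invisible(x)
}

#' @export
length.er_frame <- function(x) x$N

# Default frame with generic labels, used when beliefs arrive unnamed.
default_frame <- function(n) er_frame(paste("Proposition", seq_len(n)))
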