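# Core belief types: evidence bodies, weight vectors and basic probability
# mass assignments.

#' Normalize evidence weights
#'
#' Evidence weights express the relative importance of each source and are
#' normalized to sum to one before fusion. Callers may pass raw importances
#' (e.g. 10, 8, 5 for three experts); normalization is applied automatically
#' at the fusion boundary.
#'
#' @param raw Numeric vector of non-negative weights, length >= 1, with at
#'   least one positive entry.
#' @return Numeric vector of the same length summing to 1; order preserved.
#' @examples
#' normalize_weights(c(10, 8, 5))
#' @export
normalize_weights <- function(raw) {
  raw <- as.numeric(raw)
  if (length(raw) < 1L)
    er_abort("validation", "weight vector must have length >= 1")
  if (anyNA(raw))
    er_abort("validation", "weights must not contain missing values")
  if (any(raw < 0))
    er_abort("validation",
             sprintf("negative weight at position %d",
                     which(raw < 0)[1L]))
  s <- sum(raw)
  if (s <= 0)
    er_abort("validation", "all weights are zero; at least one must be > 0")
  raw / s
}

#' Construct and validate an evidence body
#'
#' One body of evidence assigns a belief degree in `[0, 1]` to each
#' proposition of the frame; whatever belief is left unassigned,
#' `1 - sum(beliefs)`, is the evidence's ignorance (incompleteness).
#' Belief sums slightly above 1 -- as arise when inputs are percentages
#' rounded to two decimals -- are tolerated up to `tol` and rescaled back
#' onto the simplex; larger violations are validation errors.
#'
#' @param beliefs Numeric vector of belief degrees, one per proposition.
#' @param frame An [er_frame], or `NULL` to derive one from the names of
#'   `beliefs` (falling back to generic "Proposition i" labels).
#' @param label Free-text identifier used in error messages.
#' @param tol Acceptable overshoot of `sum(beliefs)` above 1 before the
#'   input is rejected (default `1e-3`).
#' @return An object of class `evidence_body` with elements `label`,
#'   `beliefs` (named by proposition) and `ignorance`.
#' @examples
#' evidence_body(c(0.9, 0, 0), er_frame(c("Cold", "Pneumonia", "COVID-19")))
#' @export
evidence_body <- function(beliefs, frame = NULL, label = "", tol = 1e-3) {
  beliefs <- as.numeric(beliefs)
  if (is.null(frame)) {
    frame <- if (!is.null(names(beliefs))) er_frame(names(beliefs))
             else default_frame(length(beliefs))
  }
  frame <- er_frame(frame)
  who <- if (nzchar(label)) sprintf(" (evidence '%s')", label) else ""
  if (length(beliefs) != frame$N)
    er_abort("validation",
             sprintf("expected %d belief degrees, got %d%s",
                     frame$N, length(beliefs), who))
  if (anyNA(beliefs))
    er_abort("validation", sprintf("missing belief degree%s", who))
  if (any(beliefs < 0) || any(beliefs > 1)) {
    bad <- which(beliefs < 0 | beliefs > 1)[1L]
    er_abort("validation",
             sprintf("belief degree %g for '%s' outside [0, 1]%s",
                     beliefs[bad], frame$propositions[bad], who))
  }
  s <- sum(beliefs)
  # 1e-12 of slack on top of tol so that tol = 0 still accepts sums that
  # exceed 1 only by floating-point round-off
  if (s > 1 + tol + 1e-12)
    er_abort("validation",
             sprintf("belief degrees sum to %g > 1 + tol%s", s, who))
  if (s > 1) {           # rounding overshoot: pull back onto the simplex
    beliefs <- beliefs / s
    s <- 1
  }
  names(beliefs) <- frame$propositions
  structure(list(label = label, beliefs = beliefs,
                 ignorance = max(0, 1 - s), frame = frame),
            class = "evidence_body")
}

#' @export
print.evidence_body <- function(x, digits = 4, ...) {
  cat(sprintf("<evidence_body%s>\n",
              if (nzchar(x$label)) paste0(" '", x$label, "'") else ""))
  print(round(c(x$beliefs, Theta = x$ignorance), digits))
  invisible(x)
}

# Coerce a list of evidence bodies / matrix / data.frame into a list of
# evidence_body over a common frame. Rows of a matrix are evidence bodies.
as_evidence_list <- function(evidence, frame = NULL, tol = 1e-3) {
  if (inherits(evidence, "evidence_body")) evidence <- list(evidence)
  if (is.data.frame(evidence)) evidence <- as.matrix(evidence)
  if (is.matrix(evidence)) {
    if (is.null(frame) && !is.null(colnames(evidence)))
      frame <- er_frame(colnames(evidence))
    if (is.null(frame)) frame <- default_frame(ncol(evidence))
    labels <- rownames(evidence)
    if (is.null(labels)) labels <- paste("Evidence", seq_len(nrow(evidence)))
    evidence <- lapply(seq_len(nrow(evidence)), function(i)
      evidence_body(evidence[i, ], frame, label = labels[i], tol = tol))
    return(evidence)
  }
  if (!is.list(evidence) || length(evidence) < 1L)
    er_abort("validation",
             "evidence must be a matrix, data.frame or list of evidence bodies")
  if (is.null(frame)) {
    first <- evidence[[1L]]
    frame <- if (inherits(first, "evidence_body")) first$frame
             else default_frame(length(first))
  }
  frame <- er_frame(frame)
  lapply(seq_along(evidence), function(i) {
    e <- evidence[[i]]
    if (inherits(e, "evidence_body")) {
      if (e$frame$N != frame$N ||
          !identical(e$frame$propositions, frame$propositions))
        er_abort("validation",
                 sprintf("evidence %d is defined on a different frame", i))
      e
    } else {
      evidence_body(e, frame, label = paste("Evidence", i), tol = tol)
    }
  })
}

#' Basic probability masses of one weighted evidence body
#'
#' Converts an evidence body with weight `w` into its basic probability
#' mass assignment: each proposition receives `m_n = w * p_n`, while the
#' unassigned mass splits into two parts with distinct meanings --
#' `m_tilde = w * (1 - sum(p))`, driven by the incompleteness of the
#' evidence itself, and `m_bar = 1 - w`, the mass withheld because the
#' source does not carry full weight. The four components always sum to 1.
#' This separation of the two kinds of ignorance is what distinguishes the
#' ER combination from Dempster's rule.
#'
#' @param evidence An [evidence_body] (or a plain belief vector).
#' @param weight A single weight in `[0, 1]`, taken from a normalized
#'   weight vector.
#' @return An object of class `mass_assignment` with elements
#'   `prop_masses`, `m_tilde` and `m_bar`.
#' @examples
#' e <- evidence_body(c(0.9, 0, 0))
#' evidence_masses(e, 10 / 23)
#' @export
evidence_masses <- function(evidence, weight) {
  if (!inherits(evidence, "evidence_body"))
    evidence <- evidence_body(evidence)
  weight <- as.numeric(weight)
  if (length(weight) != 1L || is.na(weight) || weight < 0 || weight > 1)
    er_abort("validation", "weight must be a single number in [0, 1]")
  mass_assignment(prop_masses = weight * evidence$beliefs,
                  m_tilde = weight * evidence$ignorance,
                  m_bar = 1 - weight)
}

mass_assignment <- function(prop_masses, m_tilde, m_bar) {
  structure(list(prop_masses = prop_masses, m_tilde = m_tilde,
                 m_bar = m_bar),
            class = "mass_assignment")
}

#' @export
print.mass_assignment <- function(x, digits = 4, ...) {
  cat("<mass_assignment>\n")
  print(round(c(x$prop_masses, m_tilde = x$m_tilde, m_bar = x$m_bar),
        digits))
  invisible(x)
}

# Total unassigned mass m_Theta = m_tilde + m_bar.
total_ignorance_mass <- function(mass) mass$m_tilde + mass$m_bar
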