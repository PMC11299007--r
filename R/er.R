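# The recursive evidential reasoning (ER) combination.
#
# Evidence bodies are first discounted by their normalized weights into
# basic probability masses (see evidence_masses), then folded pairwise,
# left to right, through the recursive combination below. Writing a_n for
# the aggregate proposition masses, a~ / a- for its incompleteness and
# weight-remainder ignorance, and b_n, b~, b- for the incoming mass:
#
#   conflict = sum over n != k of a_n * b_k
#   K        = 1 / (1 - conflict)                     (normalizing factor)
#   a_n'     = K * (a_n b_n + a_n (b~ + b-) + b_n (a~ + a-))
#   a~'      = K * (a~ b~ + a- b~ + a~ b-)
#   a-'      = K * (a- b-)
#
# K restores unit total mass after each step; the operator is commutative
# and associative, so the left-to-right fold order only fixes
# floating-point reproducibility. The conflict sum is computed as
# (sum a)(sum b) - sum(a*b), which equals the literal double sum at O(N)
# cost. After all L bodies are folded, the weight-remainder mass a- is
# normalized away to yield the final belief degrees:
#
#   p_n     = a_n / (1 - a-)       p_Theta = a~ / (1 - a-)

# Threshold below which the K denominator is treated as complete conflict.
.conflict_eps <- 1e-12

new_fusion_state <- function(mass) {
  structure(list(aggregate = mass, count = 1L, last_K = 1),
            class = "fusion_state")
}

#' One step of the recursive ER combination
#'
#' Folds the next basic probability mass assignment into a running fusion
#' state. Exposed mainly for diagnostics and testing; most callers should
#' use [er_fuse()].
#'
#' @param state A fusion state as returned by a previous `combine_pair()`
#'   call, or a bare [mass_assignment][evidence_masses] for the first body.
#' @param next_mass The [mass_assignment][evidence_masses] of the next
#'   evidence body.
#' @return A `fusion_state` with the updated aggregate mass, the number of
#'   bodies combined so far, and the normalizing factor `last_K` of this
#'   step.
#' @export
combine_pair <- function(state, next_mass) {
  if (inherits(state, "mass_assignment")) state <- new_fusion_state(state)
  if (!inherits(state, "fusion_state") ||
      !inherits(next_mass, "mass_assignment"))
    er_abort("validation", "combine_pair expects a fusion state and a mass")
  a <- state$aggregate
  b <- next_mass
  if (length(a$prop_masses) != length(b$prop_masses))
    er_abort("validation",
             sprintf("mass dimension mismatch at step %d: %d vs %d",
                     state$count + 1L, length(a$prop_masses),
                     length(b$prop_masses)))

  an <- a$prop_masses; bn <- b$prop_masses
  conflict <- sum(an) * sum(bn) - sum(an * bn)
  denom <- 1 - conflict
  if (denom <= .conflict_eps)
    er_abort("conflict",
             sprintf(paste0("complete conflict at combination step %d: ",
                            "the evidence bodies support disjoint ",
                            "propositions with total belief"),
                     state$count + 1L),
             step = state$count + 1L)
  K <- 1 / denom

  a_theta <- total_ignorance_mass(a)
  b_theta <- total_ignorance_mass(b)
  agg <- mass_assignment(
    prop_masses = K * (an * bn + an * b_theta + bn * a_theta),
    m_tilde = K * (a$m_tilde * b$m_tilde + a$m_bar * b$m_tilde +
                     a$m_tilde * b$m_bar),
    m_bar = K * (a$m_bar * b$m_bar)
  )
  structure(list(aggregate = agg, count = state$count + 1L, last_K = K),
            class = "fusion_state")
}

#' Extract final belief degrees from a fusion state
#'
#' Normalizes the weight-remainder ignorance out of the aggregate mass,
#' returning combined belief degrees that sum to 1 together with the
#' residual uncertainty.
#'
#' @param state A `fusion_state` (or a bare mass assignment for a single
#'   body).
#' @param frame Optional [er_frame] naming the propositions.
#' @param algorithm Tag recorded on the result (default `"ER"`).
#' @return A [fusion_result].
#' @export
finalize <- function(state, frame = NULL, algorithm = "ER") {
  if (inherits(state, "mass_assignment")) state <- new_fusion_state(state)
  agg <- state$aggregate
  denom <- 1 - agg$m_bar
  if (denom <= .conflict_eps)
    er_abort("degenerate",
             "all residual mass on the weight remainder; cannot normalize")
  fusion_result(beliefs = agg$prop_masses / denom,
                uncertainty = agg$m_tilde / denom,
                algorithm = algorithm, frame = frame)
}

fusion_result <- function(beliefs, uncertainty, algorithm, frame = NULL) {
  beliefs <- as.numeric(beliefs) + 0  # drop incoming attributes
  if (is.null(frame)) frame <- default_frame(length(beliefs))
  frame <- er_frame(frame)
  names(beliefs) <- frame$propositions
  structure(list(beliefs = beliefs, uncertainty = as.numeric(uncertainty),
                 algorithm = algorithm, frame = frame),
            class = "fusion_result")
}

#' @export
print.fusion_result <- function(x, digits = 4, ...) {
  cat(sprintf("<fusion_result: %s>\n", x$algorithm))
  print(round(c(x$beliefs, Uncertainty = x$uncertainty), digits))
  invisible(x)
}

#' @export
as.data.frame.fusion_result <- function(x, ...) {
  d <- as.data.frame(as.list(x$beliefs), check.names = FALSE)
  d$Uncertainty <- x$uncertainty
  d
}

#' Fuse multiple evidence bodies with the ER approach
#'
#' The workhorse of the package. Takes a degrees-of-belief matrix (one row
#' per evidence body, one column per proposition) or a list of
#' [evidence_body] objects, together with raw importance weights; weights
#' are normalized automatically, each body is converted to basic
#' probability masses, the masses are combined recursively, and the final
#' belief degrees are extracted.
#'
#' @param evidence Matrix/data.frame (rows = evidence bodies) or list of
#'   [evidence_body] objects.
#' @param weights Numeric vector of raw importances, one per body. Raw
#'   values such as `c(10, 8, 5)` are accepted and normalized.
#' @param frame Optional [er_frame]; derived from column names or body
#'   frames when omitted.
#' @param tol Belief-sum tolerance passed to [evidence_body()].
#' @param normalize Normalize the weights before fusing (default `TRUE`).
#'   Setting this to `FALSE` with unit weights makes the combination
#'   reduce exactly to Dempster's rule; it is exposed as a verification
#'   hook and is not meant for routine use.
#' @return A [fusion_result] with combined belief degrees `beliefs`
#'   (summing with `uncertainty` to 1) and the residual `uncertainty`.
#' @examples
#' dbf <- rbind(c(0.9, 0, 0), c(0, 0.9, 0), c(0, 0, 0.9))
#' colnames(dbf) <- c("Cold", "Common pneumonia", "COVID-19")
#' er_fuse(dbf, weights = c(10, 8, 5))
#' @export
er_fuse <- function(evidence, weights, frame = NULL, tol = 1e-3,
                    normalize = TRUE) {
  n_rows <- if (is.matrix(evidence) || is.data.frame(evidence))
    nrow(evidence) else if (inherits(evidence, "evidence_body")) 1L
    else length(evidence)
  if (length(weights) != n_rows)
    er_abort("validation",
             sprintf("%d evidence bodies but %d weights", n_rows,
                     length(weights)))
  bodies <- as_evidence_list(evidence, frame, tol = tol)
  frame <- bodies[[1L]]$frame
  if (normalize) {
    weights <- normalize_weights(weights)
  } else {
    weights <- as.numeric(weights)
    if (any(is.na(weights)) || any(weights < 0) || any(weights > 1))
      er_abort("validation", "un-normalized weights must lie in [0, 1]")
  }
  state <- new_fusion_state(evidence_masses(bodies[[1L]], weights[1L]))
  for (i in seq_along(bodies)[-1L])
    state <- combine_pair(state, evidence_masses(bodies[[i]], weights[i]))
  finalize(state, frame, algorithm = "ER")
}
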