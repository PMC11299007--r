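# Weight-free combination rules: Dempster, Yager, Murphy.
#
# These operate on simple bodies of evidence where the only ignorance is
# the evidence's own incompleteness (mass on the whole frame Theta); no
# weights are involved. Focal elements are restricted to singleton
# propositions plus Theta, which is what the evidence_body type encodes.

# (masses, theta) representation of an unweighted body.
simple_mass <- function(body) {
  list(m = body$beliefs, theta = body$ignorance)
}

#' Pairwise conflict between two evidence bodies
#'
#' The total product mass two bodies place on disjoint proposition pairs,
#' `sum over n != k of a_n * b_k`. A value of 1 means complete conflict,
#' under which Dempster's rule is undefined.
#'
#' @param a,b [evidence_body] objects (or plain belief vectors) on the
#'   same frame.
#' @return A single number in `[0, 1]`.
#' @examples
#' pairwise_conflict(c(0.9, 0, 0), c(0, 0.9, 0))  # 0.81
#' @export
pairwise_conflict <- function(a, b) {
  if (!inherits(a, "evidence_body")) a <- evidence_body(a)
  if (!inherits(b, "evidence_body")) b <- evidence_body(b)
  if (length(a$beliefs) != length(b$beliefs))
    er_abort("validation", "conflict requires bodies on the same frame")
  sum(a$beliefs) * sum(b$beliefs) - sum(a$beliefs * b$beliefs)
}

# One Dempster step on simple masses; errors on complete conflict.
dempster_pair <- function(a, b, step = NA_integer_) {
  conflict <- sum(a$m) * sum(b$m) - sum(a$m * b$m)
  denom <- 1 - conflict
  if (denom <= .conflict_eps)
    er_abort("conflict",
             sprintf("complete conflict at combination step %s",
                     ifelse(is.na(step), "?", step)),
             step = step)
  list(m = (a$m * b$m + a$m * b$theta + b$m * a$theta) / denom,
       theta = (a$theta * b$theta) / denom)
}

# One Yager step: same numerators, no renormalization; the conflict mass
# is routed to Theta. Total, even under complete conflict.
yager_pair <- function(a, b) {
  conflict <- sum(a$m) * sum(b$m) - sum(a$m * b$m)
  list(m = a$m * b$m + a$m * b$theta + b$m * a$theta,
       theta = a$theta * b$theta + conflict)
}

rule_prep <- function(evidence, frame, weights, tol, rule) {
  if (!is.null(weights))
    warning(sprintf("%s combination is weight-free; weights are ignored",
                    rule), call. = FALSE)
  bodies <- as_evidence_list(evidence, frame, tol = tol)
  list(bodies = bodies, frame = bodies[[1L]]$frame)
}

#' Dempster's rule of combination
#'
#' Combines unweighted evidence bodies by Dempster's rule, restricted to
#' singleton focal elements plus the whole frame: the product masses that
#' agree on a proposition (or meet the frame's ignorance) are kept and
#' renormalized by one minus the conflict. With unit weights the ER
#' combination of [er_fuse()] reduces exactly to this rule, which makes it
#' a useful cross-check.
#'
#' @param evidence Matrix/data.frame/list of bodies as in [er_fuse()].
#' @param frame Optional [er_frame].
#' @param weights Ignored with a warning if supplied; present so that
#'   weight-bearing input files can be dispatched here unchanged.
#' @param tol Belief-sum tolerance.
#' @return A [fusion_result] (`uncertainty` is the final mass on the
#'   frame).
#' @examples
#' dempster_fuse(rbind(c(0.9, 0, 0), c(0, 0.9, 0)))
#' @export
dempster_fuse <- function(evidence, frame = NULL, weights = NULL,
                          tol = 1e-3) {
  prep <- rule_prep(evidence, frame, weights, tol, "Dempster")
  ms <- lapply(prep$bodies, simple_mass)
  acc <- ms[[1L]]
  for (i in seq_along(ms)[-1L]) acc <- dempster_pair(acc, ms[[i]], step = i)
  fusion_result(acc$m, acc$theta, "Dempster", prep$frame)
}

#' Yager's rule of combination
#'
#' Like Dempster's rule but without renormalization: the conflicting mass
#' is assigned to the whole frame as extra ignorance instead of being
#' redistributed. The rule is therefore total -- complete conflict yields
#' all mass on the frame rather than an error. Combination of more than
#' two bodies is performed pairwise left-to-right in input order; unlike
#' Dempster's rule, sequential Yager combination is order-dependent, so
#' the input order matters.
#'
#' @inheritParams dempster_fuse
#' @return A [fusion_result].
#' @examples
#' yager_fuse(rbind(c(0.9, 0, 0), c(0, 0.9, 0)))
#' @export
yager_fuse <- function(evidence, frame = NULL, weights = NULL, tol = 1e-3) {
  prep <- rule_prep(evidence, frame, weights, tol, "Yager")
  ms <- lapply(prep$bodies, simple_mass)
  acc <- ms[[1L]]
  for (i in seq_along(ms)[-1L]) acc <- yager_pair(acc, ms[[i]])
  fusion_result(acc$m, acc$theta, "Yager", prep$frame)
}

#' Murphy's averaging rule of combination
#'
#' Averages the `L` bodies component-wise (beliefs and ignorance alike)
#' and then combines the average with itself `L - 1` times under
#' Dempster's rule. Averaging first makes the rule robust to conflicting
#' sources that would destabilize a direct Dempster combination.
#'
#' @inheritParams dempster_fuse
#' @return A [fusion_result]. A single body is returned unchanged.
#' @examples
#' murphy_fuse(rbind(c(0.9, 0), c(0, 0.9)))
#' @export
murphy_fuse <- function(evidence, frame = NULL, weights = NULL, tol = 1e-3) {
  prep <- rule_prep(evidence, frame, weights, tol, "Murphy")
  bodies <- prep$bodies
  L <- length(bodies)
  mean_m <- Reduce(`+`, lapply(bodies, function(b) b$beliefs)) / L
  mean_theta <- sum(vapply(bodies, function(b) b$ignorance, 0)) / L
  avg <- list(m = mean_m, theta = mean_theta)
  acc <- avg
  if (L >= 2L)
    for (i in seq_len(L - 1L)) acc <- dempster_pair(acc, avg, step = i + 1L)
  fusion_result(acc$m, acc$theta, "Murphy", prep$frame)
}
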