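#' Randomised elicitation order with a fixed anchor
#'
#' The therapy the panel knows best is discussed first for every expert
#' (to anchor the exercise where certainty is highest); the remaining
#' therapies follow in a seeded uniform random permutation, so that
#' sequence effects average out across experts.
#'
#' @param therapies character vector of therapy identifiers.
#' @param anchor identifier elicited first; must be in `therapies`.
#' @param seed optional integer seed (caller's RNG state preserved).
#' @return Character vector: `anchor` followed by a permutation of the
#'   rest.
#' @export
make_elicitation_order <- function(therapies, anchor = therapies[[1]], seed = NULL) {
  therapies <- as.character(therapies)
  if (!anchor %in% therapies) {
    stop_domain("anchor '", anchor, "' is not among the therapies")
  }
  rest <- setdiff(therapies, anchor)
  tail <- if (length(rest) > 1L) with_seed(seed, sample(rest)) else rest
  c(anchor, tail)
}

#' One expert's questionnaire response
#'
#' @param expert_id unique identifier within a session.
#' @param placebo a [placebo_answers()] object.
#' @param effects named list of [effect_answers()], one per therapy.
#' @return An object of class `questionnaire_response`.
#' @export
questionnaire_response <- function(expert_id, placebo, effects) {
  stopifnot(is.character(expert_id), length(expert_id) == 1L,
            inherits(placebo, "placebo_answers"), is.list(effects))
  if (is.null(names(effects)) || any(names(effects) == "") ||
      anyDuplicated(names(effects))) {
    stop_domain("effects must be a uniquely named list of effect_answers")
  }
  ok <- vapply(effects, inherits, logical(1), what = "effect_answers")
  if (!all(ok)) {
    stop_domain("effects entries are not effect_answers: ",
                paste(names(effects)[!ok], collapse = ", "))
  }
  structure(list(expert_id = expert_id, placebo = placebo, effects = effects),
            class = "questionnaire_response")
}

#' Fit one expert's priors from their questionnaire response
#'
#' Applies [fit_beta_from_answers()] to the placebo answers and
#' [fit_logor_from_answers()] to each therapy, and attaches a fresh
#' randomised elicitation order. Any per-therapy fit failure aborts the
#' whole fit, naming the therapy; partial prior sets are never emitted.
#'
#' @param resp a [questionnaire_response()].
#' @param therapies therapy identifiers the session elicits; the
#'   response must cover all of them.
#' @param anchor therapy elicited first (default the first listed).
#' @param seed seed for the elicitation order.
#' @return An object of class `expert_prior_set` (unlocked).
#' @export
fit_expert <- function(resp, therapies = names(resp$effects),
                       anchor = therapies[[1]], seed = NULL) {
  stopifnot(inherits(resp, "questionnaire_response"))
  therapies <- as.character(therapies)
  missing <- setdiff(therapies, names(resp$effects))
  if (length(missing)) {
    stop_domain("expert '", resp$expert_id, "' has no answers for: ",
                paste(missing, collapse = ", "))
  }
  placebo_prior <- tryCatch(
    fit_beta_from_answers(resp$placebo),
    priorelicit_fit_error = function(e) {
      stop_domain("expert '", resp$expert_id, "', placebo: ", conditionMessage(e))
    })
  effect_priors <- lapply(therapies, function(tid) {
    tryCatch(fit_logor_from_answers(resp$effects[[tid]]),
             error = function(e) {
               stop_domain("expert '", resp$expert_id, "', therapy '", tid,
                           "': ", conditionMessage(e))
             })
  })
  names(effect_priors) <- therapies
  structure(list(expert_id = resp$expert_id,
                 placebo_prior = placebo_prior,
                 effect_priors = effect_priors,
                 elicitation_order = make_elicitation_order(therapies, anchor, seed),
                 locked = FALSE),
            class = "expert_prior_set")
}

#' Lock an expert's priors
#'
#' After the group discussion each expert's individual priors are
#' "locked": any subsequent mutation attempt raises an error.
#'
#' @param expert an `expert_prior_set`.
#' @return The locked set.
#' @export
lock_expert <- function(expert) {
  stopifnot(inherits(expert, "expert_prior_set"))
  ex <- unclass(expert)
  ex$locked <- TRUE
  structure(ex, class = "expert_prior_set")
}

#' @export
is_locked <- function(expert) UseMethod("is_locked")

#' @export
is_locked.expert_prior_set <- function(expert) isTRUE(expert$locked)

assert_unlocked <- function(x) {
  if (isTRUE(unclass(x)$locked)) {
    stop(errorCondition("expert prior set is locked and cannot be modified",
                        class = c("priorelicit_state_error", "error")))
  }
}

#' @export
`$<-.expert_prior_set` <- function(x, name, value) {
  assert_unlocked(x)
  NextMethod()
}

#' @export
`[[<-.expert_prior_set` <- function(x, i, value) {
  assert_unlocked(x)
  NextMethod()
}

#' Equal-weight linear opinion pool of expert densities
#'
#' Pointwise average of the member densities on a common grid, used as
#' the overlay for group discussion. For `target = "placebo"` each
#' member density is the expert's Beta pdf; for a therapy it is the
#' expert's own induced response-rate density. All experts carry equal
#' weight, so duplicating the expert list leaves the pool unchanged.
#' The pool is a discussion aid only: it is never auto-promoted to a
#' consensus, which is reached behaviourally.
#'
#' @param experts nonempty list of `expert_prior_set`s.
#' @param target `"placebo"` or a therapy identifier.
#' @param grid probability grid for the pooled density.
#' @return A [density_grid()].
#' @export
pool_densities <- function(experts, target = "placebo", grid = default_grid()) {
  if (!is.list(experts) || length(experts) == 0L) {
    stop_domain("experts must be a nonempty list of expert prior sets")
  }
  stopifnot(all(vapply(experts, inherits, logical(1), "expert_prior_set")))
  member <- function(ex) {
    if (identical(target, "placebo")) {
      stats::dbeta(grid, ex$placebo_prior$alpha, ex$placebo_prior$beta)
    } else {
      if (!target %in% names(ex$effect_priors)) {
        stop_domain("expert '", ex$expert_id, "' has no prior for '", target, "'")
      }
      induced_density(ex$placebo_prior, ex$effect_priors[[target]], grid)$values
    }
  }
  vals <- rowMeans(vapply(experts, member, numeric(length(grid))))
  density_grid(grid, vals)
}

#' Create an elicitation session
#'
#' A session tracks the therapy list, the anchor therapy, the fitted
#' expert prior sets, and (eventually) the recorded consensus.
#'
#' @param therapies character vector of therapy identifiers.
#' @param anchor therapy elicited first for every expert.
#' @return An object of class `elicitation_session`.
#' @export
elicitation_session <- function(therapies, anchor = therapies[[1]]) {
  therapies <- as.character(therapies)
  if (length(therapies) == 0L || anyDuplicated(therapies)) {
    stop_domain("therapies must be a nonempty vector of unique identifiers")
  }
  if (!anchor %in% therapies) stop_domain("anchor must be one of the therapies")
  structure(list(therapies = therapies, anchor = anchor,
                 experts = list(), consensus = NULL,
                 schema_version = "1.0"),
            class = "elicitation_session")
}

#' Add a fitted expert to a session
#' @param session an [elicitation_session()].
#' @param expert an `expert_prior_set` covering the session's therapies.
#' @return The updated session.
#' @export
add_expert <- function(session, expert) {
  stopifnot(inherits(session, "elicitation_session"),
            inherits(expert, "expert_prior_set"))
  if (!setequal(names(expert$effect_priors), session$therapies)) {
    stop_domain("expert '", expert$expert_id,
                "' does not cover the session therapy list")
  }
  ids <- vapply(session$experts, `[[`, character(1), "expert_id")
  if (expert$expert_id %in% ids) {
    stop_domain("duplicate expert id '", expert$expert_id, "'")
  }
  session$experts <- c(session$experts, list(expert))
  session
}

#' Record the behavioural consensus of a session
#'
#' The consensus placebo prior is fitted from the voted pair of
#' questionnaire answers; per-therapy consensus Normals are entered
#' either directly as [logor_prior()]s or as [effect_answers()] (both
#' entry paths are supported because a group may agree on answers or on
#' parameters). All experts must be locked first.
#'
#' @param session an [elicitation_session()] whose experts are locked.
#' @param placebo_vote a [placebo_answers()]: the voted answer pair.
#' @param effect_decisions named list over the session therapies, each a
#'   [logor_prior()] or [effect_answers()].
#' @param notes optional named list of free-text provenance notes (vote
#'   tallies, discussion record) merged into the provenance.
#' @return A [consensus_prior_set()].
#' @export
record_consensus <- function(session, placebo_vote, effect_decisions,
                             notes = list()) {
  stopifnot(inherits(session, "elicitation_session"),
            inherits(placebo_vote, "placebo_answers"))
  unlocked <- vapply(session$experts, function(e) !is_locked(e), logical(1))
  if (any(unlocked)) {
    ids <- vapply(session$experts[unlocked], `[[`, character(1), "expert_id")
    stop(errorCondition(
      paste0("consensus cannot be recorded while experts are unlocked: ",
             paste(ids, collapse = ", ")),
      class = c("priorelicit_state_error", "error")))
  }
  missing <- setdiff(session$therapies, names(effect_decisions))
  if (length(missing)) {
    stop_domain("no consensus decision for: ", paste(missing, collapse = ", "))
  }
  effect_priors <- lapply(session$therapies, function(tid) {
    dec <- effect_decisions[[tid]]
    if (inherits(dec, "logor_prior")) dec
    else if (inherits(dec, "effect_answers")) fit_logor_from_answers(dec)
    else stop_domain("decision for '", tid,
                     "' must be a logor_prior or effect_answers")
  })
  names(effect_priors) <- session$therapies
  prov <- c(list(
    placebo = sprintf("fitted from voted answers: median %.4g, %.4g-quantile %.4g",
                      placebo_vote$central, placebo_vote$bound_prob,
                      placebo_vote$bound),
    n_experts = length(session$experts),
    aggregation = "behavioural (facilitated group discussion), equal expert weighting"
  ), notes)
  consensus_prior_set(fit_beta_from_answers(placebo_vote), effect_priors, prov)
}

#' Consensus prior set
#'
#' The group's agreed control Beta prior plus per-therapy Normal
#' log-odds-ratio priors, with free-text provenance.
#'
#' @param placebo_prior a [beta_prior()].
#' @param effect_priors named list of [logor_prior()]s.
#' @param provenance named list of free-text notes.
#' @param labels optional named character vector of display labels per
#'   therapy id.
#' @return An object of class `consensus_prior_set`.
#' @export
consensus_prior_set <- function(placebo_prior, effect_priors,
                                provenance = list(), labels = NULL) {
  stopifnot(inherits(placebo_prior, "beta_prior"), is.list(effect_priors))
  if (is.null(names(effect_priors)) || any(names(effect_priors) == "")) {
    stop_domain("effect_priors must be a named list")
  }
  ok <- vapply(effect_priors, inherits, logical(1), "logor_prior")
  if (!all(ok)) {
    stop_domain("effect_priors entries are not logor_prior: ",
                paste(names(effect_priors)[!ok], collapse = ", "))
  }
  structure(list(placebo_prior = placebo_prior, effect_priors = effect_priors,
                 provenance = provenance, labels = labels),
            class = "consensus_prior_set")
}

#' @export
print.consensus_prior_set <- function(x, ...) {
  cat(sprintf("Consensus prior set: placebo Beta(%.3g, %.3g) + %d therapies\n",
              x$placebo_prior$alpha, x$placebo_prior$beta,
              length(x$effect_priors)))
  for (tid in names(x$effect_priors)) {
    th <- x$effect_priors[[tid]]
    cat(sprintf("  %-15s N(%.3g, %.3g^2)\n", tid, th$mean, th$sd))
  }
  invisible(x)
}
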