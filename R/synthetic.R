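#' Heterogeneity configuration for synthetic experts
#'
#' Controls a panel of simulated experts whose questionnaire answers are
#' independent perturbations of a true consensus: central answers are
#' jittered on the logit (placebo) / log-odds-ratio (effect) scale, and
#' uncertainty widths are jittered multiplicatively on the log scale.
#' The defaults emulate a panel of 11 experts with visibly diverse but
#' mutually consistent opinions, the typical picture of a single-day
#' elicitation workshop.
#'
#' @param n_experts panel size (>= 1); default 11.
#' @param central_jitter_sd sd of the additive perturbation of central
#'   answers on the transformed scale; default 0.3.
#' @param width_jitter_sd sd of the log-scale multiplicative jitter of
#'   uncertainty widths; default 0.15.
#' @param bound_prob confidence level the synthetic answers attach to
#'   their upper bounds; default 0.95.
#' @param seed optional integer seed for reproducible panels.
#' @return An object of class `heterogeneity_config`.
#' @export
heterogeneity_config <- function(n_experts = 11, central_jitter_sd = 0.3,
                                 width_jitter_sd = 0.15, bound_prob = 0.95,
                                 seed = NULL) {
  if (!is.numeric(n_experts) || n_experts < 1) {
    stop_domain("n_experts must be >= 1")
  }
  if (central_jitter_sd < 0 || width_jitter_sd < 0) {
    stop_domain("jitter standard deviations must be nonnegative")
  }
  check_prob(bound_prob, "bound_prob")
  structure(list(n_experts = as.integer(n_experts),
                 central_jitter_sd = central_jitter_sd,
                 width_jitter_sd = width_jitter_sd,
                 bound_prob = bound_prob,
                 seed = seed),
            class = "heterogeneity_config")
}

#' Generate synthetic questionnaire responses around a true consensus
#'
#' For each expert, the placebo central answer is
#' `expit(logit(truth median) + e)` with `e ~ N(0, central_jitter_sd^2)`
#' and the upper bound sits at the truth's logit-scale width multiplied
#' by `exp(N(0, width_jitter_sd^2))`; effect answers are perturbed
#' analogously on the log-odds-ratio scale. Draws violating the
#' questionnaire invariants are resampled (at most 100 attempts each).
#' With both jitters zero every expert reproduces the truth exactly.
#'
#' @param truth a [consensus_prior_set()] acting as the true consensus;
#'   the packaged [pfcd_consensus()] is the natural default.
#' @param cfg a [heterogeneity_config()].
#' @return List of `cfg$n_experts` [questionnaire_response()] objects,
#'   byte-identical across calls with the same truth, config, and seed.
#' @export
generate_responses <- function(truth, cfg) {
  stopifnot(inherits(truth, "consensus_prior_set"),
            inherits(cfg, "heterogeneity_config"))
  med0 <- beta_quantile(truth$placebo_prior, 0.5)
  b0 <- beta_quantile(truth$placebo_prior, cfg$bound_prob)
  w0 <- stats::qlogis(b0) - stats::qlogis(med0)
  z <- stats::qnorm(cfg$bound_prob)
  draw_one <- function(i) {
    for (attempt in 1:100) {
      central <- stats::plogis(stats::qlogis(med0) +
                                 stats::rnorm(1, 0, cfg$central_jitter_sd))
      width <- w0 * exp(stats::rnorm(1, 0, cfg$width_jitter_sd))
      bound <- stats::plogis(stats::qlogis(central) + width)
      plac <- tryCatch(placebo_answers(central, bound, cfg$bound_prob),
                       priorelicit_domain_error = function(e) NULL)
      if (is.null(plac)) next
      effects <- lapply(truth$effect_priors, function(th) {
        m <- th$mean + stats::rnorm(1, 0, cfg$central_jitter_sd)
        s <- th$sd * exp(stats::rnorm(1, 0, cfg$width_jitter_sd))
        tryCatch(effect_answers(exp(m), exp(m + z * s), cfg$bound_prob),
                 priorelicit_domain_error = function(e) NULL)
      })
      if (any(vapply(effects, is.null, logical(1)))) next
      return(questionnaire_response(sprintf("expert-%02d", i), plac, effects))
    }
    stop(errorCondition(
      sprintf("could not generate a valid response for expert %d in 100 attempts", i),
      class = c("priorelicit_generation_error", "error")))
  }
  with_seed(cfg$seed, lapply(seq_len(cfg$n_experts), draw_one))
}

# Pipeline consensus estimator used for recovery experiments: the voted
# placebo answer pair is proxied by the logit-scale average of the panel's
# answers; therapy Normals are combined as the arithmetic mean of fitted
# means and the geometric mean of fitted sds (matching the scales on which
# the heterogeneity acts).
consensus_estimate <- function(experts, responses, bound_prob) {
  central <- stats::plogis(mean(stats::qlogis(
    vapply(responses, function(r) r$placebo$central, numeric(1)))))
  bound <- stats::plogis(mean(stats::qlogis(
    vapply(responses, function(r) r$placebo$bound, numeric(1)))))
  placebo <- fit_beta_from_answers(placebo_answers(central, bound, bound_prob))
  therapies <- names(experts[[1]]$effect_priors)
  effects <- lapply(therapies, function(tid) {
    ms <- vapply(experts, function(e) e$effect_priors[[tid]]$mean, numeric(1))
    ss <- vapply(experts, function(e) e$effect_priors[[tid]]$sd, numeric(1))
    logor_prior(mean(ms), exp(mean(log(ss))))
  })
  names(effects) <- therapies
  consensus_prior_set(placebo, effects,
                      provenance = list(aggregation = "zero-noise vote proxy"))
}

#' Parameter-recovery report for the synthetic pipeline
#'
#' Runs `generate -> fit -> consensus-by-zero-noise-vote` `n_reps` times
#' and reports, for every elicited parameter (placebo alpha and beta,
#' per-therapy mean and sd), the bias and root-mean-square error of the
#' recovered consensus against the truth. Replicate seeds are derived
#' deterministically from `cfg$seed`.
#'
#' @param truth a [consensus_prior_set()].
#' @param cfg a [heterogeneity_config()].
#' @param n_reps number of replicates (>= 1).
#' @return A `data.frame` with columns `parameter`, `truth`, `bias`,
#'   `rmse`.
#' @export
recovery_report <- function(truth, cfg, n_reps) {
  stopifnot(inherits(truth, "consensus_prior_set"),
            inherits(cfg, "heterogeneity_config"))
  if (!is.numeric(n_reps) || n_reps < 1) stop_domain("n_reps must be >= 1")
  base_seed <- (cfg$seed %||% 0)
  therapies <- names(truth$effect_priors)
  truth_vec <- c(placebo_alpha = truth$placebo_prior$alpha,
                 placebo_beta = truth$placebo_prior$beta)
  for (tid in therapies) {
    truth_vec[paste0(tid, "_mean")] <- truth$effect_priors[[tid]]$mean
    truth_vec[paste0(tid, "_sd")] <- truth$effect_priors[[tid]]$sd
  }
  est <- matrix(NA_real_, nrow = n_reps, ncol = length(truth_vec),
                dimnames = list(NULL, names(truth_vec)))
  for (r in seq_len(n_reps)) {
    cfg_r <- cfg
    cfg_r$seed <- (base_seed + r) %% .Machine$integer.max
    responses <- generate_responses(truth, cfg_r)
    experts <- lapply(responses, fit_expert, therapies = therapies)
    cons <- consensus_estimate(experts, responses, cfg$bound_prob)
    row <- c(cons$placebo_prior$alpha, cons$placebo_prior$beta)
    for (tid in therapies) {
      row <- c(row, cons$effect_priors[[tid]]$mean, cons$effect_priors[[tid]]$sd)
    }
    est[r, ] <- row
  }
  err <- sweep(est, 2, truth_vec)
  data.frame(parameter = names(truth_vec),
             truth = unname(truth_vec),
             bias = colMeans(err),
             rmse = sqrt(colMeans(err^2)),
             row.names = NULL, stringsAsFactors = FALSE)
}
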