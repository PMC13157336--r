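#' Beta prior for a response probability
#'
#' Container for the two-parameter Beta prior used for the control
#' (placebo) one-year remission rate \eqn{p_0}.
#'
#' @param alpha,beta positive shape parameters.
#' @return An object of class `beta_prior`.
#' @examples
#' beta_prior(2.16, 7.57)
#' @export
beta_prior <- function(alpha, beta) {
  check_positive(alpha, "alpha")
  check_positive(beta, "beta")
  structure(list(alpha = alpha, beta = beta), class = "beta_prior")
}

#' @export
print.beta_prior <- function(x, ...) {
  cat(sprintf("Beta prior: Beta(%.4g, %.4g), mean %.3f\n",
              x$alpha, x$beta, beta_mean(x)))
  invisible(x)
}

#' Normal prior for a log-odds ratio
#'
#' Container for the Normal prior on a therapy's log-odds ratio
#' \eqn{\theta_j} of response versus control. `sd` is a standard
#' deviation, in log-odds-ratio units.
#'
#' @param mean prior mean of the log-odds ratio.
#' @param sd positive prior standard deviation.
#' @return An object of class `logor_prior`.
#' @examples
#' logor_prior(1.10, 1.70)
#' @export
logor_prior <- function(mean, sd) {
  if (!is.numeric(mean) || length(mean) != 1L || !is.finite(mean)) {
    stop_domain("mean must be a single finite number")
  }
  check_positive(sd, "sd")
  structure(list(mean = mean, sd = sd), class = "logor_prior")
}

#' @export
print.logor_prior <- function(x, ...) {
  cat(sprintf("Log-odds-ratio prior: N(%.4g, %.4g^2) [odds ratio about %.2g]\n",
              x$mean, x$sd, exp(x$mean)))
  invisible(x)
}

#' Questionnaire answers about the placebo response rate
#'
#' Captures an expert's two structured answers about the control
#' response probability: the most plausible value (interpreted as the
#' prior median) and an upper plausible bound the expert is `bound_prob`
#' sure the rate lies below. Degenerate answers of exactly 0 or 1 are
#' rejected: elicitation requires open-interval answers.
#'
#' @param central most plausible (median) response probability, in (0, 1).
#' @param bound upper plausible bound, in (`central`, 1).
#' @param bound_prob confidence attached to `bound`, in (0.5, 1);
#'   defaults to 0.95.
#' @return An object of class `placebo_answers`.
#' @export
placebo_answers <- function(central, bound, bound_prob = 0.95) {
  check_prob(central, "central")
  check_prob(bound, "bound")
  check_prob(bound_prob, "bound_prob")
  if (bound_prob <= 0.5) stop_domain("bound_prob must exceed 0.5")
  if (bound <= central) {
    stop_domain("bound (", format(bound), ") must exceed central (",
                format(central), ")")
  }
  structure(list(central = central, bound = bound, bound_prob = bound_prob),
            class = "placebo_answers")
}

#' Questionnaire answers about a therapy's effect
#'
#' Captures an expert's answers about a therapy's effect versus control,
#' elicited on the odds-ratio scale (what clinicians reason about:
#' "about 3 times more likely") and log-transformed internally: the most
#' plausible odds ratio and an upper odds ratio the expert is
#' `bound_prob` sure the effect lies below.
#'
#' @param central_or most plausible odds ratio (> 0).
#' @param upper_or upper plausible odds ratio (> `central_or`).
#' @param bound_prob confidence attached to `upper_or`, in (0.5, 1).
#' @return An object of class `effect_answers`.
#' @export
effect_answers <- function(central_or, upper_or, bound_prob = 0.95) {
  check_positive(central_or, "central_or")
  check_positive(upper_or, "upper_or")
  check_prob(bound_prob, "bound_prob")
  if (bound_prob <= 0.5) stop_domain("bound_prob must exceed 0.5")
  if (upper_or <= central_or) {
    stop_domain("upper_or (", format(upper_or),
                ") must exceed central_or (", format(central_or), ")")
  }
  structure(list(central_or = central_or, upper_or = upper_or,
                 bound_prob = bound_prob),
            class = "effect_answers")
}

#' Mean of a Beta prior
#'
#' @param prior a [beta_prior()].
#' @return `alpha / (alpha + beta)`.
#' @examples
#' beta_mean(beta_prior(2.16, 7.57)) # 0.22
#' @export
beta_mean <- function(prior) {
  stopifnot(inherits(prior, "beta_prior"))
  prior$alpha / (prior$alpha + prior$beta)
}

#' Quantiles of a Beta prior
#'
#' @param prior a [beta_prior()].
#' @param q probability level(s), strictly inside (0, 1).
#' @return The `q`-quantile(s) of the Beta distribution.
#' @examples
#' beta_quantile(beta_prior(2.16, 7.57), c(0.05, 0.95)) # 90% interval
#' @export
beta_quantile <- function(prior, q) {
  stopifnot(inherits(prior, "beta_prior"))
  if (!is.numeric(q) || any(!is.finite(q)) || any(q <= 0) || any(q >= 1)) {
    stop_domain("quantile levels must lie strictly inside (0, 1)")
  }
  stats::qbeta(q, prior$alpha, prior$beta)
}

#' Fit a Beta prior from elicited placebo answers
#'
#' Finds the Beta distribution whose median equals the expert's central
#' answer and whose `bound_prob`-quantile equals the stated upper bound
#' (two-dimensional quantile matching, the SHELF convention). The search
#' minimises the squared quantile mismatch over `(log alpha, log beta)`
#' within `[exp(-4), exp(6)]^2`, from several starting points; a fit is
#' accepted only when both residuals are below `tol` in probability
#' units.
#'
#' Note that the fitted prior's *mean* need not equal `central`: the
#' convention matches the median.
#'
#' @param ans a [placebo_answers()] object.
#' @param tol maximum absolute quantile residual accepted (probability
#'   units); default `1e-6`.
#' @return A [beta_prior()] with a `"fit"` attribute carrying the
#'   residuals and objective value.
#' @examples
#' fit_beta_from_answers(placebo_answers(0.209, 0.461, 0.95))
#' @export
fit_beta_from_answers <- function(ans, tol = 1e-6) {
  stopifnot(inherits(ans, "placebo_answers"))
  target <- c(ans$central, ans$bound)
  levels <- c(0.5, ans$bound_prob)
  obj <- function(par) {
    a <- exp(par[1]); b <- exp(par[2])
    # qbeta can warn about reduced accuracy at the extreme shapes optim
    # explores; the residual check below enforces the accuracy that counts
    sum((suppressWarnings(stats::qbeta(levels, a, b)) - target)^2)
  }
  # heuristic start: normal-ish moment match on (central, bound)
  m <- ans$central
  s <- max((ans$bound - ans$central) / stats::qnorm(ans$bound_prob), 1e-3)
  kappa <- max(m * (1 - m) / s^2 - 1, 0.05)
  starts <- rbind(
    log(pmin(pmax(c(m * kappa, (1 - m) * kappa), exp(-4)), exp(6))),
    c(log(2), log(2)),
    c(0, 0),
    c(log(1), log(4)),
    c(log(10), log(10))
  )
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      stats::optim(starts[i, ], obj, method = "L-BFGS-B",
                   lower = c(-4, -4), upper = c(6, 6),
                   control = list(factr = 1e2, maxit = 500)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
    if (best$value < tol^2 * 1e-4) break
  }
  if (is.null(best)) stop_fit_failure(ans, NA_real_, c(NA_real_, NA_real_))
  # derivative-free polish of the best candidate
  polish <- stats::optim(best$par, obj, method = "Nelder-Mead",
                         control = list(reltol = 1e-15, maxit = 2000))
  if (polish$value < best$value &&
      all(abs(polish$par) <= c(6, 6) + 1e-9) && all(polish$par >= -4 - 1e-9)) {
    best <- polish
  }
  a <- exp(best$par[1]); b <- exp(best$par[2])
  resid <- stats::qbeta(levels, a, b) - target
  if (any(abs(resid) >= tol)) stop_fit_failure(ans, best$value, resid)
  out <- beta_prior(a, b)
  attr(out, "fit") <- list(objective = best$value, residuals = resid,
                           levels = levels, convention = "median+quantile")
  out
}

stop_fit_failure <- function(ans, objective, resid) {
  stop(errorCondition(
    sprintf(paste0("no Beta distribution matches median %.4g and %.4g-quantile ",
                   "%.4g within tolerance (objective %.3g, residuals %s); ",
                   "the answers may imply a concentration outside the ",
                   "supported shape range [exp(-4), exp(6)]"),
            ans$central, ans$bound_prob, ans$bound, objective,
            paste(format(resid, digits = 3), collapse = ", ")),
    class = c("priorelicit_fit_error", "error"),
    answers = ans, objective = objective, residuals = resid))
}

#' Fit a Normal log-odds-ratio prior from elicited effect answers
#'
#' Closed form: the prior mean is `log(central_or)` (the stated odds
#' ratio is the prior median) and the standard deviation is
#' `(log(upper_or) - log(central_or)) / z(bound_prob)` with `z` the
#' standard-normal quantile.
#'
#' @param ans an [effect_answers()] object.
#' @return A [logor_prior()].
#' @examples
#' fit_logor_from_answers(effect_answers(3, 30, 0.95))
#' @export
fit_logor_from_answers <- function(ans) {
  stopifnot(inherits(ans, "effect_answers"))
  m <- log(ans$central_or)
  s <- (log(ans$upper_or) - m) / stats::qnorm(ans$bound_prob)
  logor_prior(m, s)
}

#' Mean +/- k standard deviation interval of a log-odds-ratio prior
#'
#' @param prior a [logor_prior()].
#' @param k nonnegative multiplier; `k = 1.645` gives the equal-tailed
#'   90\% interval of the Normal.
#' @return Numeric vector `c(lower, upper)`.
#' @examples
#' logor_sd_interval(logor_prior(1.10, 1.70), 1) # (-0.6, 2.8)
#' @export
logor_sd_interval <- function(prior, k = 1) {
  stopifnot(inherits(prior, "logor_prior"))
  if (!is.numeric(k) || length(k) != 1L || !is.finite(k) || k < 0) {
    stop_domain("k must be a single nonnegative number")
  }
  c(prior$mean - k * prior$sd, prior$mean + k * prior$sd)
}

#' Point odds ratio implied by a log-odds-ratio prior
#'
#' @param prior a [logor_prior()].
#' @return `exp(mean)`, the prior-median odds ratio.
#' @export
odds_ratio_point <- function(prior) {
  stopifnot(inherits(prior, "logor_prior"))
  exp(prior$mean)
}

#' Prior probability that a therapy is superior to control
#'
#' @param prior a [logor_prior()].
#' @return `P(theta > 0) = pnorm(mean / sd)`.
#' @export
prior_prob_superiority <- function(prior) {
  stopifnot(inherits(prior, "logor_prior"))
  stats::pnorm(prior$mean / prior$sd)
}
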