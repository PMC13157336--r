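#' Two-arm trial design specification
#'
#' Arm sizes and the known per-observation standard deviation `sigma` of
#' the approximately Normal log-odds-ratio response model used for
#' conjugate updating. `sigma` is user-supplied and treated as known; no
#' estimation from binary outcomes is attempted.
#'
#' @param n_treatment,n_control patients per arm (>= 1).
#' @param sigma known standard deviation (> 0), log-odds-ratio units.
#' @return An object of class `trial_design`.
#' @export
trial_design <- function(n_treatment, n_control, sigma) {
  if (!is.numeric(n_treatment) || n_treatment < 1 ||
      !is.numeric(n_control) || n_control < 1) {
    stop_domain("arm sizes must be >= 1")
  }
  check_positive(sigma, "sigma")
  structure(list(n_treatment = as.integer(n_treatment),
                 n_control = as.integer(n_control), sigma = sigma),
            class = "trial_design")
}

#' Prior effective sample size
#'
#' The number of trial patients whose data would carry the same
#' information as the prior under the Normal model with known `sigma`:
#' `(sigma / sd)^2`. For the upadacitinib-style prior with sd 1.70 and
#' `sigma = 8` this is 22.1, i.e. about 22 patients.
#'
#' @param prior a [logor_prior()].
#' @param sigma known standard deviation(s) (> 0); vectorised.
#' @return Nonnegative real(s); round to the nearest integer for a
#'   patient-count reading.
#' @export
prior_ess <- function(prior, sigma) {
  stopifnot(inherits(prior, "logor_prior"))
  if (!is.numeric(sigma) || length(sigma) < 1L || any(!is.finite(sigma)) ||
      any(sigma <= 0)) {
    stop_domain("sigma must be positive")
  }
  (sigma / prior$sd)^2
}

#' Data precision of a two-arm design
#'
#' Precision of the sample log-odds ratio under the known-`sigma` Normal
#' model: `1 / (sigma^2 * (1/n_treatment + 1/n_control))`. For 80
#' patients 1:1 this is the familiar `20 / sigma^2`.
#'
#' @param design a [trial_design()].
#' @return Positive real.
#' @export
data_precision <- function(design) {
  stopifnot(inherits(design, "trial_design"))
  1 / (design$sigma^2 * (1 / design$n_treatment + 1 / design$n_control))
}

#' Conjugate Normal posterior for the log-odds ratio
#'
#' Precision-weighted Normal-Normal update: the posterior precision is
#' the prior precision plus the data precision, and the posterior mean
#' is the precision-weighted average of the prior mean and the observed
#' sample log-odds ratio `xbar`.
#'
#' @param prior a [logor_prior()].
#' @param xbar observed sample mean log-odds ratio.
#' @param design a [trial_design()].
#' @return An object of class `normal_posterior` with elements `mean`
#'   and `variance`.
#' @examples
#' posterior_update(logor_prior(1.10, 1.70), xbar = 0.8,
#'                  trial_design(40, 40, sigma = 8))
#' @export
posterior_update <- function(prior, xbar, design) {
  stopifnot(inherits(prior, "logor_prior"), inherits(design, "trial_design"))
  if (!is.numeric(xbar) || length(xbar) != 1L || !is.finite(xbar)) {
    stop_domain("xbar must be a single finite number")
  }
  prior_prec <- 1 / prior$sd^2
  dat_prec <- data_precision(design)
  post_prec <- prior_prec + dat_prec
  structure(list(mean = (prior_prec * prior$mean + dat_prec * xbar) / post_prec,
                 variance = 1 / post_prec),
            class = "normal_posterior")
}

#' @export
print.normal_posterior <- function(x, ...) {
  cat(sprintf("Posterior log-odds ratio: N(%.4g, %.4g^2)\n",
              x$mean, sqrt(x$variance)))
  invisible(x)
}

#' Design-prior export table
#'
#' Tabulates, for every therapy in a consensus set and every `sigma` in
#' a grid, the prior effective sample size (raw and nearest-integer)
#' alongside the prior probability of superiority. Deterministic.
#'
#' @param consensus a [consensus_prior_set()].
#' @param sigma_grid nonempty vector of positive `sigma` values.
#' @return A long-format `data.frame` with one row per therapy x sigma.
#' @export
export_design_priors <- function(consensus, sigma_grid) {
  stopifnot(inherits(consensus, "consensus_prior_set"))
  if (length(sigma_grid) == 0L) stop_domain("sigma_grid must be nonempty")
  if (any(!is.finite(sigma_grid)) || any(sigma_grid <= 0)) {
    stop_domain("sigma_grid values must be positive")
  }
  rows <- lapply(names(consensus$effect_priors), function(tid) {
    th <- consensus$effect_priors[[tid]]
    data.frame(therapy = tid,
               log_or_mean = th$mean,
               log_or_sd = th$sd,
               prob_superiority = prior_prob_superiority(th),
               sigma = sigma_grid,
               ess = (sigma_grid / th$sd)^2,
               ess_patients = round((sigma_grid / th$sd)^2),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
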