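# Published consensus quantities used as expected values across the suite.
# Effect-prior scale numbers are the quoted dispersion figures; under the
# package's default (variance) reading the prior sd is sqrt(scale).
published_arms <- function() {
  data.frame(
    id = c("iv-infliximab", "adalimumab", "sc-infliximab", "iv-vedolizumab",
           "upadacitinib", "ustekinumab", "anti-il23"),
    label = c("IV infliximab", "Adalimumab", "SC infliximab", "IV vedolizumab",
              "Upadacitinib", "Ustekinumab", "Anti-IL-23"),
    log_or_mean = c(1.90, 0.83, 1.60, 0.00, 1.10, 0.53, 0.62),
    scale = c(2.20, 0.97, 1.55, 0.64, 1.70, 1.04, 1.41),
    pj_mean = c(0.58, 0.39, 0.53, 0.24, 0.44, 0.34, 0.36),
    cri_low = c(0.09, 0.06, 0.09, 0.03, 0.05, 0.04, 0.04),
    cri_high = c(0.96, 0.82, 0.93, 0.60, 0.90, 0.77, 0.82),
    stringsAsFactors = FALSE)
}

placebo_fixture <- function() beta_prior(2.16, 7.57)

# Invert a consensus prior set into the questionnaire answers that
# reproduce it exactly under the median+quantile fitting convention.
truth_to_response <- function(truth, expert_id = "expert-01", bound_prob = 0.95) {
  z <- qnorm(bound_prob)
  effects <- lapply(truth$effect_priors, function(th) {
    effect_answers(exp(th$mean), exp(th$mean + z * th$sd), bound_prob)
  })
  questionnaire_response(
    expert_id,
    placebo_answers(beta_quantile(truth$placebo_prior, 0.5),
                    beta_quantile(truth$placebo_prior, bound_prob),
                    bound_prob),
    effects)
}
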