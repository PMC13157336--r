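Package: priorelicit
Title: Expert Prior Elicitation and Induced Treatment-Arm Priors for
    Bayesian Clinical Trial Design
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for structured expert prior elicitation for binary
    clinical-trial endpoints, following the Sheffield Elicitation
    Framework (SHELF) style of workshop: per-expert questionnaires are
    converted into a Beta prior for the control (placebo) response rate
    and Normal priors for each therapy's log-odds ratio against control;
    the marginal ("induced") prior of each treatment arm's response rate
    is computed by Monte Carlo or deterministic quadrature; equal-weight
    linear opinion pools support group discussion; and consensus priors
    are translated into trial-design quantities (prior effective sample
    size, conjugate Normal posterior updates). Ships the consensus prior
    set for one-year fistula remission under placebo and seven medical
    therapies in perianal fistulizing Crohn's disease, elicited at a
    2024 expert workshop, together with a synthetic-expert generator so
    the full pipeline can be exercised end-to-end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    pracma,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
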