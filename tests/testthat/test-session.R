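therapy7 <- function() published_arms()$id

test_that("elicitation orders anchor first and permute the rest uniformly", {
  ths <- therapy7()
  ord <- make_elicitation_order(ths, anchor = "iv-infliximab", seed = 5)
  expect_length(ord, 7)
  expect_identical(ord[1], "iv-infliximab")
  expect_setequal(ord[-1], setdiff(ths, "iv-infliximab"))
  expect_identical(make_elicitation_order(ths, "iv-infliximab", 5), ord)
  expect_identical(make_elicitation_order("only-one"), "only-one")
  expect_error(make_elicitation_order(ths, anchor = "nope"),
               class = "priorelicit_domain_error")

  # 3 therapies: the two possible tail orders are equally likely
  tails <- vapply(1:10000, function(s) {
    paste(make_elicitation_order(c("a", "b", "c"), "a", seed = s)[-1],
          collapse = "")
  }, character(1))
  expect_equal(mean(tails == "bc"), 0.5, tolerance = 0.02)

  # 4 therapies: each non-anchor appears in each tail slot with freq 1/3
  pos <- t(vapply(1:2000, function(s) {
    make_elicitation_order(c("a", "b", "c", "d"), "a", seed = 20000 + s)[-1]
  }, character(3)))
  se3 <- sqrt((1 / 3) * (2 / 3) / 2000)
  for (slot in 1:3) for (th in c("b", "c", "d")) {
    expect_equal(mean(pos[, slot] == th), 1 / 3, tolerance = 3 * se3)
  }
})

test_that("fit_expert recovers an inverted consensus and validates completeness", {
  truth <- pfcd_consensus()
  resp <- truth_to_response(truth)
  ex <- fit_expert(resp, therapy7(), anchor = "iv-infliximab", seed = 1)
  expect_equal(ex$placebo_prior$alpha, 2.16, tolerance = 2e-3)
  expect_equal(ex$placebo_prior$beta, 7.57, tolerance = 5e-3)
  for (tid in therapy7()) {
    expect_equal(ex$effect_priors[[tid]]$mean,
                 truth$effect_priors[[tid]]$mean, tolerance = 1e-10)
    expect_equal(ex$effect_priors[[tid]]$sd,
                 truth$effect_priors[[tid]]$sd, tolerance = 1e-10)
  }
  expect_false(is_locked(ex))

  # a panel of 11 gets distinct orders from distinct seeds
  panel <- lapply(1:11, function(i) {
    e <- fit_expert(truth_to_response(truth, sprintf("expert-%02d", i)),
                    therapy7(), "iv-infliximab", seed = i)
    paste(e$elicitation_order, collapse = "|")
  })
  expect_gt(length(unique(unlist(panel))), 8)

  # a missing therapy is reported by name, and no partial set is emitted
  short <- resp
  short$effects[["upadacitinib"]] <- NULL
  short <- questionnaire_response("expert-x", resp$placebo, short$effects)
  expect_error(fit_expert(short, therapy7()), "upadacitinib")
})

test_that("locking freezes an expert prior set", {
  truth <- pfcd_consensus()
  ex <- fit_expert(truth_to_response(truth), therapy7(), seed = 2)
  ex$expert_id <- "renamed-while-unlocked"
  expect_identical(ex$expert_id, "renamed-while-unlocked")
  lk <- lock_expert(ex)
  expect_true(is_locked(lk))
  expect_error(lk$expert_id <- "no", class = "priorelicit_state_error")
  expect_error(lk[["placebo_prior"]] <- beta_prior(1, 1),
               class = "priorelicit_state_error")
})

test_that("equal-weight pooling averages member densities", {
  truth <- pfcd_consensus()
  grid <- seq(0.01, 0.99, length.out = 99)
  e1 <- fit_expert(truth_to_response(truth, "e1"), therapy7(), seed = 1)

  # identical experts: the pool equals the common density pointwise
  pool_same <- pool_densities(list(e1, e1, e1), "placebo", grid)
  expect_equal(pool_same$values,
               dbeta(grid, e1$placebo_prior$alpha, e1$placebo_prior$beta),
               tolerance = 1e-12)

  # two distinct experts: the pool is the midpoint curve
  cfg <- heterogeneity_config(n_experts = 2, central_jitter_sd = 0.4,
                              width_jitter_sd = 0.2, seed = 99)
  two <- lapply(generate_responses(truth, cfg), fit_expert,
                therapies = therapy7())
  pool2 <- pool_densities(two, "placebo", grid)
  d1 <- dbeta(grid, two[[1]]$placebo_prior$alpha, two[[1]]$placebo_prior$beta)
  d2 <- dbeta(grid, two[[2]]$placebo_prior$alpha, two[[2]]$placebo_prior$beta)
  expect_equal(pool2$values, (d1 + d2) / 2, tolerance = 1e-12)

  # duplication leaves the (equal-weight) pool unchanged
  pool_dup <- pool_densities(c(two, two), "placebo", grid)
  expect_equal(pool_dup$values, pool2$values, tolerance = 1e-12)

  # pooled mean is the average of member means (linearity of expectation)
  wide <- seq(0.001, 0.999, length.out = 400)
  pool_t <- pool_densities(two, "upadacitinib", wide)
  member_means <- vapply(two, function(e) {
    grid_mean(induced_density(e$placebo_prior, e$effect_priors[["upadacitinib"]],
                              wide))
  }, numeric(1))
  expect_equal(grid_mean(pool_t), mean(member_means), tolerance = 1e-4)
  expect_equal(grid_integral(pool_t), 1, tolerance = 0.005)

  expect_error(pool_densities(list(), "placebo"),
               class = "priorelicit_domain_error")
})

test_that("consensus recording requires locked experts and honours the vote", {
  truth <- pfcd_consensus()
  session <- elicitation_session(therapy7(), anchor = "iv-infliximab")
  for (i in 1:3) {
    session <- add_expert(session, fit_expert(
      truth_to_response(truth, sprintf("e%d", i)), therapy7(),
      "iv-infliximab", seed = i))
  }
  vote <- placebo_answers(beta_quantile(truth$placebo_prior, 0.5),
                          beta_quantile(truth$placebo_prior, 0.95), 0.95)
  decisions <- truth$effect_priors
  expect_error(record_consensus(session, vote, decisions),
               class = "priorelicit_state_error")

  session$experts <- lapply(session$experts, lock_expert)
  cons <- record_consensus(session, vote, decisions,
                           notes = list(vote_tally = "unanimous"))
  expect_equal(round(beta_mean(cons$placebo_prior), 2), 0.22)
  expect_equal(cons$effect_priors[["upadacitinib"]]$mean, 1.10)
  expect_identical(cons$provenance$vote_tally, "unanimous")
  expect_error(record_consensus(session, vote, decisions[-1]),
               class = "priorelicit_domain_error")

  # single-expert session: consensus may equal that expert's priors exactly
  solo <- elicitation_session(therapy7())
  solo <- add_expert(solo, lock_expert(fit_expert(
    truth_to_response(truth, "only"), therapy7(), seed = 9)))
  cons1 <- record_consensus(solo, vote, solo$experts[[1]]$effect_priors)
  expect_equal(cons1$effect_priors[["ustekinumab"]]$mean,
               solo$experts[[1]]$effect_priors[["ustekinumab"]]$mean)
})

test_that("sessions round-trip losslessly through JSON", {
  truth <- pfcd_consensus()
  session <- elicitation_session(therapy7(), "iv-infliximab")
  for (i in 1:2) {
    session <- add_expert(session, lock_expert(fit_expert(
      truth_to_response(truth, sprintf("e%d", i)), therapy7(),
      "iv-infliximab", seed = i)))
  }
  vote <- placebo_answers(beta_quantile(truth$placebo_prior, 0.5),
                          beta_quantile(truth$placebo_prior, 0.95))
  session$consensus <- record_consensus(session, vote, truth$effect_priors)

  path <- withr::local_tempfile(fileext = ".json")
  write_session(session, path)
  back <- read_session(path)
  expect_identical(back$therapies, session$therapies)
  expect_identical(back$anchor, session$anchor)
  expect_equal(length(back$experts), 2)
  for (i in 1:2) {
    expect_identical(back$experts[[i]]$elicitation_order,
                     session$experts[[i]]$elicitation_order)
    expect_equal(back$experts[[i]]$placebo_prior$alpha,
                 session$experts[[i]]$placebo_prior$alpha)
    expect_true(is_locked(back$experts[[i]]))
  }
  expect_equal(back$consensus$placebo_prior$beta,
               session$consensus$placebo_prior$beta)
})
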