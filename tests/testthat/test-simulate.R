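test_that("simulated responses follow the generating branch probabilities", {
  spec <- design_spec("exp1", seed = 4)
  d <- build_design(spec)
  # perfect identification: every probe response is correct
  pars1 <- sim_params(spec, ci = 1, psc = 0.5, prr_c = 0.5, effect = 0)
  r1 <- simulate_experiment(d, pars1, n_participants = 2, seed = 8)
  expect_true(all(r1$category[r1$analyzed] == "correct"))
  expect_true(all(r1$response[r1$analyzed] ==
                    d$probe_target[match(r1$trial[r1$analyzed], d$trial)]))

  # (.5, .5, .5) in every cell: pooled category frequencies within 3 SE of
  # (.5, .25, .125, .125) over 100 participants x 288 analyzed trials
  pars2 <- sim_params(spec, ci = 0.5, psc = 0.5, prr_c = 0.5, effect = 0)
  r2 <- simulate_experiment(d, pars2, n_participants = 100, seed = 8)
  obs <- table(factor(r2$category[r2$analyzed],
                      levels = c("correct", "distractor_error",
                                 "prime_response_error", "other_error")))
  N <- sum(obs)
  expected <- c(0.5, 0.25, 0.125, 0.125)
  se <- sqrt(expected * (1 - expected) * N)
  expect_true(all(abs(obs - N * expected) <= 3 * se))
})

test_that("simulation is seeded and leaves the caller's RNG alone", {
  spec <- design_spec("exp2", seed = 1)
  d <- build_design(spec)
  pars <- sim_params(spec, pattern = "configural")
  r1 <- simulate_experiment(d, pars, n_participants = 5, seed = 42)
  r2 <- simulate_experiment(d, pars, n_participants = 5, seed = 42)
  expect_identical(r1, r2)
  r3 <- simulate_experiment(d, pars, n_participants = 5, seed = 43)
  expect_false(identical(r1$response, r3$response))
  set.seed(7); before <- runif(1)
  set.seed(7)
  invisible(simulate_experiment(d, pars, n_participants = 2, seed = 42))
  expect_identical(runif(1), before)
  # per-participant accuracy jitter stays reproducible
  j1 <- simulate_experiment(d, pars, 5, seed = 9, ci_jitter_sd = 0.4)
  j2 <- simulate_experiment(d, pars, 5, seed = 9, ci_jitter_sd = 0.4)
  expect_identical(j1, j2)
  expect_error(simulate_experiment(d, pars[-1, ], 2, seed = 1),
               "no generating parameters")
})

test_that("sim_params builds the prototypical patterns within bounds", {
  spec <- design_spec("exp1", seed = 1)
  p0 <- sim_params(spec, pattern = "none")
  expect_identical(nrow(p0), 12L)   # 2 types x 2 relations x 3 levels
  expect_true(all(p0$prr[p0$trial_type == "ignored_repetition"] -
                    p0$prr[p0$trial_type == "control"] == 0.06))
  pc <- sim_params(spec, pattern = "configural",
                   saliency_levels = "moderate")
  eff <- function(p, cr, sal) {
    p$prr[p$trial_type == "ignored_repetition" & p$context_relation == cr &
            p$saliency == sal] -
      p$prr[p$trial_type == "control" & p$context_relation == cr &
              p$saliency == sal]
  }
  expect_equal(eff(pc, "repeated", "moderate"), 0.10)
  expect_equal(eff(pc, "changed", "moderate"), 0.02)
  expect_equal(eff(pc, "repeated", "low"), 0.06)   # untouched level
  pb <- sim_params(spec, pattern = "binary")
  expect_equal(unique(pb$prr[pb$trial_type == "control" &
                               pb$context_relation == "repeated"]), 0.20)
  expect_error(sim_params(spec, ci = 1.4), "\\[0, 1\\]")
})

test_that("aggregation applies the error-rate exclusion rule", {
  mk <- function(participant, n_correct, n_other) {
    data.frame(
      participant = participant,
      trial_type = "ignored_repetition", context_relation = "repeated",
      saliency = "moderate",
      category = rep(c("correct", "other_error"), c(n_correct, n_other)),
      analyzed = TRUE, stringsAsFactors = FALSE
    )
  }
  resp <- rbind(mk(1, 40, 60),   # error rate .60 -> excluded
                mk(2, 100, 0),   # all correct -> retained
                mk(3, 50, 50))   # error rate .50, not above threshold
  agg <- aggregate_and_filter(resp)
  expect_identical(agg$exclusions$excluded, c(TRUE, FALSE, FALSE))
  expect_identical(sum(agg$table[, grep("^n_", names(agg$table))]), 200L)
  expect_identical(agg$table$n_correct, 150L)
  # threshold is strict: .50 stays in at the default cut
  expect_error(aggregate_and_filter(rbind(mk(1, 10, 90))),
               "all participants excluded")
})

test_that("battery rejection rates are calibrated under a null generator", {
  # identical prr everywhere; parameters chosen so every category has
  # comfortable expected counts and the chi-square asymptotics apply
  spec <- design_spec("exp1", seed = 300)
  design <- build_design(spec)
  pars <- sim_params(spec, pattern = "none", ci = 0.6, psc = 0.5,
                     prr_c = 0.3, effect = 0)
  rej <- vapply(seq_len(400), function(r) {
    resp <- simulate_experiment(design, pars, n_participants = 30,
                                seed = 300000 + r)
    b <- run_binding_battery(aggregate_and_filter(resp)$table,
                             n_restarts = 2)
    b$tests$significant
  }, logical(12))
  rates <- rowMeans(rej)           # one rate per battery test and level
  expect_true(all(abs(rates - 0.05) < 0.035))
  expect_lt(abs(mean(rates) - 0.05), 0.015)
})

test_that("the simulated pipeline feeds the battery end to end", {
  spec <- design_spec("exp1", seed = 21)
  d <- build_design(spec)
  pars <- sim_params(spec, pattern = "configural")
  resp <- simulate_experiment(d, pars, n_participants = 30, seed = 22)
  agg <- aggregate_and_filter(resp)
  expect_s3_class(agg$table, "mpt_freq_table")
  expect_identical(nrow(agg$table), 12L)
  # conservation: every retained analyzed trial lands in exactly one cell
  retained <- agg$exclusions$participant[!agg$exclusions$excluded]
  expect_identical(sum(agg$table[, grep("^n_", names(agg$table))]),
                   sum(resp$analyzed & resp$participant %in% retained))
  b <- run_binding_battery(agg$table, n_restarts = 2)
  expect_identical(nrow(b$tests), 12L)
  expect_setequal(names(b$verdicts), c("low", "moderate", "high"))
})
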