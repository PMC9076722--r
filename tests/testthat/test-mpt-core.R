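test_that("category probabilities follow the branch products and normalize", {
  tr <- baseline_tree()
  expect_equal(unname(category_probs(tr, c(ci = 1, psc = 0.3, prr = 0.9))),
               c(1, 0, 0, 0))
  expect_equal(unname(category_probs(tr, c(ci = 0.5, psc = 0.5, prr = 0.5))),
               c(0.5, 0.25, 0.125, 0.125))
  set.seed(101)
  for (i in 1:200) {
    p <- category_probs(tr, c(ci = runif(1), psc = runif(1), prr = runif(1)))
    expect_true(all(p >= 0 & p <= 1))
    expect_lt(abs(sum(p) - 1), 1e-12)
  }
  expect_error(category_probs(tr, c(ci = 0.5, psc = 0.5)), "missing parameter")
  expect_error(category_probs(tr, c(ci = 1.2, psc = 0.5, prr = 0.5)),
               "\\[0, 1\\]")
  expect_error(mpt_tree(list(a = "t", b = "t")), "not a distribution|distribution")
})

test_that("log-likelihood kernel matches the brute-force formula", {
  tr <- baseline_tree()
  n <- c(70, 15, 10, 5)
  pars <- c(ci = 0.7, psc = 0.5, prr = 2 / 3)
  p <- c(0.7, 0.3 * 0.5, 0.3 * 0.5 * 2 / 3, 0.3 * 0.5 * 1 / 3)
  expect_equal(loglik_mpt(tr, pars, n), sum(n * log(p)))
  # perfect prediction: 100 * ln 1 = 0
  expect_equal(loglik_mpt(tr, c(ci = 1, psc = 0.3, prr = 0.9),
                          c(100, 0, 0, 0)), 0)
  # zero predicted probability with positive count flags -Inf, no error
  expect_identical(loglik_mpt(tr, c(ci = 1, psc = 0.3, prr = 0.9),
                              c(99, 1, 0, 0)), -Inf)
  # uniform cell probabilities: N * ln(1/4)
  expect_equal(loglik_mpt(tr, c(ci = 0.25, psc = 1 / 3, prr = 0.5),
                          c(13, 21, 8, 44)), 86 * log(0.25))
})

test_that("saturated baseline fit equals the closed-form MLE", {
  f <- fit_mpt(baseline_tree(), c(70, 15, 10, 5))
  expect_equal(unname(f$estimates), c(0.70, 0.50, 2 / 3), tolerance = 1e-12)
  expect_equal(f$g_squared, 0, tolerance = 1e-10)
  expect_identical(f$df, 0L)
  expect_true(f$converged)
  # non-identifiable denominators are flagged, not fatal
  f0 <- fit_mpt(baseline_tree(), c(100, 0, 0, 0))
  expect_identical(unname(f0$estimates["ci"]), 1)
  expect_true(all(c("psc", "prr") %in% f0$undefined))
  expect_true(all(is.na(f0$estimates[c("psc", "prr")])))
  expect_error(fit_mpt(baseline_tree(), c(0, 0, 0, 0)), "positive total")
  expect_error(fit_mpt(baseline_tree(), c(-1, 5, 3, 2)), "nonnegative")
})

test_that("equality-restricted joint fits pool the closed form", {
  m <- joint_model(list(IR = baseline_tree("IR"), C = baseline_tree("C")),
                   restrict_equal("prr@IR", "prr@C"))
  # restriction already satisfied by identical data: common prr equals the
  # single-tree closed form and G^2 = 0
  f <- fit_mpt(m, rbind(IR = c(70, 15, 10, 5), C = c(70, 15, 10, 5)))
  expect_equal(unname(f$estimates["prr@IR"]), 2 / 3, tolerance = 1e-12)
  expect_equal(unname(f$estimates["prr@C"]), 2 / 3, tolerance = 1e-12)
  expect_equal(f$g_squared, 0, tolerance = 1e-10)
  expect_identical(f$df, 1L)
  # unequal data: pooled binomial MLE (n3_IR + n3_C) / (n34_IR + n34_C)
  cts <- rbind(IR = c(60, 20, 15, 5), C = c(70, 10, 6, 14))
  f2 <- fit_mpt(m, cts)
  expect_equal(unname(f2$estimates["prr@IR"]), (15 + 6) / (20 + 20),
               tolerance = 1e-12)
  # numeric optimizer agrees with the closed form on the same model
  f3 <- fit_mpt(m, cts, method = "optim", n_restarts = 3)
  expect_equal(f3$estimates, f2$estimates, tolerance = 1e-7)
  expect_equal(f3$g_squared, f2$g_squared, tolerance = 1e-7)
})

test_that("difference-restricted fits honor the shared retrieval effect", {
  md <- joint4(restrict_difference(c("prr@IR:repeated", "prr@C:repeated"),
                                   c("prr@IR:changed", "prr@C:changed")))
  expect_identical(.subset2(fit_mpt(md, rbind(
    "IR:repeated" = c(50, 20, 20, 10), "C:repeated" = c(50, 20, 12, 18),
    "IR:changed" = c(50, 20, 20, 10), "C:changed" = c(50, 20, 12, 18)
  )), "df"), 1L)
  # data whose unrestricted prr differences are already equal fit perfectly:
  # prr-hat = n3/(n3+n4) gives .6 - .4 in both context conditions
  cts_eq <- rbind(
    "IR:repeated" = c(40, 20, 24, 16), "C:repeated" = c(40, 20, 16, 24),
    "IR:changed" = c(50, 10, 30, 20), "C:changed" = c(50, 10, 20, 30)
  )
  f_eq <- fit_mpt(md, cts_eq)
  expect_equal(f_eq$g_squared, 0, tolerance = 1e-8)
  est <- f_eq$estimates
  expect_equal(unname(est["prr@IR:repeated"] - est["prr@C:repeated"]),
               unname(est["prr@IR:changed"] - est["prr@C:changed"]),
               tolerance = 1e-8)
  expect_true(f_eq$converged)
})

test_that("restriction nesting is respected by G-squared", {
  set.seed(77)
  md <- joint4(restrict_difference(c("prr@IR:repeated", "prr@C:repeated"),
                                   c("prr@IR:changed", "prr@C:changed")))
  me <- joint4(restrict_equal("prr@IR:repeated", "prr@C:repeated",
                              "prr@IR:changed", "prr@C:changed"))
  m0 <- joint4()
  for (i in 1:25) {
    cts <- do.call(rbind, lapply(1:4, function(j) random_count_table()))
    rownames(cts) <- c("IR:repeated", "C:repeated", "IR:changed", "C:changed")
    g_sat <- fit_mpt(m0, cts)$g_squared
    g_diff <- fit_mpt(md, cts, n_restarts = 3)$g_squared
    g_all <- fit_mpt(me, cts)$g_squared
    expect_lt(abs(g_sat), 1e-8)
    # equality of all four prr implies equality of the two differences
    expect_gte(g_all + 1e-7, g_diff)
    expect_gte(g_diff + 1e-9, 0)
  }
})

test_that("estimates recover generating parameters as N grows", {
  truth <- c(ci = 0.8, psc = 0.4, prr = 0.2)
  p <- baseline_probs(0.8, 0.4, 0.2)
  mae <- vapply(c(1e3, 1e5), function(N) {
    set.seed(2024 + N)
    n <- stats::rmultinom(1, N, p)[, 1]
    mean(abs(fit_mpt(baseline_tree(), n)$estimates - truth))
  }, numeric(1))
  expect_lt(mae[2], mae[1])
  expect_lt(mae[2], 0.01)
})

test_that("restriction objects validate their targets", {
  expect_error(restrict_equal("prr@IR"), "at least two")
  expect_error(restrict_difference(c("a", "b"), c("a", "c")), "distinct")
  expect_error(joint_model(list(IR = baseline_tree("IR")),
                           restrict_equal("prr@IR", "prr@C")),
               "unknown parameter")
  # same unqualified names in two trees must be rejected
  expect_error(joint_model(list(a = baseline_tree(), b = baseline_tree())),
               "unique across")
})
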