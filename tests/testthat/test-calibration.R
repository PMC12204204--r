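test_that("the efficacy decision thresholds posterior probabilities", {
  s <- data.frame(basket = c("a", "b"), prob_effective = c(0.99, 0.50))
  expect_equal(unname(decide(s, decision_rule(0.1, 0.9))), c(TRUE, FALSE))
  expect_equal(unname(decide(s, decision_rule(0.1, 0))), c(TRUE, TRUE))
  # Delta = 1 rejects only P = 1 exactly; Delta > 1 violates the invariant
  s1 <- data.frame(basket = c("a", "b"), prob_effective = c(1, 0.999999))
  expect_equal(unname(decide(s1, decision_rule(0.1, 1))), c(TRUE, FALSE))
  expect_error(decision_rule(0.1, 1.000001), "\\[0, 1\\]")
  expect_error(decide(s[0, ], decision_rule(0.1, c(0.9, 0.9))), "baskets")
})

test_that("the empirical cutoff converges to the quantile of a uniform", {
  set.seed(2024)
  pool <- runif(40000)
  cut <- basketbh:::calibrate_cutoff(pool, rep(1 / 40000, 40000), 0.10)
  expect_equal(cut$delta, 0.90, tolerance = 0.01)
  expect_equal(cut$achieved, 0.10, tolerance = 1e-3)
  # monotone: a laxer target never raises the cutoff
  c05 <- basketbh:::calibrate_cutoff(pool, rep(1 / 40000, 40000), 0.05)
  c20 <- basketbh:::calibrate_cutoff(pool, rep(1 / 40000, 40000), 0.20)
  expect_lte(c20$delta, cut$delta)
  expect_lte(cut$delta, c05$delta)
  expect_error(basketbh:::calibrate_cutoff(rep(0.5, 100), rep(0.01, 100), 0.1),
               "unattainable")
})

test_that("calibration controls the weighted average null rejection", {
  scen <- trial_scenarios("none", n_k = 20)
  sp <- model_spec("Ind")
  rule <- calibrate(sp, calibration_spec(scen, target = 0.1, n_sims = 150),
                    quick_mcmc(), seed = 30)
  expect_equal(attr(rule, "achieved"), 0.1, tolerance = 0.02)
  # closure: independent re-simulation at the calibrated cutoff recovers the
  # target within binomial Monte Carlo error (scenario-weighted average)
  errs <- c()
  for (s in seq_along(scen)) {
    nullk <- scen[[s]]$p_true <= 0.1
    if (!any(nullk)) next
    oc <- operating_characteristics(sp, scen[[s]], rule, n_sims = 150,
                                    mcmc = quick_mcmc(), seed = 777)
    errs <- c(errs, mean(oc$reject_rate[nullk]))
  }
  se <- sqrt(0.1 * 0.9 / (150 * length(errs)))
  expect_lt(abs(mean(errs) - 0.1), 4 * se)
})

test_that("calibration is invariant to scenario order", {
  scen <- trial_scenarios("none", n_k = 15)[c(1, 2, 5, 6)]
  sp <- model_spec("Ind")
  cal1 <- calibration_spec(scen, n_sims = 80)
  cal2 <- calibration_spec(rev(scen), n_sims = 80)
  r1 <- calibrate(sp, cal1, quick_mcmc(), seed = 12)
  r2 <- calibrate(sp, cal2, quick_mcmc(), seed = 12)
  expect_equal(r1$delta, r2$delta)
})

test_that("degenerate calibration problems are refused with diagnostics", {
  # all scenarios effective: no null basket anywhere
  s <- scenario(rep(0.4, 3), n = 10)
  expect_error(calibrate(model_spec("Ind"),
                         calibration_spec(list(s), n_sims = 20),
                         quick_mcmc(), seed = 1),
               "no null baskets")
})

test_that("cutoff grouping follows the history boundary", {
  expect_equal(basketbh:::cutoff_groups(5, 3, "history"),
               c(1L, 1L, 1L, 2L, 2L))
  expect_equal(basketbh:::cutoff_groups(5, 0, "history"), rep(1L, 5))
  expect_equal(basketbh:::cutoff_groups(3, 2, "per_basket"), 1:3)
  expect_equal(basketbh:::cutoff_groups(3, 2, "common"), rep(1L, 3))
})

test_that("calibration results serialize to JSON", {
  rule <- decision_rule(0.1, c(0.9, 0.95))
  attr(rule, "model_name") <- "EXNEX"
  attr(rule, "achieved") <- 0.1
  js <- jsonlite::fromJSON(calibration_json(rule, sub_case = "a"))
  expect_equal(js$model, "EXNEX")
  expect_equal(js$delta, c(0.9, 0.95))
  expect_equal(js$sub_case, "a")
})
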