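test_that("the benchmark grid holds 8 rate vectors times 4 historic sub-cases", {
  scen <- trial_scenarios()
  expect_length(scen, 32)
  expect_equal(scen[["6a"]]$p_true, rep(0.25, 5))
  expect_equal(scen[["8d"]]$p_true, c(0.25, 0.10, 0.10, 0.25, 0.10))
  expect_equal(scen[["1a"]]$p_true, rep(0.10, 5))
  expect_true(all(vapply(scen, function(s) all(s$n == 34), logical(1))))
  # sub-case (c) history: responders (3, 3, 1) out of 13
  h <- scen[["2c"]]$hist
  expect_equal(h$K_star, 3)
  expect_equal(vapply(1:3, function(k) h$studies[[k]][[1]][1], numeric(1)),
               c(3, 3, 1))
  expect_equal(h$studies[[1]][[1]][2], 13)
  none <- trial_scenarios("none")
  expect_length(none, 8)
  expect_equal(none[["3"]]$hist$K_star, 0)
})

test_that("trial simulation is binomial with fixed history", {
  s0 <- scenario(rep(0, 3), n = 10)
  expect_equal(simulate_trial(s0, seed = 1)$y, c(0, 0, 0))
  s1 <- scenario(rep(1, 3), n = 10)
  expect_equal(simulate_trial(s1, seed = 1)$y, c(10, 10, 10))
  sc <- trial_scenarios("a")[["2a"]]
  reps <- vapply(1:4000, function(r)
    simulate_trial(sc, seed = replicate_seed(5, r))$y / sc$n, numeric(5))
  se <- sqrt(sc$p_true * (1 - sc$p_true) / (sc$n * 4000))
  expect_true(all(abs(rowMeans(reps) - sc$p_true) < 3 * se))
})

test_that("replicates are reproducible from (seed, index) and order-invariant", {
  expect_equal(replicate_seed(42, 7), replicate_seed(42, 7))
  expect_false(replicate_seed(42, 7) == replicate_seed(42, 8))
  expect_true(replicate_seed(42, 7) >= 1 && replicate_seed(42, 7) <= 2^30)
  sc <- trial_scenarios("a")[["2a"]]
  expect_equal(simulate_trial(sc, seed = replicate_seed(3, 12))$y,
               simulate_trial(sc, seed = replicate_seed(3, 12))$y)
  sp <- model_spec("Ind")
  rule <- decision_rule(0.1, 0.9)
  oc1 <- operating_characteristics(sp, sc, rule, n_sims = 40,
                                   mcmc = quick_mcmc(), seed = 6)
  oc2 <- operating_characteristics(sp, sc, rule, n_sims = 40,
                                   mcmc = quick_mcmc(), seed = 6)
  expect_equal(oc1$reject_rate, oc2$reject_rate)
  expect_equal(oc1$est_mean, oc2$est_mean)
})

test_that("independent-analysis error rates match exact binomial enumeration", {
  # brute-force oracle: rejection happens iff y >= 6 when Delta = 0.9
  # (1 - pbeta(0.1, 1 + y, 35 - y) crosses 0.9 between y = 5 and 6)
  tails <- 1 - pbeta(0.1, 1 + 0:34, 1 + 34 - 0:34)
  ymin <- min(which(tails >= 0.9)) - 1
  expect_equal(ymin, 6)
  exact_t1 <- 1 - pbinom(ymin - 1, 34, 0.10)
  exact_pow <- 1 - pbinom(ymin - 1, 34, 0.25)
  sc <- trial_scenarios("none")[["2"]]
  oc <- operating_characteristics(model_spec("Ind"), sc,
                                  decision_rule(0.1, 0.9), n_sims = 800,
                                  mcmc = mcmc_config(8000, 1000), seed = 14)
  se_t1 <- sqrt(exact_t1 * (1 - exact_t1) / 800)
  se_pw <- sqrt(exact_pow * (1 - exact_pow) / 800)
  expect_lt(abs(mean(oc$reject_rate[2:5]) - exact_t1), 3 * se_t1 / 2)
  expect_lt(abs(oc$reject_rate[1] - exact_pow), 3 * se_pw)
})

test_that("FWER dominates every individual null error and responds to Delta", {
  sc <- trial_scenarios("none")[["2"]]
  sp <- model_spec("Ind")
  oc <- operating_characteristics(sp, sc, decision_rule(0.1, 0.8),
                                  n_sims = 200, mcmc = quick_mcmc(),
                                  seed = 21)
  expect_gte(oc$fwer, max(oc$reject_rate[sc$p_true <= 0.1]))
  oc0 <- operating_characteristics(sp, sc, decision_rule(0.1, 0),
                                   n_sims = 50, mcmc = quick_mcmc(),
                                   seed = 21)
  expect_equal(oc0$reject_rate, rep(1, 5))
  expect_equal(oc0$fwer, 1)
  df <- as.data.frame(oc0)
  expect_equal(nrow(df), 5)
  expect_true(all(c("model", "scenario", "sub_case", "basket", "true_p",
                    "reject_rate", "fwer", "est_mean", "est_sd", "n_sims",
                    "seed") %in% names(df)))
})

test_that("a one-point sensitivity grid reproduces operating characteristics", {
  sp <- model_spec("Ind")
  sc <- trial_scenarios("a")[["2a"]]
  rule <- decision_rule(0.1, 0.9)
  tab <- sensitivity_grid(sp, grid = list(list(alpha = 0.5)),
                          sub_cases = "a", n_sims = 60, mcmc = quick_mcmc(),
                          seed = 10, scenarios = list(sc), rule = rule)
  oc <- operating_characteristics(sp, sc, rule, n_sims = 60,
                                  mcmc = quick_mcmc(), seed = 10 + 1)
  row13 <- tab[tab$group == "ystar_1", ]
  expect_equal(row13$mean_power, 100 * oc$reject_rate[1])
  expect_equal(row13$max_type1, 100 * max(oc$reject_rate[2:3]))
  expect_error(sensitivity_grid(sp, grid = list()), "non-empty")
})

test_that("the thyroid example data carries the published counts", {
  fx <- believe_roar_data()
  expect_equal(fx$data$y[1] / fx$data$n[1], 5 / 15)
  expect_equal(fx$hist$studies[[1]][[1]], c(20, 36))
  expect_equal(fx$hist$studies[[1]][[1]][1] / fx$hist$studies[[1]][[1]][2],
               20 / 36)
  expect_equal(fx$data$y[8], 1)
  expect_equal(fx$data$n[8], 1)
  expect_equal(sum(!fx$available), 13)
  expect_equal(length(fx$data$y), 15)
})
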