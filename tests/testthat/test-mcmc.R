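test_that("identical seeds give bit-identical draws, different seeds differ", {
  d <- basket_data(c(5, 2, 3, 1, 4), rep(34, 5))
  h <- study_history(c(1, 1, 1))
  for (mn in c("EXNEX", "EXppNEX", "MLMixture", "Ind")) {
    m <- build_model(model_spec(mn), d, h)
    f1 <- fit_basket(m, quick_mcmc(seed = 11))
    f2 <- fit_basket(m, quick_mcmc(seed = 11))
    f3 <- fit_basket(m, quick_mcmc(seed = 12))
    expect_identical(f1$draws$p, f2$draws$p, info = mn)
    expect_false(identical(f1$draws$p, f3$draws$p))
  }
})

test_that("forced power-prior component reproduces the conjugate Beta posterior", {
  # pi = 0 pins every sweep to the NEX component, whose Beta update is an
  # exact conjugate draw: p | y ~ Beta(a + alpha y* + y, b + alpha (n*-y*) + n-y)
  d <- basket_data(5, 34)
  h <- historic_data(list(list(c(3, 13))))
  m <- build_model(model_spec("EXppNEX", prior_config(pi = 0), alpha = 0.5),
                   d, h)
  f <- fit_basket(m, mcmc_config(12000, 2000, seed = 5))
  p <- f$draws$p[, 1]
  expect_lt(abs(mean(p) - 7.5 / 42.5), 3 * sd(p) / sqrt(length(p)))
  ts <- tail_and_se(p)
  expect_lt(abs(ts["est"] - (1 - pbeta(0.1, 7.5, 35))), 3 * ts["se"])
})

test_that("single-basket fits agree with one-dimensional quadrature", {
  # pure NEX (pi = 0): logit-normal prior times binomial likelihood
  d <- basket_data(5, 34)
  m <- build_model(model_spec("EXNEX", prior_config(pi = 0)), d)
  orc <- posterior_oracle(m)
  f <- fit_basket(m, mcmc_config(30000, 3000, seed = 2))
  ts <- tail_and_se(f$draws$p[, 1])
  expect_lt(abs(ts["est"] - orc[1]), 3 * ts["se"])
})

test_that("removing all history reduces EXppNEX to EXNEX draw for draw", {
  d <- basket_data(c(3, 6), c(20, 20))
  mpp <- build_model(model_spec("EXppNEX"), d, no_history(2))
  mex <- build_model(model_spec("EXNEX"), d, no_history(2))
  fpp <- fit_basket(mpp, quick_mcmc(seed = 9))
  fex <- fit_basket(mex, quick_mcmc(seed = 9))
  expect_identical(fpp$draws$p, fex$draws$p)
  expect_identical(fpp$draws$delta, fex$draws$delta)
})

test_that("with empty baskets the chain reproduces the mixture prior", {
  # narrow the hyper-mean prior so the prior predictive is well concentrated
  pr <- prior_config(nu_mu = 4)
  d <- basket_data(c(0, 0, 0), c(0, 0, 0))
  m <- build_model(model_spec("EXNEX", pr), d)
  f <- fit_basket(m, mcmc_config(30000, 3000, seed = 8))
  # direct Monte Carlo from the prior
  set.seed(81)
  nmc <- 30000
  mu <- rnorm(nmc, pr$m_mu, sqrt(pr$nu_mu))
  sg <- abs(rnorm(nmc, 0, 1))
  th1 <- rnorm(nmc, mu, sg)
  nx <- nex_prior_params(pr$rho)
  th2 <- rnorm(nmc, nx$m, sqrt(nx$nu))
  del <- runif(nmc) < 0.5
  pprior <- plogis(ifelse(del, th1, th2))
  for (k in 1:3) {
    pk <- f$draws$p[, k]
    se_m <- max(mc_se(pk), sd(pprior) / sqrt(nmc))
    expect_lt(abs(mean(pk) - mean(pprior)), 3 * (se_m + sd(pprior) / sqrt(nmc)))
    expect_lt(abs(sd(pk) - sd(pprior)), 0.03)
  }
})

test_that("multi-level mixture endpoints reproduce their sub-models", {
  d <- basket_data(c(5, 2, 3, 1, 4), rep(34, 5))
  h <- study_history(c(1, 1, 1))
  au <- augment_trial(d, h)
  mm <- build_model(model_spec("MLMixture"), d, h)
  # generic-engine fits of the two sub-models alone, over the same units
  sub_model <- function(pi_vec, a2, b2) {
    g <- mm
    g$engine <- "exnex"
    g$K <- length(au$y)
    g$y <- au$y; g$n <- au$n
    g$pi <- pi_vec
    g$nex_type <- rep(1L, g$K)
    g$nex_a <- a2; g$nex_b <- b2
    g$nex_m <- rep(0, g$K); g$nex_nu <- rep(4, g$K)
    g$sigma_scale <- 1
    g$labels <- paste0("unit_", seq_len(g$K))
    g
  }
  cfg <- mcmc_config(20000, 3000)
  for (lam in c(1, 0)) {
    spec <- model_spec("MLMixture", pi_lambda = lam)
    fmix <- fit_basket(build_model(spec, d, h), c0 <- {cfg$seed <- 31; cfg})
    sub <- if (lam == 1) sub_model(mm$pi_all, mm$a2_all, mm$b2_all)
           else sub_model(ifelse(au$psi == 1, 0, mm$pi_curr), mm$a0, mm$b0)
    fsub <- fit_basket(sub, {cfg$seed <- 77; cfg})
    for (k in 1:5) {
      t1 <- tail_and_se(fmix$draws$p[, k])
      t2 <- tail_and_se(fsub$draws$p[, k])
      expect_lt(abs(t1["est"] - t2["est"]), 3 * (t1["se"] + t2["se"]),
                label = paste("lambda", lam, "basket", k))
    }
  }
})

test_that("historical borrowing strengthens monotonically in alpha", {
  # current rate far below the historical rate: the posterior mean must
  # move up as the power parameter grows (matched seeds)
  d <- basket_data(2, 34)
  h <- historic_data(list(list(c(10, 13))))
  means <- vapply(c(0, 0.5, 1), function(al) {
    m <- build_model(model_spec("EXppNEX", prior_config(pi = 0), alpha = al),
                     d, h)
    mean(fit_basket(m, mcmc_config(8000, 1000, seed = 404))$draws$p[, 1])
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("posterior_summary reports deterministic functions of the draws", {
  fake <- structure(list(draws = list(p = matrix(0.3, 50, 1)),
                         model_name = "Ind", q0 = 0.1, labels = "b1", K = 1),
                    class = "bbh_fit")
  s <- posterior_summary(fake)
  expect_equal(s$mean, 0.3)
  expect_equal(s$sd, 0)
  expect_equal(s$prob_effective, 1)
  fake$draws$p <- matrix(c(0.05, 0.15), 2, 1)
  s2 <- posterior_summary(fake)
  expect_equal(s2$prob_effective, 0.5)
  fake$draws$p <- matrix(numeric(0), 0, 1)
  expect_error(posterior_summary(fake), "two retained draws")
})

test_that("draw files round-trip losslessly through CSV", {
  d <- basket_data(c(2, 4), c(10, 10))
  f <- fit_basket(build_model(model_spec("EXNEX"), d), quick_mcmc(seed = 3))
  path <- tempfile(fileext = ".csv")
  write_draws(f, path)
  back <- read_draws(path)
  expect_equal(unname(back$p), unname(f$draws$p))
  expect_equal(unname(back$delta), unname(f$draws$delta))
  expect_equal(back$mu, f$draws$mu)
  expect_equal(back$sigma, f$draws$sigma)
})

test_that("invalid sampler configurations are refused", {
  expect_error(mcmc_config(100, 200), "n_iter > n_burn")
  expect_error(mcmc_config(150, 100), "fewer than 100")
  expect_error(mcmc_config(2000, 100, proposal_sd = 0))
})
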