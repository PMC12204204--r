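test_that("nex_prior_params maps a plausible guess to logit-normal moments", {
  expect_equal(nex_prior_params(0.5), list(m = 0, nu = 4))
  p <- nex_prior_params(0.1)
  expect_equal(p$m, -2.1972246, tolerance = 1e-6)
  expect_equal(p$nu, 11.111111, tolerance = 1e-6)
  p <- nex_prior_params(0.175)
  expect_equal(p$m, -1.5505974, tolerance = 1e-6)
  expect_equal(p$nu, 6.9264069, tolerance = 1e-6)
  expect_error(nex_prior_params(0), "\\(0, 1\\)")
  expect_error(nex_prior_params(1), "\\(0, 1\\)")
  # variance is minimized at rho = 0.5 with value 4
  grid <- seq(0.01, 0.99, by = 0.01)
  nu <- nex_prior_params(grid)$nu
  expect_true(all(nu >= 4))
  expect_equal(grid[which.min(nu)], 0.5)
})

test_that("power_prior_params discounts history linearly in alpha", {
  expect_equal(power_prior_params(1, 1, 0, list(c(3, 13)))[c("a", "b")],
               list(a = 1, b = 1))
  expect_equal(power_prior_params(1, 1, 1, list(c(3, 13)))[c("a", "b")],
               list(a = 4, b = 11))
  expect_equal(power_prior_params(1, 1, 0.5, list(c(3, 13)))[c("a", "b")],
               list(a = 2.5, b = 6))
  # shapes interpolate affinely between no-borrowing and full pooling
  for (al in c(0, 0.25, 0.5, 1)) {
    pp <- power_prior_params(2, 3, al, list(c(5, 20), c(1, 10)))
    expect_equal(pp$a, 2 + al * 6)
    expect_equal(pp$b, 3 + al * 24)
  }
  expect_equal(power_prior_params(2, 3, 1, list())[c("a", "b")],
               list(a = 2, b = 3))
  expect_error(power_prior_params(1, 1, c(0.5, 0.5), list(c(3, 13))),
               "one entry per")
  expect_error(power_prior_params(0, 1, 0.5, list(c(3, 13))))
})

test_that("pooling adds historical counts and conserves totals", {
  d <- basket_data(c(5, 2, 3, 1, 4), rep(34, 5))
  h <- study_history(c(3))
  p <- pool_with_history(d, h)
  expect_equal(p$y, c(8, 2, 3, 1, 4))
  expect_equal(p$n, c(47, 34, 34, 34, 34))
  # no history is the identity
  expect_equal(pool_with_history(d, no_history(5))$y, d$y)
  # two studies sum over H_k
  h2 <- historic_data(list(list(c(1, 13), c(3, 13)), list(), list(),
                           list(), list()))
  p2 <- pool_with_history(d, h2)
  expect_equal(p2$y[1], 5 + 4)
  expect_equal(p2$n[1], 34 + 26)
  # conservation of responders and patients across the system
  expect_equal(sum(p2$y), sum(d$y) + 4)
  expect_equal(sum(p2$n), sum(d$n) + 26)
})

test_that("augment_trial unrolls historical baskets with owners and psi", {
  d <- basket_data(c(5, 2, 3, 1, 4), rep(34, 5))
  au <- augment_trial(d, study_history(c(1, 1, 1)))
  expect_equal(length(au$y), 8)
  expect_equal(au$psi, c(rep(0L, 5), rep(1L, 3)))
  expect_equal(au$owner, c(1:5, 1:3))
  expect_equal(au$y, c(d$y, 1, 1, 1))
  au0 <- augment_trial(d, no_history(5))
  expect_equal(au0$psi, rep(0L, 5))
  d1 <- basket_data(2, 10)
  au1 <- augment_trial(d1, historic_data(list(list(c(1, 5), c(2, 6)))))
  expect_equal(length(au1$y), 3)
  expect_equal(au1$owner, c(1, 1, 1))
})

test_that("data containers enforce their invariants", {
  expect_error(basket_data(5, 3), "0 <= y")
  expect_error(basket_data(-1, 3))
  expect_error(basket_data(c(1, 2), 3), "equal length")
  expect_error(historic_data(list(list(c(5, 3)))), "y\\* <= n\\*")
  # history must occupy leading indices
  expect_error(historic_data(list(list(), list(c(1, 13)))), "leading")
  ro <- reorder_history(basket_data(c(1, 2), c(5, 5)),
                        list(list(), list(c(1, 13))))
  expect_equal(ro$perm, c(2, 1))
  expect_equal(ro$data$y, c(2, 1))
  expect_equal(ro$hist$K_star, 1)
})

test_that("build_model assembles the documented graphs", {
  d <- basket_data(c(5, 2, 3, 1, 4), rep(34, 5))
  h <- study_history(c(1, 1, 1))
  expect_error(model_spec("EXNEXX"), "unknown model")

  # EXNEX with pi = 1 is a pure hierarchical model: no NEX branch reachable
  m <- build_model(model_spec("EXNEX", prior_config(pi = 1)), d)
  expect_equal(m$pi, rep(1, 5))

  # EXppNEX: baskets without history keep the logit-normal NEX of EXNEX
  mpp <- build_model(model_spec("EXppNEX"), d, h)
  mex <- build_model(model_spec("EXNEX"), d, h)
  expect_equal(mpp$nex_type, c(1L, 1L, 1L, 0L, 0L))
  expect_equal(mpp$nex_m[4:5], mex$nex_m[4:5])
  expect_equal(mpp$nex_nu[4:5], mex$nex_nu[4:5])
  expect_equal(mpp$nex_a[1:3], rep(1.5, 3)) # 1 + 0.5 * 1
  expect_equal(mpp$nex_b[1:3], rep(7, 3))   # 1 + 0.5 * 12

  # EXppNEX with no history anywhere is EXNEX term by term
  mpp0 <- build_model(model_spec("EXppNEX"), d, no_history(5))
  mex0 <- build_model(model_spec("EXNEX"), d, no_history(5))
  for (f in c("y", "n", "pi", "nex_type", "nex_m", "nex_nu", "m_mu",
              "nu_mu", "sigma_scale"))
    expect_equal(mpp0[[f]], mex0[[f]], info = f)

  # EXNEX_pool's internal counts equal pool_with_history output
  mp <- build_model(model_spec("EXNEX_pool"), d, h)
  pooled <- pool_with_history(d, h)
  expect_equal(mp$y, pooled$y)
  expect_equal(mp$n, pooled$n)

  # MLMixture informative NEX shapes pool each basket's own history fully
  mm <- build_model(model_spec("MLMixture"), d, h)
  expect_equal(mm$a2_all[1:3], rep(2, 3))
  expect_equal(mm$b2_all[1:3], rep(13, 3))
  expect_equal(mm$a2_all[4:5], rep(1, 2))
  expect_equal(mm$a2_all[6:8], rep(1, 3)) # historical units stay flat
  expect_warning(build_model(model_spec("MLMixture"), d, no_history(5)),
                 "degenerates")

  # mEXNEX_hist with a single historical basket falls back to fixed weights
  expect_message(build_model(model_spec("mEXNEX_hist"), d, study_history(c(1))),
                 "equivalent to")
  m1 <- suppressMessages(
    build_model(model_spec("mEXNEX_hist"), d, study_history(c(1))))
  expect_equal(m1$pi, rep(0.5, 5))
})
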