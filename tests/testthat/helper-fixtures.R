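# Shared builders for small test instances.

quick_mcmc <- function(n_iter = 3000, n_burn = 1000, seed = NULL) {
  mcmc_config(n_iter = n_iter, n_burn = n_burn, seed = seed)
}

# history for the first length(ys) of K baskets, one study each
study_history <- function(ys, n_star = 13, K = 5) {
  studies <- replicate(K, list(), simplify = FALSE)
  for (k in seq_along(ys)) studies[[k]] <- list(c(ys[k], n_star))
  historic_data(studies)
}

# draws-based tail probability with its batch-means Monte Carlo SE
tail_and_se <- function(p_draws, q0 = 0.1) {
  ind <- as.numeric(p_draws >= q0)
  c(est = mean(ind), se = max(mc_se(ind), 0.002))
}
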