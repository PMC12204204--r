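#' MCMC configuration
#'
#' @param n_iter Total number of sweeps.
#' @param n_burn Discarded warm-up sweeps (`n_iter > n_burn >= 0`).
#' @param thin Keep-every stride (>= 1).
#' @param seed Integer RNG seed, or `NULL` to continue the current R RNG
#'   stream.  With a seed, draws are bit-identical across runs.
#' @param proposal_sd Initial random-walk step on the logit scale.
#' @param adapt Adapt the step size during burn-in toward a 20-40 percent
#'   acceptance rate (frozen afterwards, so the kept chain is Markovian).
#' @return An object of class `mcmc_config`.
#' @export
mcmc_config <- function(n_iter = 10000, n_burn = 2000, thin = 1,
                        seed = NULL, proposal_sd = 0.5, adapt = TRUE) {
  stopifnot(n_iter > n_burn, n_burn >= 0, thin >= 1, proposal_sd > 0)
  if ((n_iter - n_burn) / thin < 100)
    stop("configuration retains fewer than 100 draws")
  structure(list(n_iter = as.integer(n_iter), n_burn = as.integer(n_burn),
                 thin = as.integer(thin), seed = seed,
                 proposal_sd = proposal_sd, adapt = isTRUE(adapt)),
            class = "mcmc_config")
}

#' Fit a basket model by Metropolis-within-Gibbs sampling
#'
#' Runs the seeded sampler appropriate for the model graph's engine and
#' returns posterior draws of the basket response rates together with the
#' component-membership indicators and hierarchy parameters.  The
#' independent (conjugate Beta) engine draws i.i.d. samples from the exact
#' posterior so the same downstream summaries apply.
#'
#' The R random number generator (Mersenne-Twister) drives all randomness;
#' identical seed, configuration and model give bit-identical draws.
#'
#' @param model A model graph from [build_model()].
#' @param mcmc An [mcmc_config()].
#' @return An object of class `bbh_fit` with a `draws` list (`p` is an
#'   iterations-by-baskets matrix; `delta`, `mu`, `sigma`, `lambda` present
#'   where the model defines them) and fitting metadata.
#' @examples
#' d <- basket_data(c(5, 2, 3, 1, 4), rep(34, 5))
#' fit <- fit_basket(build_model(model_spec("EXNEX"), d),
#'                   mcmc_config(2000, 500, seed = 1))
#' posterior_summary(fit)
#' @export
fit_basket <- function(model, mcmc = mcmc_config()) {
  stopifnot(inherits(model, "bbh_model"), inherits(mcmc, "mcmc_config"))
  if (!is.null(mcmc$seed)) set.seed(mcmc$seed)
  n_keep <- (mcmc$n_iter - mcmc$n_burn) %/% mcmc$thin
  draws <- switch(model$engine,
    beta = {
      p <- vapply(seq_len(model$K), function(k) {
        rbeta(n_keep, model$a[k] + model$y[k],
              model$b[k] + model$n[k] - model$y[k])
      }, numeric(n_keep))
      list(p = p)
    },
    exnex = {
      out <- exnex_mcmc(model$y, model$n, model$pi, model$nex_type,
                        model$nex_m, model$nex_nu, model$nex_a, model$nex_b,
                        model$m_mu, model$nu_mu, model$sigma_scale,
                        mcmc$n_iter, mcmc$n_burn, mcmc$thin,
                        mcmc$proposal_sd, mcmc$adapt)
      if (all(!is.na(out$accept_ex)) && all(out$accept_ex == 0) &&
          any(model$pi > 0))
        warning("zero acceptance for the EX random-walk updates")
      list(p = out$p, delta = out$delta, mu = out$mu, sigma = out$sigma,
           accept = out$accept_ex)
    },
    mlmix = {
      au <- model$units
      out <- mlmix_mcmc(au$y, au$n, au$psi, au$owner, model$K,
                        model$pi_all, model$pi_curr,
                        model$a2_all, model$b2_all, model$a0, model$b0,
                        model$pi_lambda, model$m_mu, model$nu_mu,
                        model$sigma_scale_all, model$sigma_scale_curr,
                        mcmc$n_iter, mcmc$n_burn, mcmc$thin,
                        mcmc$proposal_sd, mcmc$adapt, model$distinct)
      list(p = out$p, lambda = out$lambda, delta = out$delta_all,
           delta_curr = out$delta_curr, p_all = out$p_all,
           p_curr = out$p_curr, mu = out$mu_all, sigma = out$sigma_all,
           mu_curr = out$mu_curr, sigma_curr = out$sigma_curr)
    },
    stop("unknown engine: ", model$engine))
  colnames(draws$p) <- model$labels
  structure(list(draws = draws, model_name = model$model_name,
                 q0 = model$q0, labels = model$labels, K = model$K,
                 mcmc = mcmc),
            class = "bbh_fit")
}

#' Posterior summaries per basket
#'
#' @param fit A [fit_basket()] result.
#' @param q0 Null response rate the efficacy probability is computed
#'   against; defaults to the rate stored in the fit.
#' @return A data frame with one row per basket: posterior mean, SD,
#'   equal-tailed 95 percent interval, `prob_effective`
#'   (`P(p_k >= q0 | data)`), and the posterior mean of the membership
#'   indicators where defined (`ex_weight` for `delta_k`, `lambda_weight`
#'   for the model-mixture indicator).
#' @export
posterior_summary <- function(fit, q0 = fit$q0) {
  stopifnot(inherits(fit, "bbh_fit"))
  p <- fit$draws$p
  if (is.null(p) || nrow(p) < 2L) stop("need at least two retained draws")
  out <- data.frame(
    basket = fit$labels,
    mean = colMeans(p),
    sd = apply(p, 2, sd),
    lower95 = apply(p, 2, quantile, probs = 0.025, names = FALSE),
    upper95 = apply(p, 2, quantile, probs = 0.975, names = FALSE),
    prob_effective = colMeans(p >= q0),
    stringsAsFactors = FALSE)
  if (!is.null(fit$draws$delta)) out$ex_weight <- colMeans(fit$draws$delta)
  if (!is.null(fit$draws$lambda))
    out$lambda_weight <- colMeans(fit$draws$lambda)
  rownames(out) <- NULL
  out
}

#' @export
print.bbh_fit <- function(x, ...) {
  cat("basketbh fit:", x$model_name, "model,",
      nrow(x$draws$p), "retained draws\n")
  print(posterior_summary(x), digits = 3)
  invisible(x)
}

#' Monte Carlo standard error by batch means
#'
#' @param x Numeric vector of (possibly autocorrelated) draws.
#' @param n_batch Number of batches.
#' @return Estimated standard error of `mean(x)`.
#' @export
mc_se <- function(x, n_batch = 40) {
  n <- length(x)
  if (n < 2 * n_batch) return(sd(x) / sqrt(n))
  m <- n %/% n_batch
  bm <- colMeans(matrix(x[seq_len(m * n_batch)], nrow = m))
  sd(bm) / sqrt(n_batch)
}

#' Write posterior draws to CSV
#'
#' One row per retained draw; columns are named `p[1]..p[K]`,
#' `delta[1]..delta[K]`, `mu`, `sigma`, `lambda[1]..lambda[K]` as the model
#' defines them.  Values are written with 17 significant digits so the file
#' round-trips losslessly through [read_draws()].
#'
#' @param fit A [fit_basket()] result.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_draws <- function(fit, path) {
  stopifnot(inherits(fit, "bbh_fit"))
  d <- fit$draws
  K <- fit$K
  cols <- list()
  add_mat <- function(cols, m, base) {
    for (k in seq_len(ncol(m))) cols[[sprintf("%s[%d]", base, k)]] <- m[, k]
    cols
  }
  cols <- add_mat(cols, d$p, "p")
  if (!is.null(d$delta)) cols <- add_mat(cols, d$delta, "delta")
  if (!is.null(d$mu)) cols$mu <- d$mu
  if (!is.null(d$sigma)) cols$sigma <- d$sigma
  if (!is.null(d$lambda)) cols <- add_mat(cols, d$lambda, "lambda")
  txt <- vapply(cols, function(x) sprintf("%.17g", x),
                character(length(cols[[1]])))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(sprintf('"%s"', names(cols)), collapse = ","), con)
  writeLines(apply(matrix(txt, ncol = length(cols)), 1, paste,
                   collapse = ","), con)
  invisible(path)
}

#' Read posterior draws written by [write_draws()]
#'
#' @param path CSV path.
#' @return A draws list with matrices/vectors reassembled by name.
#' @export
read_draws <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  out <- list()
  for (base in c("p", "delta", "lambda")) {
    idx <- grep(sprintf("^%s\\[", base), names(df))
    if (length(idx)) out[[base]] <- as.matrix(df[, idx, drop = FALSE])
  }
  if ("mu" %in% names(df)) out$mu <- df$mu
  if ("sigma" %in% names(df)) out$sigma <- df$sigma
  out
}
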