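#' Prior configuration for the basket models
#'
#' Collects the hyperparameters shared by the model family.  Defaults follow
#' common practice for binomial basket designs: the exchangeable (EX)
#' hyper-mean is centred at `logit(q0)` with variance 100, the borrowing
#' standard deviation has a Half-Normal(0, 1) prior, the nonexchangeable
#' (NEX) plausible guess `rho` sits midway between the null and target
#' rates, and all Beta priors are the flat Beta(1, 1).
#'
#' @param q0 Null response rate in (0, 1).
#' @param q1 Target response rate in (0, 1).
#' @param m_mu EX hyper-mean location (default `logit(q0)`).
#' @param nu_mu EX hyper-mean variance (> 0).
#' @param sigma_prior_scale Scale of the half-normal prior on the borrowing
#'   SD `sigma` in the EX hierarchy.
#' @param sigma_prior_scale_curr Scale for the second (current-only)
#'   hierarchy of the multi-level mixture; defaults to `sigma_prior_scale`.
#' @param rho Per-basket plausible guess for the NEX logit-normal prior;
#'   recycled to length K at model build time.  Default `(q0 + q1)/2`.
#' @param a,b Beta prior shape parameters used wherever a Beta prior enters
#'   (power prior baseline, multi-level mixture NEX, independent analysis).
#' @param pi Prior exchangeability weight(s) `pi_k` in `[0, 1]`.
#' @return An object of class `prior_config`.
#' @export
prior_config <- function(q0 = 0.1, q1 = 0.25,
                         m_mu = NULL, nu_mu = 100,
                         sigma_prior_scale = 1,
                         sigma_prior_scale_curr = sigma_prior_scale,
                         rho = (q0 + q1) / 2,
                         a = 1, b = 1, pi = 0.5) {
  stopifnot(q0 > 0, q0 < 1, q1 > 0, q1 < 1, nu_mu > 0,
            sigma_prior_scale > 0, sigma_prior_scale_curr > 0,
            all(a > 0), all(b > 0))
  if (any(rho <= 0) || any(rho >= 1)) stop("'rho' must lie in (0, 1)")
  if (any(pi < 0) || any(pi > 1)) stop("'pi' must lie in [0, 1]")
  if (is.null(m_mu)) m_mu <- stats::qlogis(q0)
  structure(list(q0 = q0, q1 = q1, m_mu = m_mu, nu_mu = nu_mu,
                 sigma_prior_scale = sigma_prior_scale,
                 sigma_prior_scale_curr = sigma_prior_scale_curr,
                 rho = rho, a = a, b = b, pi = pi),
            class = "prior_config")
}

#' Nonexchangeable prior parameters from a plausible guess
#'
#' Maps a plausible response rate `rho` to the mean and variance of the
#' weakly-informative logit-normal NEX prior: `m = logit(rho)`,
#' `nu = 1/rho + 1/(1 - rho)`.  The variance is minimal (4) at `rho = 0.5`,
#' which keeps the prior close to uniform on the probability scale.
#'
#' @param rho Plausible response rate in (0, 1); vectorized.
#' @return A list with numeric components `m` and `nu`.
#' @examples
#' nex_prior_params(0.5)    # m = 0, nu = 4
#' nex_prior_params(0.175)
#' @export
nex_prior_params <- function(rho) {
  if (any(!is.finite(rho)) || any(rho <= 0) || any(rho >= 1))
    stop("'rho' must lie strictly in (0, 1)")
  list(m = stats::qlogis(rho), nu = 1 / rho + 1 / (1 - rho))
}

#' Power-prior Beta parameters from historical counts
#'
#' Discounts each historical study's binomial likelihood by a power
#' `alpha_j` in `[0, 1]` and folds it into an initial Beta(a, b) prior,
#' giving `Beta(a + sum_j alpha_j * y*_j, b + sum_j alpha_j * (n*_j - y*_j))`.
#' `alpha = 0` erases the history; `alpha = 1` is full conjugate pooling.
#'
#' @param a,b Initial Beta shape parameters (> 0).
#' @param alpha Numeric vector of per-study power parameters, one per
#'   historical study.
#' @param historic List of `c(y_star, n_star)` pairs (may be empty).
#' @return A list with shapes `a` and `b` (class `beta_params`).
#' @examples
#' power_prior_params(1, 1, alpha = 0.5, historic = list(c(3, 13)))
#' @export
power_prior_params <- function(a, b, alpha, historic) {
  stopifnot(a > 0, b > 0)
  if (length(historic) == 0L)
    return(structure(list(a = a, b = b), class = "beta_params"))
  if (length(alpha) == 1L) alpha <- rep(alpha, length(historic))
  if (length(alpha) != length(historic))
    stop("'alpha' must have one entry per historical study")
  if (any(alpha < 0) || any(alpha > 1)) stop("'alpha' must lie in [0, 1]")
  for (j in seq_along(historic)) {
    s <- as.numeric(historic[[j]])
    if (length(s) != 2L || s[1] < 0 || s[1] > s[2])
      stop("invalid historical counts in study ", j)
    a <- a + alpha[j] * s[1]
    b <- b + alpha[j] * (s[2] - s[1])
  }
  structure(list(a = a, b = b), class = "beta_params")
}

#' Model specification
#'
#' Names one of the six analysis models and its hyperparameters.  Fields
#' irrelevant to the chosen model are validated but ignored.
#'
#' Models: `"Ind"` (independent conjugate Beta-binomial per basket),
#' `"EXNEX"` (exchangeability-nonexchangeability mixture over current
#' baskets), `"EXNEX_pool"` (EXNEX over counts pooled with history),
#' `"mEXNEX_hist"` (EXNEX with exchangeability weights computed from
#' Hellinger distances between Beta posteriors of the pooled historical
#' baskets), `"EXppNEX"` (EXNEX whose NEX component is a power-prior Beta
#' when history exists), `"MLMixture"` (per-basket mixture of two EXNEX
#' models fitted over current plus historical units).
#'
#' @param model_name One of `"Ind"`, `"EXNEX"`, `"EXNEX_pool"`,
#'   `"mEXNEX_hist"`, `"EXppNEX"`, `"MLMixture"`.
#' @param prior A [prior_config()].
#' @param alpha Power parameter(s) for EXppNEX, in `[0, 1]`.
#' @param zeta Down-weight scalar in `[0, 1]` applied to the exchangeability
#'   weight of baskets without history (mEXNEX_hist).
#' @param pi_lambda Prior model-mixture weight(s) of the multi-level mixture.
#' @param pi_all,pi_curr Prior EX weights of the two multi-level mixture
#'   sub-models.
#' @param coupling How the two multi-level mixture sub-models are coupled:
#'   `"distinct"` (default) fits both with the full likelihood and lets
#'   `lambda_k` mix their draws with likelihood-ratio odds;
#'   `"product_space"` runs a Carlin-Chib product-space chain in which a
#'   basket's likelihood feeds only the sub-model its `lambda_k` selects.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(model_name, prior = prior_config(),
                       alpha = 0.5, zeta = 0.8,
                       pi_lambda = 0.5, pi_all = 0.5, pi_curr = 0.5,
                       coupling = c("distinct", "product_space")) {
  models <- c("Ind", "EXNEX", "EXNEX_pool", "mEXNEX_hist", "EXppNEX",
              "MLMixture")
  if (!is.character(model_name) || length(model_name) != 1L ||
      !(model_name %in% models))
    stop("unknown model '", paste(model_name, collapse = ","),
         "'; must be one of: ", paste(models, collapse = ", "))
  stopifnot(inherits(prior, "prior_config"))
  for (w in list(alpha = alpha, zeta = zeta, pi_lambda = pi_lambda,
                 pi_all = pi_all, pi_curr = pi_curr)) {
    if (any(w < 0) || any(w > 1)) stop("weights and alpha must lie in [0, 1]")
  }
  coupling <- match.arg(coupling)
  structure(list(model_name = model_name, prior = prior, alpha = alpha,
                 zeta = zeta, pi_lambda = pi_lambda, pi_all = pi_all,
                 pi_curr = pi_curr, coupling = coupling),
            class = "model_spec")
}

rep_len_chk <- function(x, K) {
  if (length(x) == 1L) rep(x, K) else if (length(x) == K) x
  else stop("parameter has length ", length(x), ", expected 1 or ", K)
}

#' Build an inference-ready model graph
#'
#' Combines a [model_spec()] with observed data into the deterministic
#' description the sampler consumes: per-basket prior parameters, NEX
#' component types (logit-normal or Beta), mixture weights, and for the
#' multi-level mixture the augmented unit list.  No inference is performed.
#'
#' @param spec A [model_spec()].
#' @param data A [basket_data()] object.
#' @param hist A [historic_data()] object (defaults to no history).
#' @return An object of class `bbh_model` whose `engine` element selects the
#'   sampler (`"beta"`, `"exnex"` or `"mlmix"`).
#' @export
build_model <- function(spec, data, hist = no_history(data$K)) {
  stopifnot(inherits(spec, "model_spec"), inherits(data, "basket_data"),
            inherits(hist, "historic_data"))
  if (hist$K != data$K) stop("'data' and 'hist' must cover the same baskets")
  pr <- spec$prior
  K <- data$K
  a <- rep_len_chk(pr$a, K); b <- rep_len_chk(pr$b, K)
  pi <- rep_len_chk(pr$pi, K)
  nx <- nex_prior_params(rep_len_chk(pr$rho, K))
  base <- list(model_name = spec$model_name, spec = spec, data = data,
               hist = hist, q0 = pr$q0, labels = data$labels)

  g <- switch(spec$model_name,
    Ind = c(base, list(engine = "beta", K = K, y = data$y, n = data$n,
                       a = a, b = b)),
    EXNEX = c(base, list(engine = "exnex", K = K, y = data$y, n = data$n,
                         pi = pi, nex_type = rep(0L, K), nex_m = nx$m,
                         nex_nu = nx$nu, nex_a = a, nex_b = b,
                         m_mu = pr$m_mu, nu_mu = pr$nu_mu,
                         sigma_scale = pr$sigma_prior_scale)),
    EXNEX_pool = {
      pooled <- pool_with_history(data, hist)
      c(base, list(engine = "exnex", K = K, y = pooled$y, n = pooled$n,
                   pi = pi, nex_type = rep(0L, K), nex_m = nx$m,
                   nex_nu = nx$nu, nex_a = a, nex_b = b,
                   m_mu = pr$m_mu, nu_mu = pr$nu_mu,
                   sigma_scale = pr$sigma_prior_scale))
    },
    mEXNEX_hist = {
      pih <- if (hist$K_star >= 2L) {
        exchangeability_weights(hist, K, zeta = spec$zeta, a0 = a[1],
                                b0 = b[1])$pi
      } else {
        # with fewer than two historical baskets the Hellinger average is
        # undefined; fall back to the configured fixed weights
        message("mEXNEX_hist: fewer than two historical baskets; ",
                "using the fixed prior weights (equivalent to EXNEX)")
        pi
      }
      c(base, list(engine = "exnex", K = K, y = data$y, n = data$n,
                   pi = pih, nex_type = rep(0L, K), nex_m = nx$m,
                   nex_nu = nx$nu, nex_a = a, nex_b = b,
                   m_mu = pr$m_mu, nu_mu = pr$nu_mu,
                   sigma_scale = pr$sigma_prior_scale))
    },
    EXppNEX = {
      nex_type <- as.integer(hist$H > 0L)
      na <- a; nb <- b
      for (k in seq_len(K)) {
        if (hist$H[k] > 0L) {
          pp <- power_prior_params(a[k], b[k], spec$alpha, hist$studies[[k]])
          na[k] <- pp$a; nb[k] <- pp$b
        }
      }
      c(base, list(engine = "exnex", K = K, y = data$y, n = data$n,
                   pi = pi, nex_type = nex_type, nex_m = nx$m,
                   nex_nu = nx$nu, nex_a = na, nex_b = nb,
                   m_mu = pr$m_mu, nu_mu = pr$nu_mu,
                   sigma_scale = pr$sigma_prior_scale))
    },
    MLMixture = {
      if (hist$K_star == 0L)
        warning("MLMixture without historical data degenerates to two ",
                "coupled copies of an EXNEX model with Beta NEX priors")
      au <- augment_trial(data, hist)
      I <- length(au$y)
      a2_all <- numeric(I); b2_all <- numeric(I)
      a0 <- numeric(I); b0 <- numeric(I)
      for (i in seq_len(I)) {
        k <- au$owner[i]
        a0[i] <- a[k]; b0[i] <- b[k]
        if (au$psi[i] == 0L && hist$H[k] > 0L) {
          # informative NEX of the all-units sub-model: full conjugate
          # pooling of the basket's own history
          pp <- power_prior_params(a[k], b[k], 1, hist$studies[[k]])
          a2_all[i] <- pp$a; b2_all[i] <- pp$b
        } else {
          a2_all[i] <- a[k]; b2_all[i] <- b[k]
        }
      }
      c(base, list(engine = "mlmix", K = K, units = au,
                   distinct = spec$coupling == "distinct",
                   pi_all = rep_len_chk(spec$pi_all, I),
                   pi_curr = rep_len_chk(spec$pi_curr, I),
                   pi_lambda = rep_len_chk(spec$pi_lambda, K),
                   a2_all = a2_all, b2_all = b2_all, a0 = a0, b0 = b0,
                   m_mu = pr$m_mu, nu_mu = pr$nu_mu,
                   sigma_scale_all = pr$sigma_prior_scale,
                   sigma_scale_curr = pr$sigma_prior_scale_curr))
    })
  class(g) <- "bbh_model"
  g
}

#' @export
print.bbh_model <- function(x, ...) {
  cat("basketbh model graph:", x$model_name, "(engine:", x$engine, ")\n")
  cat("  baskets:", x$K, " null rate q0:", x$q0, "\n")
  if (x$engine == "exnex")
    cat("  pi:", paste(round(x$pi, 3), collapse = ", "), "\n")
  invisible(x)
}
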