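#' Deterministic quadrature oracle for small model instances
#'
#' Computes `P(p_k > q0 | data)` for an EXNEX-family model graph by direct
#' numerical integration instead of MCMC: the posterior is decomposed over
#' the `2^K` membership configurations `delta`; nonexchangeable components
#' contribute closed-form (Beta) or one-dimensional (logit-normal) marginal
#' likelihoods; the exchangeable block is integrated over a `(mu, sigma)`
#' grid with an inner theta quadrature whose nodes include the `logit(q0)`
#' cut exactly.  Intended as a validation oracle for instances with few
#' baskets and small counts; refusal on large state spaces is deliberate.
#'
#' @param model A model graph from [build_model()] with engine `"beta"` or
#'   `"exnex"`.
#' @param q0 Threshold rate; defaults to the model's null rate.
#' @param resolution Positive multiplier on all grid densities; doubling it
#'   roughly halves the discretization error.
#' @param max_states Guard on `2^K * n_mu * n_sigma * K`.
#' @return Named numeric vector of per-basket posterior probabilities
#'   `P(p_k > q0)`, with the posterior configuration weights attached as
#'   attribute `config_weights`.
#' @examples
#' d <- basket_data(c(1, 4), c(5, 5))
#' m <- build_model(model_spec("EXNEX"), d)
#' posterior_oracle(m)
#' @export
posterior_oracle <- function(model, q0 = model$q0, resolution = 1,
                             max_states = 1e7) {
  stopifnot(inherits(model, "bbh_model"))
  if (model$engine == "beta") {
    out <- 1 - pbeta(q0, model$a + model$y, model$b + model$n - model$y)
    names(out) <- model$labels
    return(out)
  }
  if (model$engine != "exnex")
    stop("the quadrature oracle supports the beta and exnex engines only")
  K <- model$K
  n_mu <- round(321 * resolution)
  n_sigma <- round(61 * resolution)
  n_z <- round(601 * resolution)
  if (2^K * n_mu * n_sigma * K > max_states)
    stop("state space exceeds ", max_states,
         "; shrink the instance or lower 'resolution'")
  sd_mu <- sqrt(model$nu_mu)
  mu_grid <- seq(model$m_mu - 4.5 * sd_mu, model$m_mu + 4.5 * sd_mu,
                 length.out = n_mu)
  sig_grid <- seq(1e-3, 4 * model$sigma_scale, length.out = n_sigma)
  trap_w <- function(g) {
    h <- diff(g)
    c(h[1] / 2, (h[-1] + h[-length(h)]) / 2, h[length(h)] / 2)
  }
  hn_dens <- function(s, scale) {
    sqrt(2 / pi) / scale * exp(-s^2 / (2 * scale^2))
  }
  w_mu <- trap_w(mu_grid) * dnorm(mu_grid, model$m_mu, sd_mu)
  w_sig <- trap_w(sig_grid) * hn_dens(sig_grid, model$sigma_scale)
  W <- outer(w_mu, w_sig)
  gi <- ex_grid_integrals(model$y, model$n, mu_grid, sig_grid, q0, n_z)
  ell <- gi$ell
  tau <- gi$tau

  # NEX marginal likelihood and conditional tail per basket
  m2 <- tail2 <- numeric(K)
  for (k in seq_len(K)) {
    y <- model$y[k]; n <- model$n[k]
    if (model$nex_type[k] == 1L) {
      a <- model$nex_a[k]; b <- model$nex_b[k]
      m2[k] <- exp(lchoose(n, y) + lbeta(a + y, b + n - y) - lbeta(a, b))
      tail2[k] <- 1 - pbeta(q0, a + y, b + n - y)
    } else {
      m <- model$nex_m[k]; s <- sqrt(model$nex_nu[k])
      f <- function(t) dbinom(y, n, stats::plogis(t)) * dnorm(t, m, s)
      m2[k] <- integrate(f, -Inf, Inf, rel.tol = 1e-10)$value
      up <- integrate(f, stats::qlogis(q0), Inf, rel.tol = 1e-10)$value
      tail2[k] <- up / m2[k]
    }
  }

  configs <- as.matrix(expand.grid(rep(list(0:1), K)))
  prob <- numeric(K)
  wgt <- numeric(nrow(configs))
  Pmat <- matrix(0, nrow(configs), K)
  for (ci in seq_len(nrow(configs))) {
    d <- configs[ci, ]
    pw <- prod(ifelse(d == 1, model$pi, 1 - model$pi))
    if (pw == 0) next
    S <- which(d == 1)
    if (length(S)) {
      EXmat <- Reduce(`*`, ell[S])
      m_ex <- sum(W * EXmat)
    } else {
      m_ex <- 1
    }
    wgt[ci] <- pw * m_ex * prod(m2[setdiff(seq_len(K), S)])
    for (k in seq_len(K)) {
      if (d[k] == 1) {
        others <- setdiff(S, k)
        rest <- if (length(others)) Reduce(`*`, ell[others]) else 1
        Pmat[ci, k] <- sum(W * rest * tau[[k]]) / m_ex
      } else {
        Pmat[ci, k] <- tail2[k]
      }
    }
  }
  if (sum(wgt) <= 0) stop("all configuration weights vanished")
  wgt <- wgt / sum(wgt)
  prob <- as.numeric(crossprod(wgt, Pmat))
  names(prob) <- model$labels
  attr(prob, "config_weights") <- setNames(
    wgt, apply(configs, 1, paste, collapse = ""))
  prob
}
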