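#' Hellinger distance between two Beta distributions
#'
#' Uses the closed form for the Bhattacharyya coefficient of two Beta
#' densities,
#' `BC = B((a1 + a2)/2, (b1 + b2)/2) / sqrt(B(a1, b1) * B(a2, b2))`,
#' evaluated through log-Beta functions for numerical stability, giving
#' `H = sqrt(1 - BC)`.  The distance is symmetric, zero iff the parameters
#' coincide, and bounded by 1.
#'
#' @param a1,b1 Shape parameters of the first Beta distribution (> 0).
#' @param a2,b2 Shape parameters of the second Beta distribution (> 0).
#' @return Hellinger distance in `[0, 1]`; vectorized over the shapes.
#' @examples
#' hellinger_beta(2, 13, 2, 13)  # 0
#' hellinger_beta(2, 13, 4, 11)
#' @export
hellinger_beta <- function(a1, b1, a2, b2) {
  if (any(c(a1, b1, a2, b2) <= 0) || any(!is.finite(c(a1, b1, a2, b2))))
    stop("Beta shape parameters must be positive and finite")
  log_bc <- lbeta((a1 + a2) / 2, (b1 + b2) / 2) -
    0.5 * (lbeta(a1, b1) + lbeta(a2, b2))
  h2 <- 1 - exp(log_bc)
  sqrt(pmax(h2, 0))
}

#' Data-driven exchangeability weights from historical baskets
#'
#' Computes the prior exchangeability probabilities used by the
#' `mEXNEX_hist` model.  For each of the `K*` baskets with history, the
#' studies are pooled (`y_hat = sum y*`, `n_hat = sum n*`), a Beta-binomial
#' model with a Beta(a0, b0) prior is fitted, and the weight is the average
#' of one minus the Hellinger distance to every other historical basket's
#' posterior.  Baskets without history receive the mean of those weights
#' scaled down by `zeta` to reflect the extra uncertainty.
#'
#' @param hist A [historic_data()] object with `K* >= 2` historical baskets.
#' @param K Total number of current baskets.
#' @param zeta Down-weight scalar(s) in `[0, 1]` for baskets without
#'   history.
#' @param a0,b0 Beta prior shapes for the historical Beta-binomial fits.
#' @return A list with elements `pi` (length-`K` weight vector), `posterior`
#'   (the Beta shape matrix of the historical posteriors) and `h` (the
#'   `K* x K*` Hellinger distance matrix).
#' @examples
#' h <- historic_data(list(list(c(3, 13)), list(c(1, 13)), list(c(1, 13)),
#'                         list(), list()))
#' exchangeability_weights(h, K = 5)$pi
#' @export
exchangeability_weights <- function(hist, K, zeta = 0.8, a0 = 1, b0 = 1) {
  stopifnot(inherits(hist, "historic_data"), a0 > 0, b0 > 0)
  if (hist$K != K) stop("'hist' must describe the same ", K, " baskets")
  Ks <- hist$K_star
  if (Ks <= 1L)
    stop("exchangeability weights need at least two historical baskets; ",
         "with K* <= 1 fall back to fixed prior weights")
  zeta <- rep_len_chk(zeta, K)
  if (any(zeta < 0) || any(zeta > 1)) stop("'zeta' must lie in [0, 1]")
  yh <- nh <- numeric(Ks)
  for (k in seq_len(Ks)) {
    yh[k] <- sum(vapply(hist$studies[[k]], `[`, numeric(1), 1))
    nh[k] <- sum(vapply(hist$studies[[k]], `[`, numeric(1), 2))
  }
  if (any(nh == 0))
    stop("historical baskets with pooled sample size 0 are not supported")
  ap <- a0 + yh
  bp <- b0 + nh - yh
  h <- outer(seq_len(Ks), seq_len(Ks),
             function(i, j) hellinger_beta(ap[i], bp[i], ap[j], bp[j]))
  pi <- numeric(K)
  for (k in seq_len(Ks)) pi[k] <- mean(1 - h[-k, k])
  if (K > Ks) pi[(Ks + 1):K] <- zeta[(Ks + 1):K] * mean(pi[seq_len(Ks)])
  pi <- pmin(pmax(pi, 0), 1)
  list(pi = pi, posterior = cbind(a = ap, b = bp), h = h)
}
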