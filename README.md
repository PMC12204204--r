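# basketbh

Bayesian analysis and design of basket trials that borrow information
both **between baskets** and **from historical data**.

In a basket trial one treatment is tested across several disease types
("baskets") sharing a genetic aberration, each basket observing
`y_k ~ Binomial(n_k, p_k)` responders, with the per-basket test
`H0: p_k <= q0` vs `H1: p_k > q0`.  Basket sample sizes are small, so
Bayesian information borrowing is standard practice — classically via the
exchangeability–nonexchangeability (EXNEX) model,

```
p_k = delta_k * M_1k + (1 - delta_k) * M_2k,     delta_k ~ Bernoulli(pi_k)
logit(M_1k) ~ N(mu, sigma^2),   mu ~ N(m_mu, nu_mu),  sigma ~ HalfNormal(0, 1)
logit(M_2k) ~ N(logit(rho_k), 1/rho_k + 1/(1 - rho_k))
```

This package is for trial statisticians who also have **historical
baskets** — the same disease/treatment pair observed in a completed study
with fixed counts `(y*_k, n*_k)` — and want to fold them in.  It
implements six calibrated analyses behind one interface:

| model | historical borrowing |
|---|---|
| `Ind` | none; independent Beta–binomial per basket |
| `EXNEX` | none; between-basket only |
| `EXNEX_pool` | pools each basket with its own history before fitting EXNEX |
| `EXppNEX` | power prior `Beta(a + sum alpha_j y*_j, b + sum alpha_j (n*_j - y*_j))` as the NEX component |
| `mEXNEX_hist` | prior weights `pi_k` from Hellinger distances between Beta posteriors of the historical baskets |
| `MLMixture` | per-basket mixture of two EXNEX models fitted over current *and* historical units |

plus the surrounding machinery: a seeded Metropolis-within-Gibbs sampler
(C++), deterministic quadrature oracles for validation, efficacy-cutoff
calibration controlling the **average basket-wise type I error** across a
scenario set, and a Monte Carlo engine for operating characteristics
(power, type I error, FWER, estimate summaries) over a benchmark
8-scenario × 4-historic-sub-case grid.

## Worked example

Five baskets of 34 patients; the first three have one historical study
of 13 patients each.  Fit the power-prior model and apply a 0.9 efficacy
cutoff at `q0 = 0.1`:

```r
library(basketbh)

d <- basket_data(y = c(8, 2, 3, 1, 4), n = rep(34, 5),
                 labels = c("NSCLC", "ovarian", "colorectal", "thyroid", "larynx"))
h <- historic_data(list(list(c(3, 13)), list(c(1, 13)), list(c(1, 13)),
                        list(), list()))

fit <- fit_basket(build_model(model_spec("EXppNEX", alpha = 0.5), d, h),
                  mcmc_config(seed = 1))
fit
#> basketbh fit: EXppNEX model, 8000 retained draws
#>       basket   mean     sd lower95 upper95 prob_effective ex_weight
#> 1      NSCLC 0.2395 0.0691 0.11500   0.383         0.9889     0.152
#> 2    ovarian 0.0782 0.0402 0.01823   0.171         0.2597     0.427
#> 3 colorectal 0.0998 0.0461 0.02956   0.210         0.4445     0.384
#> 4    thyroid 0.0457 0.0340 0.00335   0.128         0.0765     0.433
#> 5     larynx 0.1107 0.0511 0.03540   0.231         0.5290     0.474

decide(posterior_summary(fit), decision_rule(q0 = 0.1, delta = 0.9))
#>      NSCLC    ovarian colorectal    thyroid     larynx
#>       TRUE      FALSE      FALSE      FALSE      FALSE
```

Reading the output: `mean`/`sd` summarize the posterior response rate,
`prob_effective` is `P(p_k >= 0.1 | data)`, and `ex_weight` the posterior
probability the basket sits in the exchangeable (borrowing) component.
The 8/34 NSCLC basket, backed by a 3/13 historical study feeding its
power prior, clears the 0.9 cutoff; the others do not.  The data-driven
weights used by `mEXNEX_hist` for the same history are

```r
round(exchangeability_weights(h, K = 5)$pi, 3)
#> [1] 0.533 0.766 0.766 0.551 0.551
```

— basket 1's heterogeneous 3/13 history lowers its weight relative to
baskets 2 and 3, and baskets without history get 0.8 times the mean.

In practice `delta` comes from `calibrate()`, which simulates the
scenario grid (`trial_scenarios()`) and picks the cutoffs achieving a
10% average basket-wise type I error; `operating_characteristics()` then
evaluates power and error rates at those cutoffs.  A YAML/JSON-driven
command line sits in `inst/cli/basketbh.R` (commands `fit`, `calibrate`,
`oc`, `sensitivity`, `fixtures`).

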