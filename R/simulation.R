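#' Construct a simulation scenario
#'
#' A scenario fixes the true response rates of the current baskets, the
#' basket sample sizes, and the (non-resampled) historical counts.
#'
#' @param p_true Per-basket true response rates in [0, 1].
#' @param n Per-basket sample sizes (recycled from a scalar).
#' @param hist A [historic_data()] object; defaults to no history.
#' @param label Free-form scenario id.
#' @param scenario,sub_case Optional grid coordinates when the scenario is
#'   drawn from [trial_scenarios()].
#' @return An object of class `bbh_scenario`.
#' @export
scenario <- function(p_true, n, hist = no_history(length(p_true)),
                     label = "", scenario = NA, sub_case = NA) {
  stopifnot(all(p_true >= 0), all(p_true <= 1))
  n <- rep_len_chk(n, length(p_true))
  stopifnot(inherits(hist, "historic_data"), hist$K == length(p_true))
  structure(list(p_true = p_true, n = n, hist = hist, label = label,
                 scenario = scenario, sub_case = sub_case),
            class = "bbh_scenario")
}

scenario_rates <- function() {
  matrix(c(0.10, 0.10, 0.10, 0.10, 0.10,
           0.25, 0.10, 0.10, 0.10, 0.10,
           0.25, 0.25, 0.10, 0.10, 0.10,
           0.25, 0.25, 0.25, 0.10, 0.10,
           0.25, 0.25, 0.25, 0.25, 0.10,
           0.25, 0.25, 0.25, 0.25, 0.25,
           0.10, 0.10, 0.10, 0.25, 0.10,
           0.25, 0.10, 0.10, 0.25, 0.10),
         nrow = 8, byrow = TRUE)
}

sub_case_history <- function(sub_case, n_star = 13, K = 5) {
  ys <- switch(sub_case,
               a = c(1, 1, 1), b = c(3, 1, 1), c = c(3, 3, 1),
               d = c(3, 3, 3),
               none = return(no_history(K)),
               stop("unknown sub-case '", sub_case, "'"))
  studies <- replicate(K, list(), simplify = FALSE)
  for (k in seq_along(ys)) studies[[k]] <- list(c(ys[k], n_star))
  historic_data(studies)
}

#' The benchmark simulation scenario grid
#'
#' Eight true-response-rate vectors for five baskets crossed with four
#' historic data sub-cases: three historical baskets of 13 patients whose
#' responder counts are (a) (1,1,1), (b) (3,1,1), (c) (3,3,1), (d) (3,3,3).
#' Scenario 1 is the global null (all rates at `q0 = 0.1`), scenario 6 the
#' global alternative (all at 0.25); the design parameters mirror the
#' MyPathway and VE-BASKET trials (34 patients per current basket, history
#' for the first three baskets).
#'
#' @param sub_case One of `"a"`, `"b"`, `"c"`, `"d"` for the 8 scenarios of
#'   that sub-case, `"none"` for the 8 scenarios without historical data,
#'   or `NULL` (default) for the full 32-scenario grid.
#' @param n_k Current-basket sample size.
#' @param n_star Historical-basket sample size.
#' @return A named list of [scenario()] objects (names like `"2a"`).
#' @examples
#' length(trial_scenarios())        # 32
#' trial_scenarios("c")[["6c"]]
#' @export
trial_scenarios <- function(sub_case = NULL, n_k = 34, n_star = 13) {
  rates <- scenario_rates()
  subs <- if (is.null(sub_case)) c("a", "b", "c", "d") else sub_case
  out <- list()
  for (sc in subs) {
    hist <- sub_case_history(sc, n_star = n_star)
    for (s in seq_len(nrow(rates))) {
      nm <- if (sc == "none") as.character(s) else paste0(s, sc)
      out[[nm]] <- scenario(rates[s, ], n = n_k, hist = hist,
                            label = nm, scenario = s, sub_case = sc)
    }
  }
  out
}

#' Simulate one trial under a scenario
#'
#' Responder counts are drawn independently as
#' `y_k ~ Binomial(n_k, p_true_k)`; the historical counts are fixed by the
#' scenario and passed through unchanged.
#'
#' @param scenario A [scenario()] object.
#' @param seed Optional integer seed.
#' @return A [basket_data()] object.
#' @export
simulate_trial <- function(scenario, seed = NULL) {
  stopifnot(inherits(scenario, "bbh_scenario"))
  if (!is.null(seed)) set.seed(seed)
  basket_data(rbinom(length(scenario$p_true), scenario$n, scenario$p_true),
              scenario$n)
}

#' Derive a replicate seed
#'
#' Integer hash of `(stream, index)` onto `[1, 2^30]`, used to give every
#' simulated replicate an independent, order-invariant seed.
#'
#' @param stream Stream id (e.g. master seed plus scenario position).
#' @param index Replicate index.
#' @return An integer-valued double in `[1, 2^30]`.
#' @export
replicate_seed <- function(stream, index) seed_mix(stream, index)

#' Operating characteristics of a model under a scenario
#'
#' Simulates `n_sims` trials, fits the model to each, applies the decision
#' rule and aggregates: per-basket rejection proportion (type I error where
#' `p_true <= q0`, power otherwise), the family-wise error rate (proportion
#' of replicates rejecting in at least one null basket), and the mean and
#' SD over replicates of the per-basket posterior-mean estimates.
#'
#' @param spec A [model_spec()].
#' @param scenario A [scenario()] object.
#' @param rule A [decision_rule()] (typically from [calibrate()]).
#' @param n_sims Number of replicated trials (>= 1).
#' @param mcmc An [mcmc_config()].
#' @param seed Integer master seed; replicate `r` uses
#'   `replicate_seed(seed, r)`.
#' @return An object of class `bbh_oc`; see [as.data.frame.bbh_oc()] for
#'   the tidy form.
#' @export
operating_characteristics <- function(spec, scenario, rule, n_sims = 1000,
                                      mcmc = mcmc_config(), seed = 1) {
  stopifnot(inherits(spec, "model_spec"), inherits(scenario, "bbh_scenario"),
            inherits(rule, "decision_rule"))
  if (n_sims < 1) stop("'n_sims' must be at least 1")
  q0 <- spec$prior$q0
  K <- length(scenario$p_true)
  delta <- if (length(rule$delta) == 1L) rep(rule$delta, K) else rule$delta
  if (length(delta) != K) stop("rule does not cover the ", K, " baskets")
  fit_mcmc <- mcmc
  fit_mcmc$seed <- NULL
  rej <- matrix(FALSE, n_sims, K)
  est <- matrix(NA_real_, n_sims, K)
  for (r in seq_len(n_sims)) {
    set.seed(seed_mix(seed, r))
    data <- basket_data(rbinom(K, scenario$n, scenario$p_true), scenario$n)
    model <- build_model(spec, data, scenario$hist)
    fit <- fit_basket(model, fit_mcmc)
    prob <- colMeans(fit$draws$p >= q0)
    rej[r, ] <- prob >= delta
    est[r, ] <- colMeans(fit$draws$p)
  }
  nullk <- scenario$p_true <= q0
  structure(list(model_name = spec$model_name, scenario = scenario,
                 q0 = q0, delta = delta,
                 reject_rate = colMeans(rej),
                 fwer = if (any(nullk))
                   mean(apply(rej[, nullk, drop = FALSE], 1, any))
                 else NA_real_,
                 null_basket = nullk,
                 est_mean = colMeans(est),
                 est_sd = apply(est, 2, sd),
                 n_sims = n_sims, seed = seed),
            class = "bbh_oc")
}

#' Tidy operating characteristics
#'
#' @param x A `bbh_oc` object.
#' @param row.names,optional,... Ignored (S3 signature).
#' @return One row per basket with columns `model`, `scenario`, `sub_case`,
#'   `basket`, `true_p`, `reject_rate`, `fwer`, `est_mean`, `est_sd`,
#'   `n_sims`, `seed`.
#' @export
as.data.frame.bbh_oc <- function(x, row.names = NULL, optional = FALSE, ...) {
  K <- length(x$reject_rate)
  data.frame(model = x$model_name, scenario = x$scenario$scenario,
             sub_case = x$scenario$sub_case,
             basket = seq_len(K), true_p = x$scenario$p_true,
             reject_rate = x$reject_rate, fwer = x$fwer,
             est_mean = x$est_mean, est_sd = x$est_sd,
             n_sims = x$n_sims, seed = x$seed,
             stringsAsFactors = FALSE)
}

#' @export
print.bbh_oc <- function(x, ...) {
  cat("Operating characteristics:", x$model_name, "model, scenario",
      x$scenario$label, "(", x$n_sims, "sims )\n")
  df <- as.data.frame(x)
  df$type <- ifelse(x$null_basket, "type I error", "power")
  print(df[, c("basket", "true_p", "type", "reject_rate", "est_mean",
               "est_sd")], digits = 3, row.names = FALSE)
  cat("FWER:", round(x$fwer, 4), "\n")
  invisible(x)
}

#' Sensitivity analysis over model hyperparameter grids
#'
#' For every grid point (a named list of [model_spec()] field overrides,
#' e.g. `list(alpha = 0.25)` or `list(pi_lambda = 0.25, pi_all = 0.75,
#' pi_curr = 0.75)`) and every historic sub-case, recalibrates the decision
#' cutoffs over the scenario set and recomputes rejection rates, then
#' summarizes the maximum type I error and mean power across scenarios by
#' basket group (baskets sharing history status and historical responder
#' count).  Rejection rates are computed on the calibration replicates,
#' whose posterior probabilities the calibrated rule thresholds directly.
#'
#' When `rule` is supplied, calibration is skipped and fresh operating
#' characteristics are computed per scenario with
#' `operating_characteristics(..., seed = seed + s)` where `s` is the
#' scenario position.
#'
#' @param spec Base [model_spec()].
#' @param grid Non-empty list of override lists.
#' @param sub_cases Historic sub-cases to cover.
#' @param n_sims Simulated trials per scenario.
#' @param mcmc An [mcmc_config()].
#' @param seed Master seed.
#' @param target Calibration target (average basket-wise type I error).
#' @param scenarios Optional scenario subset (defaults to the 8-scenario
#'   grid of each sub-case).
#' @param rule Optional fixed [decision_rule()] (skips calibration).
#' @return A data frame with one row per (grid point, sub-case, basket
#'   group): `max_type1` and `mean_power` in percent.
#' @export
sensitivity_grid <- function(spec, grid, sub_cases = c("a", "b", "c", "d"),
                             n_sims = 1000, mcmc = mcmc_config(), seed = 1,
                             target = 0.1, scenarios = NULL, rule = NULL) {
  if (!is.list(grid) || length(grid) == 0L) stop("'grid' must be non-empty")
  q0 <- spec$prior$q0
  rows <- list()
  for (gi in seq_along(grid)) {
    gspec <- spec
    for (nm in names(grid[[gi]])) {
      if (!nm %in% names(gspec)) stop("unknown model_spec field '", nm, "'")
      gspec[[nm]] <- grid[[gi]][[nm]]
    }
    glab <- paste(names(grid[[gi]]), unlist(grid[[gi]]), sep = "=",
                  collapse = ",")
    for (sc in sub_cases) {
      scen <- if (is.null(scenarios)) trial_scenarios(sc) else scenarios
      if (is.null(rule)) {
        cs <- calibration_spec(scen, target = target, n_sims = n_sims)
        crule <- calibrate(gspec, cs, mcmc, seed = seed)
        probs <- attr(crule, "probs")
        rej <- lapply(seq_along(scen), function(s) {
          sweep(probs[[s]], 2, crule$delta, `>=`)
        })
      } else {
        crule <- rule
        rej <- lapply(seq_along(scen), function(s) {
          oc <- operating_characteristics(gspec, scen[[s]], rule,
                                          n_sims = n_sims, mcmc = mcmc,
                                          seed = seed + s)
          matrix(rep(oc$reject_rate, each = 1), nrow = 1)
        })
      }
      K <- length(scen[[1]]$p_true)
      hist <- scen[[1]]$hist
      ystar <- vapply(seq_len(K), function(k) {
        if (hist$H[k] > 0) sum(vapply(hist$studies[[k]], `[`, numeric(1), 1))
        else NA_real_
      }, numeric(1))
      bgroup <- ifelse(is.na(ystar), "no_history", paste0("ystar_", ystar))
      for (bg in unique(bgroup)) {
        ks <- which(bgroup == bg)
        t1 <- pow <- numeric(0)
        for (s in seq_along(scen)) {
          rr <- colMeans(rej[[s]][, ks, drop = FALSE])
          isnull <- scen[[s]]$p_true[ks] <= q0
          t1 <- c(t1, rr[isnull])
          pow <- c(pow, rr[!isnull])
        }
        rows[[length(rows) + 1]] <- data.frame(
          grid_point = glab, sub_case = sc, baskets = paste(ks, collapse = ","),
          group = bg,
          max_type1 = if (length(t1)) 100 * max(t1) else NA_real_,
          mean_power = if (length(pow)) 100 * mean(pow) else NA_real_,
          n_sims = n_sims, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' BELIEVE/ROAR thyroid example data
#'
#' The published counts of the BELIEVE trial re-analysis with historical
#' information from the ROAR trial: the thyroid cancer basket observed 5
#' responders out of 15 patients in BELIEVE with 20 of 36 responding in the
#' ROAR thyroid basket, and one basket enrolled a single responding
#' patient.  Per-basket counts of the remaining 13 of the 15 BELIEVE
#' baskets were not published; they are included as zero-size placeholders
#' with `available = FALSE`.
#'
#' @return A list with `data` ([basket_data()]), `hist` ([historic_data()])
#'   and the logical vector `available`.
#' @examples
#' fx <- believe_roar_data()
#' sum(!fx$available)  # baskets without published counts
#' @export
believe_roar_data <- function() {
  K <- 15
  y <- c(5, rep(0, K - 1))
  n <- c(15, rep(0, K - 1))
  y[8] <- 1; n[8] <- 1
  labels <- c("thyroid", paste0("basket_", 2:K))
  available <- n > 0
  studies <- replicate(K, list(), simplify = FALSE)
  studies[[1]] <- list(c(20, 36))
  list(data = basket_data(y, n, labels),
       hist = historic_data(studies),
       available = available)
}
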