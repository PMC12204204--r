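#' Efficacy decision rule
#'
#' @param q0 Null response rate.
#' @param delta Per-basket posterior-probability cutoffs `Delta_k` in
#'   `[0, 1]` (a scalar is shared by all baskets).  Basket `k` is declared
#'   effective when `P(p_k >= q0 | data) >= Delta_k`; the comparison is
#'   non-strict by convention.
#' @return An object of class `decision_rule`.
#' @export
decision_rule <- function(q0, delta) {
  if (any(delta < 0) || any(delta > 1)) stop("'delta' must lie in [0, 1]")
  stopifnot(q0 > 0, q0 < 1)
  structure(list(q0 = q0, delta = as.numeric(delta)), class = "decision_rule")
}

#' @export
print.decision_rule <- function(x, ...) {
  cat("Efficacy rule: P(p_k >=", x$q0, ") >= Delta_k with Delta =",
      paste(round(x$delta, 4), collapse = ", "), "\n")
  ach <- attr(x, "achieved")
  if (!is.null(ach))
    cat("  calibrated average null rejection:",
        paste(round(ach, 4), collapse = ", "), "\n")
  invisible(x)
}

#' Apply the efficacy decision rule
#'
#' @param summary A [posterior_summary()] data frame (needs column
#'   `prob_effective`).
#' @param rule A [decision_rule()].
#' @return Logical vector of per-basket efficacy flags.
#' @examples
#' s <- data.frame(basket = c("a", "b"), prob_effective = c(0.99, 0.5))
#' decide(s, decision_rule(0.1, 0.9))
#' @export
decide <- function(summary, rule) {
  stopifnot(inherits(rule, "decision_rule"))
  if (!is.data.frame(summary) || is.null(summary$prob_effective) ||
      any(is.na(summary$prob_effective)))
    stop("summary must provide prob_effective for every basket")
  K <- nrow(summary)
  delta <- if (length(rule$delta) == 1L) rep(rule$delta, K) else rule$delta
  if (length(delta) != K)
    stop("rule has ", length(rule$delta), " cutoffs but summary has ",
         K, " baskets")
  setNames(summary$prob_effective >= delta, summary$basket)
}

#' Calibration specification
#'
#' @param scenarios List of scenarios (see [trial_scenarios()]) over which
#'   the average basket-wise type I error is controlled.  At least one
#'   scenario must contain a null basket (`p_true <= q0`).
#' @param target Target average basket-wise type I error rate in (0, 1).
#' @param n_sims Simulated trials per scenario.
#' @param grouping How baskets share a cutoff: `"history"` (one cutoff for
#'   baskets with historical data, one for those without — the default),
#'   `"per_basket"`, or `"common"`.
#' @return An object of class `calibration_spec`.
#' @export
calibration_spec <- function(scenarios, target = 0.1, n_sims = 1000,
                             grouping = c("history", "per_basket", "common")) {
  grouping <- match.arg(grouping)
  stopifnot(target > 0, target < 1, n_sims >= 1, length(scenarios) >= 1)
  structure(list(scenarios = scenarios, target = target,
                 n_sims = as.integer(n_sims), grouping = grouping),
            class = "calibration_spec")
}

cutoff_groups <- function(K, K_star, grouping) {
  switch(grouping,
         per_basket = seq_len(K),
         common = rep(1L, K),
         history = if (K_star == 0L || K_star == K) rep(1L, K)
                   else ifelse(seq_len(K) <= K_star, 1L, 2L))
}

#' Calibrate efficacy cutoffs to an average type I error target
#'
#' Simulates replicated trials under every calibration scenario and records
#' each null basket's posterior efficacy probability.  Within each cutoff
#' group, the average basket-wise type I error is defined with every
#' scenario weighted equally (within a scenario, its null baskets share the
#' scenario's weight), so a scenario with a single null basket counts as
#' much as the global null; the returned cutoff is the pooled-probability
#' value whose weighted average rejection rate is closest to the target
#' from below (ties resolved toward the target).  Because the cutoff only
#' thresholds stored probabilities, the cost is one model fit per simulated
#' trial.
#'
#' Replicate seeds are derived from `(seed + scenario position, replicate)`
#' by an integer hash, so results are invariant to the order scenarios are
#' processed and replicates are independent of `n_sims`.
#'
#' @param spec A [model_spec()].
#' @param cal A [calibration_spec()].
#' @param mcmc An [mcmc_config()] used for every fit (its seed is ignored;
#'   replicate seeds are derived from `seed`).
#' @param seed Integer master seed.
#' @return A [decision_rule()] carrying diagnostic attributes: `groups`,
#'   `achieved` (per-group average null rejection at the cutoff), `n_pooled`,
#'   `probs` (per-scenario matrices of posterior efficacy probabilities),
#'   `model_name`, `n_sims` and `seed`.
#' @export
calibrate <- function(spec, cal, mcmc = mcmc_config(), seed = 1) {
  stopifnot(inherits(spec, "model_spec"), inherits(cal, "calibration_spec"))
  q0 <- spec$prior$q0
  scen <- cal$scenarios
  probs <- vector("list", length(scen))
  for (s in seq_along(scen)) {
    # stream keyed to the scenario's grid id where it has one, so results
    # do not depend on the order scenarios are listed
    sid <- if (!is.na(scen[[s]]$scenario)) scen[[s]]$scenario else s
    probs[[s]] <- scenario_probs(spec, scen[[s]], cal$n_sims, mcmc,
                                 stream = seed + sid)
  }
  K <- length(scen[[1]]$p_true)
  K_star <- scen[[1]]$hist$K_star
  groups <- cutoff_groups(K, K_star, cal$grouping)
  delta <- numeric(K)
  achieved <- n_pooled <- numeric(max(groups))
  for (g in sort(unique(groups))) {
    pool <- wts <- numeric(0)
    n_scen_g <- sum(vapply(scen, function(s)
      any(s$p_true <= q0 & groups == g), logical(1)))
    for (s in seq_along(scen)) {
      nullk <- which(scen[[s]]$p_true <= q0 & groups == g)
      if (length(nullk)) {
        v <- as.vector(probs[[s]][, nullk])
        pool <- c(pool, v)
        wts <- c(wts, rep(1 / (n_scen_g * length(v)), length(v)))
      }
    }
    if (!length(pool))
      stop("no null baskets in any calibration scenario for group ", g)
    cut <- calibrate_cutoff(pool, wts, cal$target)
    delta[groups == g] <- cut$delta
    achieved[g] <- cut$achieved
    n_pooled[g] <- length(pool)
  }
  rule <- decision_rule(q0, delta)
  attr(rule, "groups") <- groups
  attr(rule, "achieved") <- achieved
  attr(rule, "n_pooled") <- n_pooled
  attr(rule, "probs") <- probs
  attr(rule, "model_name") <- spec$model_name
  attr(rule, "n_sims") <- cal$n_sims
  attr(rule, "seed") <- seed
  rule
}

# Weighted empirical cutoff: the smallest observed probability value whose
# weighted rejection rate (mass at or above it) does not exceed the target,
# nudged one step when the next value is strictly closer to the target.
calibrate_cutoff <- function(pool, wts, target) {
  if (max(pool) - min(pool) < .Machine$double.eps)
    stop("pooled null probabilities are all identical (",
         signif(pool[1], 4), "); the target ", target, " is unattainable")
  ord <- order(pool, decreasing = TRUE)
  cw <- cumsum(wts[ord])
  i <- findInterval(target, c(0, cw)) - 1L # largest i with cw[i] <= target
  if (i < 1L) i <- 1L
  else if (i < length(cw) && abs(cw[i + 1] - target) < abs(cw[i] - target))
    i <- i + 1L
  list(delta = pool[ord][i], achieved = cw[i])
}

# Posterior efficacy probabilities over replicated trials of one scenario.
# Returns an n_sims x K matrix; replicate r uses seed seed_mix(stream, r).
scenario_probs <- function(spec, scenario, n_sims, mcmc, stream) {
  K <- length(scenario$p_true)
  P <- matrix(NA_real_, n_sims, K)
  fit_mcmc <- mcmc
  fit_mcmc$seed <- NULL
  for (r in seq_len(n_sims)) {
    set.seed(seed_mix(stream, r))
    data <- basket_data(rbinom(K, scenario$n, scenario$p_true), scenario$n)
    model <- build_model(spec, data, scenario$hist)
    fit <- fit_basket(model, fit_mcmc)
    P[r, ] <- colMeans(fit$draws$p >= spec$prior$q0)
  }
  P
}

#' Serialize a calibration result to JSON
#'
#' @param rule A calibrated [decision_rule()].
#' @param sub_case Optional historic sub-case label to record.
#' @param path Optional output path; when `NULL` the JSON string is
#'   returned.
#' @return The JSON string, invisibly when written to `path`.
#' @export
calibration_json <- function(rule, sub_case = NULL, path = NULL) {
  out <- list(model = attr(rule, "model_name"), sub_case = sub_case,
              grouping = attr(rule, "groups"), q0 = rule$q0,
              delta = rule$delta, achieved = attr(rule, "achieved"),
              n_sims = attr(rule, "n_sims"), seed = attr(rule, "seed"))
  js <- jsonlite::toJSON(out, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
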