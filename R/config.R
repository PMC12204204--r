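#' Parse a run configuration
#'
#' Reads a YAML or JSON document describing a reproducible run: which
#' command to execute, the model and its hyperparameters, the data (file
#' paths, an inline scenario, or a grid scenario id like `"2a"`), the MCMC
#' and calibration settings, the output directory and the master seed.
#' Unknown keys are rejected so misspelled hyperparameters cannot be
#' silently ignored.  All documented defaults are filled in, and the fully
#' resolved configuration is echoed into the output directory by
#' [run_trial_config()].
#'
#' @param path Path to a YAML or JSON file (YAML is a superset, so both
#'   parse through the YAML reader; `.json` files go through jsonlite).
#' @param text Alternatively, the document as a string.
#' @return An object of class `run_config`.
#' @export
parse_run_config <- function(path = NULL, text = NULL) {
  if (is.null(path) == is.null(text))
    stop("supply exactly one of 'path' or 'text'")
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
      jsonlite::fromJSON(path, simplifyVector = TRUE)
    else yaml::read_yaml(path)
  } else {
    raw <- tryCatch(jsonlite::fromJSON(text, simplifyVector = TRUE),
                    error = function(e) yaml::yaml.load(text))
  }
  if (!is.list(raw)) stop("configuration must be a mapping")
  check_keys(raw, c("command", "model", "data", "historic", "scenario",
                    "prior", "mcmc", "calibration", "delta", "out_dir",
                    "seed", "n_sims"), "top level")
  command <- raw$command
  if (is.null(command) ||
      !command %in% c("fit", "calibrate", "oc", "sensitivity", "fixtures"))
    stop("'command' must be one of fit, calibrate, oc, sensitivity, fixtures")
  if (!is.null(raw$seed) && raw$seed != as.integer(raw$seed))
    stop("'seed' must be an integer")

  pr_raw <- raw$prior
  if (!is.null(pr_raw))
    check_keys(pr_raw, c("q0", "q1", "m_mu", "nu_mu", "sigma_prior_scale",
                         "sigma_prior_scale_curr", "rho", "a", "b", "pi"),
               "prior")
  prior <- do.call(prior_config, if (is.null(pr_raw)) list() else pr_raw)

  md <- raw$model
  if (is.character(md)) md <- list(name = md)
  if (is.null(md) && command != "fixtures") stop("'model' is required")
  spec <- NULL
  if (!is.null(md)) {
    check_keys(md, c("name", "alpha", "zeta", "pi_lambda", "pi_all",
                     "pi_curr", "coupling"), "model")
    if (is.null(md$name)) stop("'model' needs a 'name'")
    args <- md[setdiff(names(md), "name")]
    spec <- do.call(model_spec,
                    c(list(model_name = md$name, prior = prior), args))
  }

  mc_raw <- raw$mcmc
  if (!is.null(mc_raw))
    check_keys(mc_raw, c("n_iter", "n_burn", "thin", "seed", "proposal_sd",
                         "adapt"), "mcmc")
  mcmc <- do.call(mcmc_config, if (is.null(mc_raw)) list() else mc_raw)

  cal_raw <- raw$calibration
  if (!is.null(cal_raw))
    check_keys(cal_raw, c("target", "n_sims", "grouping", "sub_case"),
               "calibration")

  if (!is.null(raw$scenario) && !is.character(raw$scenario) &&
      !is.list(raw$scenario))
    stop("'scenario' must be a grid id like \"2a\" or a mapping")
  if (is.list(raw$scenario))
    check_keys(raw$scenario, c("p_true", "n", "sub_case"), "scenario")
  if (!is.null(raw$data) && !is.null(raw$data$path) &&
      !file.exists(raw$data$path))
    stop("data file not found: ", raw$data$path)

  structure(list(command = command, spec = spec, prior = prior, mcmc = mcmc,
                 data = raw$data, historic = raw$historic,
                 scenario = raw$scenario, calibration = cal_raw,
                 delta = raw$delta,
                 out_dir = if (is.null(raw$out_dir)) "." else raw$out_dir,
                 seed = if (is.null(raw$seed)) 1L else as.integer(raw$seed),
                 n_sims = if (is.null(raw$n_sims)) 1000L
                          else as.integer(raw$n_sims)),
            class = "run_config")
}

check_keys <- function(x, allowed, where) {
  if (is.null(names(x)) && length(x)) stop(where, " must be a mapping")
  bad <- setdiff(names(x), allowed)
  if (length(bad))
    stop("unknown key(s) in ", where, ": ", paste(bad, collapse = ", "))
  invisible(TRUE)
}

resolve_scenario <- function(config) {
  sc <- config$scenario
  if (is.null(sc)) stop("this command needs a 'scenario'")
  if (is.character(sc)) {
    all <- c(trial_scenarios(), trial_scenarios("none"))
    if (!sc %in% names(all))
      stop("unknown scenario id '", sc, "'; use e.g. \"2a\" or \"2\"")
    return(all[[sc]])
  }
  hist <- if (is.null(sc$sub_case)) no_history(length(sc$p_true))
          else sub_case_history(sc$sub_case)
  scenario(sc$p_true, if (is.null(sc$n)) 34 else sc$n, hist,
           label = "inline")
}

resolve_data <- function(config) {
  if (!is.null(config$data) && !is.null(config$data$path)) {
    data <- read_basket_data(config$data$path)
    hist <- if (!is.null(config$historic) && !is.null(config$historic$path))
      read_historic_csv(config$historic$path, data)
    else replicate(data$K, list(), simplify = FALSE)
    ro <- reorder_history(data, hist)
    return(list(data = ro$data, hist = ro$hist, perm = ro$perm))
  }
  sc <- resolve_scenario(config)
  list(data = simulate_trial(sc, seed = config$seed), hist = sc$hist,
       perm = seq_along(sc$p_true))
}

#' Execute a run configuration
#'
#' Dispatches on `config$command`, writes the result files (CSV/JSON), the
#' fully resolved configuration and a log with the seeds used into
#' `config$out_dir`, and returns the result invisibly.  Identical
#' configuration and seed give byte-identical result files.
#'
#' @param config A [parse_run_config()] result.
#' @return The command's result object, invisibly.
#' @export
run_trial_config <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)
  log <- c(paste("basketbh", as.character(utils::packageVersion("basketbh"))),
           paste("command:", config$command),
           paste("seed:", config$seed))
  res <- switch(config$command,
    fit = {
      dd <- resolve_data(config)
      model <- build_model(config$spec, dd$data, dd$hist)
      mc <- config$mcmc
      if (is.null(mc$seed)) mc$seed <- config$seed
      fit <- fit_basket(model, mc)
      summ <- posterior_summary(fit)
      write.csv(summ, out("summary.csv"), row.names = FALSE)
      write_draws(fit, out("draws.csv"))
      jsonlite::write_json(summ, out("summary.json"), dataframe = "rows",
                           auto_unbox = TRUE, digits = NA)
      fit
    },
    calibrate = {
      cal <- resolved_calibration(config)
      rule <- calibrate(config$spec, cal, config$mcmc, seed = config$seed)
      calibration_json(rule, sub_case = cal$scenarios[[1]]$sub_case,
                       path = out("calibration.json"))
      rule
    },
    oc = {
      sc <- resolve_scenario(config)
      rule <- if (!is.null(config$delta))
        decision_rule(config$prior$q0, config$delta)
      else calibrate(config$spec, resolved_calibration(config), config$mcmc,
                     seed = config$seed)
      oc <- operating_characteristics(config$spec, sc, rule,
                                      n_sims = config$n_sims,
                                      mcmc = config$mcmc,
                                      seed = config$seed)
      write.csv(as.data.frame(oc), out("oc.csv"), row.names = FALSE)
      oc
    },
    sensitivity = {
      grid <- list(list(alpha = config$spec$alpha))
      tab <- sensitivity_grid(config$spec, grid, n_sims = config$n_sims,
                              mcmc = config$mcmc, seed = config$seed)
      write.csv(tab, out("sensitivity.csv"), row.names = FALSE)
      tab
    },
    fixtures = {
      scen <- trial_scenarios()
      rows <- do.call(rbind, lapply(names(scen), function(nm) {
        s <- scen[[nm]]
        data.frame(id = nm, scenario = s$scenario, sub_case = s$sub_case,
                   basket = seq_along(s$p_true), p_true = s$p_true,
                   n = s$n)
      }))
      write.csv(rows, out("scenarios.csv"), row.names = FALSE)
      fx <- believe_roar_data()
      write.csv(data.frame(basket_id = fx$data$labels, y = fx$data$y,
                           n = fx$data$n, available = fx$available),
                out("believe.csv"), row.names = FALSE)
      write.csv(data.frame(basket_id = "thyroid", study_id = "ROAR",
                           y_star = 20, n_star = 36),
                out("roar_historic.csv"), row.names = FALSE)
      invisible(NULL)
    })
  cfg <- config
  cfg$spec <- NULL
  jsonlite::write_json(
    list(command = config$command,
         model = if (!is.null(config$spec)) config$spec$model_name,
         seed = config$seed, n_sims = config$n_sims,
         mcmc = unclass(config$mcmc),
         out_dir = config$out_dir),
    out("resolved_config.json"), auto_unbox = TRUE, digits = NA,
    null = "null")
  writeLines(log, out("run.log"))
  invisible(res)
}

resolved_calibration <- function(config) {
  cal <- config$calibration
  sub_case <- if (!is.null(cal$sub_case)) cal$sub_case
              else if (is.character(config$scenario) &&
                       grepl("[a-d]$", config$scenario))
                substring(config$scenario, nchar(config$scenario))
              else "none"
  calibration_spec(
    trial_scenarios(sub_case),
    target = if (is.null(cal$target)) 0.1 else cal$target,
    n_sims = if (is.null(cal$n_sims)) config$n_sims else cal$n_sims,
    grouping = if (is.null(cal$grouping)) "history" else cal$grouping)
}

#' Command-line entry point
#'
#' Thin wrapper used by the `inst/cli/basketbh.R` script: parses
#' `--config`, `--seed`, `--out`, `--n-sims` and `--mcmc-iter` flags
#' (flags override config keys), runs the configuration, and returns an
#' exit status.
#'
#' @param args Character vector of command-line arguments.
#' @return Integer exit status (0 on success).
#' @export
run_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  get_flag <- function(flag) {
    i <- which(args == flag)
    if (length(i) == 1 && i < length(args)) args[i + 1] else NULL
  }
  path <- get_flag("--config")
  if (is.null(path)) {
    message("usage: basketbh.R --config FILE [--seed N] [--out DIR] ",
            "[--n-sims N] [--mcmc-iter N]")
    return(2L)
  }
  status <- tryCatch({
    config <- parse_run_config(path)
    if (!is.null(get_flag("--seed")))
      config$seed <- as.integer(get_flag("--seed"))
    if (!is.null(get_flag("--out"))) config$out_dir <- get_flag("--out")
    if (!is.null(get_flag("--n-sims")))
      config$n_sims <- as.integer(get_flag("--n-sims"))
    if (!is.null(get_flag("--mcmc-iter"))) {
      it <- as.integer(get_flag("--mcmc-iter"))
      config$mcmc <- mcmc_config(n_iter = it, n_burn = it %/% 5,
                                 thin = config$mcmc$thin,
                                 proposal_sd = config$mcmc$proposal_sd,
                                 adapt = config$mcmc$adapt)
    }
    run_trial_config(config)
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  status
}
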