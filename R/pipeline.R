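#' Flat key-value run configuration
#'
#' The pipeline stages share a flat text configuration format: one
#' `key = value` pair per line, `#` comments allowed. Unknown keys are
#' rejected so typos fail loudly. All settings have defaults; an empty or
#' absent config runs the study-emulation defaults.
#'
#' Recognised keys (with defaults): `n_participants` (50),
#' `generative_model` (spillover), `food_shift` (2.4), `out_shift` (0.6),
#' `cauchy_scale` (0.5), `choice_alpha` (2), `choice_epsilon` (0.01),
#' `chains` (4), `iter` (1000), `warmup` (500), `n_bic` (participants),
#' `n_boot` (2000), `n_particles` (500), `trials_per_session` (35),
#' `seed` (1).
#'
#' @param path Path to a config file, or `NULL` for all defaults.
#' @param overrides Named list overriding file values.
#' @return Named list of settings, class `dd_run_config`.
#' @export
read_run_config <- function(path = NULL, overrides = list()) {
  defaults <- list(n_participants = 50, generative_model = "spillover",
                   food_shift = 2.4, out_shift = 0.6, cauchy_scale = 0.5,
                   choice_alpha = 2, choice_epsilon = 0.01,
                   chains = 4, iter = 1000, warmup = 500, n_bic = NA,
                   n_boot = 2000, n_particles = 500,
                   trials_per_session = 35, seed = 1)
  cfg <- defaults
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    lines <- readLines(path, warn = FALSE)
    lines <- sub("#.*$", "", lines)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines)]
    for (ln in lines) {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
      if (length(kv) != 2L) stop("malformed config line: ", ln)
      key <- trimws(kv[1]); val <- trimws(kv[2])
      if (!key %in% names(defaults)) stop("unknown config key: ", key)
      cfg[[key]] <- if (key == "generative_model") val else as.numeric(val)
    }
  }
  for (key in names(overrides)) {
    if (!key %in% names(defaults)) stop("unknown config key: ", key)
    cfg[[key]] <- overrides[[key]]
  }
  structure(cfg, class = c("dd_run_config", "list"))
}

run_config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(paste(names(cfg), vapply(cfg, function(v)
    paste(format(v), collapse = ","), character(1)), sep = "="), tmp)
  unname(tools::md5sum(tmp))
}

run_meta <- function(cfg, extra = NULL) {
  c(package = paste("ddspill", as.character(utils::packageVersion("ddspill"))),
    seed = format(cfg$seed), config_hash = run_config_hash(cfg), extra)
}

as_population_config <- function(cfg) {
  gp <- if (cfg$generative_model == "spillover") {
    c(food_shift = cfg$food_shift, out_shift = cfg$out_shift)
  } else if (cfg$generative_model == "trait_only") numeric(0) else {
    model <- hypothesis_model(cfg$generative_model)
    stats::setNames(rep(cfg$food_shift, length(model$par_names)),
                    model$par_names)
  }
  population_config(n_participants = cfg$n_participants,
                    generative_model = cfg$generative_model,
                    generative_params = gp,
                    cauchy_scale = cfg$cauchy_scale,
                    choice_alpha = cfg$choice_alpha,
                    choice_epsilon = cfg$choice_epsilon,
                    rng_seed = cfg$seed)
}

#' Pipeline stage: simulate a synthetic study to disk
#'
#' Runs [simulate_study()] under the configuration and writes the trial
#' table and ground truth as CSV (with `#` metadata headers recording the
#' package version, seed and a config hash).
#'
#' @param out_dir Output directory (created if needed).
#' @param config A [read_run_config()] result, or `NULL` for defaults.
#' @param quiet Suppress progress messages.
#' @return Invisibly, paths of the written files.
#' @export
run_simulate <- function(out_dir, config = NULL, quiet = FALSE) {
  cfg <- if (is.null(config)) read_run_config() else config
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!quiet) message("simulating ", cfg$n_participants,
                      " participants x 2 conditions x 3 commodities")
  sim <- simulate_study(as_population_config(cfg),
                        n_particles = cfg$n_particles)
  meta <- run_meta(cfg)
  trial_path <- file.path(out_dir, "trials.csv")
  truth_path <- file.path(out_dir, "ground_truth.csv")
  write_trials(sim$trials, trial_path, meta)
  write_ground_truth(sim$truth, truth_path)
  if (!quiet) message("wrote ", trial_path, " and ", truth_path)
  invisible(c(trials = trial_path, ground_truth = truth_path))
}

#' Pipeline stage: fit every session of a trial table
#'
#' Fits the per-session posterior for each participant x condition x
#' commodity combination separately and independently, and summarises each
#' fit: posterior median and SD of log(k), medians of acuity and lapse,
#' the predictive AUC-ROC, and the worst split-chain Rhat. Sessions whose
#' sampler fails the convergence check are flagged in the `converged`
#' column, never dropped.
#'
#' @param trials Trial table (data frame or CSV path).
#' @param config A [read_run_config()] or `NULL`.
#' @param priors A [prior_spec()].
#' @param out Optional CSV path for the summary.
#' @param quiet Suppress per-session progress.
#' @return Data frame with one row per session: `participant`,
#'   `condition`, `commodity`, `logk_median`, `logk_sd`, `alpha_median`,
#'   `epsilon_median`, `auc_roc`, `rhat_max`, `converged`.
#' @export
run_fit <- function(trials, config = NULL, priors = prior_spec(),
                    out = NULL, quiet = FALSE) {
  cfg <- if (is.null(config)) read_run_config() else config
  if (is.character(trials)) trials <- read_trials(trials)
  validate_trials(trials)
  keys <- unique(trials[c("participant", "condition", "commodity")])
  keys <- keys[order(keys$participant, keys$condition, keys$commodity), ]
  rows <- vector("list", nrow(keys))
  for (i in seq_len(nrow(keys))) {
    sess <- trials[trials$participant == keys$participant[i] &
                     trials$condition == keys$condition[i] &
                     trials$commodity == keys$commodity[i], ]
    seed <- session_seed(cfg$seed, match(keys$participant[i],
                                         unique(trials$participant)),
                         keys$commodity[i], keys$condition[i])
    post <- fit_posterior(sess, priors, rng_seed = seed,
                          chains = cfg$chains, iter = cfg$iter,
                          warmup = cfg$warmup)
    probs <- posterior_predictive_probs(post, sess)
    auc <- suppressWarnings(auc_roc(probs, sess$R))
    rows[[i]] <- data.frame(
      participant = keys$participant[i], condition = keys$condition[i],
      commodity = keys$commodity[i],
      logk_median = post$point_log_k,
      logk_sd = stats::sd(post$draws$log_k),
      alpha_median = stats::median(post$draws$alpha),
      epsilon_median = stats::median(post$draws$epsilon),
      auc_roc = auc,
      rhat_max = max(post$diagnostics$rhat),
      converged = post$diagnostics$converged)
    if (!quiet && i %% 20L == 0L) {
      message("fitted ", i, "/", nrow(keys), " sessions")
    }
  }
  summary <- do.call(rbind, rows)
  if (!is.null(out)) write_csv_with_meta(summary, out, run_meta(cfg))
  summary
}

#' Per-participant changes in log(k) from session summaries
#'
#' @param summaries Output of [run_fit()].
#' @return Long delta table: fasted minus control posterior median log(k)
#'   per participant and commodity.
#' @export
delta_from_summaries <- function(summaries) {
  ctrl <- summaries[summaries$condition == "control", ]
  fast <- summaries[summaries$condition == "fasted", ]
  key <- function(d) paste(d$participant, d$commodity)
  fast <- fast[match(key(ctrl), key(fast)), ]
  if (any(is.na(fast$logk_median))) {
    stop("every control session needs a matching fasted session")
  }
  data.frame(participant = ctrl$participant, commodity = ctrl$commodity,
             delta_logk = fast$logk_median - ctrl$logk_median)
}

#' Pipeline stage: six-model comparison report
#'
#' Runs [compare_all()] on a delta table and augments it with the
#' descriptive statistics of the analysis: the spillover ratio and a
#' bootstrap confidence interval of the mean change per commodity.
#'
#' @param deltas Long delta table (data frame or CSV path).
#' @param config A [read_run_config()] or `NULL`.
#' @param out Optional CSV path for the Table-style report.
#' @return List with `comparison` (the [compare_all()] table),
#'   `spillover_ratio_pct`, and `commodity_ci` (mean change and bootstrap
#'   CI per commodity).
#' @export
run_compare <- function(deltas, config = NULL, out = NULL) {
  cfg <- if (is.null(config)) read_run_config() else config
  if (is.character(deltas)) deltas <- read_delta_table(deltas)
  m <- as_delta_matrix(deltas)
  n_bic <- if (is.na(cfg$n_bic)) nrow(m) else cfg$n_bic
  comp <- compare_all(deltas, n_bic = n_bic, rng_seed = cfg$seed)
  ci <- do.call(rbind, lapply(COMMODITIES, function(cc) {
    b <- bootstrap_mean_ci(m[, cc], n_boot = cfg$n_boot,
                           rng_seed = cfg$seed + match(cc, COMMODITIES))
    data.frame(commodity = cc, mean_delta = mean(m[, cc]),
               ci_low = b["low"], ci_high = b["high"], row.names = NULL)
  }))
  ratio <- spillover_ratio(deltas)
  if (!is.null(out)) {
    rep_df <- data.frame(model = comp$model, n = comp$n,
                         LL = round(comp$LL, 2), dAIC = round(comp$dAIC, 2),
                         wAIC = round(comp$wAIC, 4),
                         dBIC = round(comp$dBIC, 2),
                         wBIC = round(comp$wBIC, 4))
    write_csv_with_meta(rep_df, out, run_meta(cfg, c(
      spillover_ratio_pct = sprintf("%.2f", ratio))))
  }
  list(comparison = comp, spillover_ratio_pct = ratio, commodity_ci = ci)
}

#' Headline descriptive statistics of a fitted study
#'
#' From per-session posterior summaries: the median discount half-life per
#' condition and commodity (half-life of the median rate), the paired
#' Cohen's d of the control-to-fasted change in log(k) per commodity, the
#' median predictive AUC-ROC across sessions, and the spillover ratio.
#'
#' @param summaries Output of [run_fit()].
#' @return List with `half_life_days` (2 x 3 matrix), `effect_sizes`
#'   (named per commodity), `median_auc_roc`, `spillover_ratio_pct`.
#' @export
study_report <- function(summaries) {
  hl <- sapply(COMMODITIES, function(cc) {
    vapply(CONDITIONS, function(cond) {
      lk <- summaries$logk_median[summaries$commodity == cc &
                                    summaries$condition == cond]
      half_life(exp(stats::median(lk)))
    }, numeric(1))
  })
  es <- vapply(COMMODITIES, function(cc) {
    s <- summaries[summaries$commodity == cc, ]
    ctrl <- s[s$condition == "control", ]
    fast <- s[s$condition == "fasted", ]
    fast <- fast[match(ctrl$participant, fast$participant), ]
    paired_cohens_d(ctrl$logk_median, fast$logk_median)
  }, numeric(1))
  deltas <- delta_from_summaries(summaries)
  list(half_life_days = hl,
       effect_sizes = es,
       median_auc_roc = stats::median(summaries$auc_roc, na.rm = TRUE),
       spillover_ratio_pct = spillover_ratio(deltas))
}
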