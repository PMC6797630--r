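#' Configuration of a synthetic study population
#'
#' Describes the generative settings of a simulated repeated-measures study
#' (2 conditions x 3 commodities): population size, baseline discount
#' rates, the generative hypothesis model for condition effects, and the
#' choice-model parameters of the simulated participants.
#'
#' Defaults emulate the motivating study's conditions: 50 participants,
#' baseline log(k) centred on a 50-day half-life (`log(1/50)`, SD 1.0)
#' with correlation 0.5 across commodities, condition effects generated
#' under the spillover model with an in-domain change of 2.4 log-units and
#' an out-of-domain change of 0.6 (a 25% spillover), Cauchy scatter of
#' scale 0.5 across participants, and attentive responders
#' (`alpha = 2` commodity units, lapse `epsilon = 0.01`).
#'
#' @param n_participants Number of participants (>= 2).
#' @param baseline_logk_mean,baseline_logk_sd Normal distribution of
#'   control-condition log(k) per participant x commodity.
#' @param baseline_cor Correlation of baseline log(k) across commodities.
#' @param generative_model Name of the generating [hypothesis_model()].
#' @param generative_params Named free parameters of that model (natural
#'   scale, all positive; for `spillover` give `out_shift` and
#'   `food_excess`, or `food_shift` and `out_shift`).
#' @param cauchy_scale Cauchy scale of participant-level scatter of the
#'   change in log(k).
#' @param delta_cap Absolute bound on generated changes; draws beyond it
#'   are resampled (a documented truncation keeping sessions informative —
#'   raw Cauchy tails occasionally produce physically absurd rates).
#' @param choice_alpha,choice_epsilon Simulated responders' acuity and
#'   lapse rate.
#' @param rng_seed Integer seed.
#' @return An object of class `dd_population_config`.
#' @export
population_config <- function(n_participants = 50L,
                              baseline_logk_mean = log(1 / 50),
                              baseline_logk_sd = 1.0,
                              baseline_cor = 0.5,
                              generative_model = "spillover",
                              generative_params = c(out_shift = 0.6,
                                                    food_excess = 1.8),
                              cauchy_scale = 0.5,
                              delta_cap = 10,
                              choice_alpha = 2,
                              choice_epsilon = 0.01,
                              rng_seed = 1L) {
  if (n_participants < 2L) stop("`n_participants` must be >= 2")
  if (cauchy_scale <= 0) stop("`cauchy_scale` must be positive")
  if (baseline_cor < 0 || baseline_cor >= 1) {
    stop("`baseline_cor` must lie in [0, 1)")
  }
  model <- hypothesis_model(generative_model)
  par <- resolve_generative_params(model, generative_params)
  structure(list(n_participants = as.integer(n_participants),
                 baseline_logk_mean = baseline_logk_mean,
                 baseline_logk_sd = baseline_logk_sd,
                 baseline_cor = baseline_cor,
                 model = model, generative_params = par,
                 cauchy_scale = cauchy_scale, delta_cap = delta_cap,
                 choice_alpha = choice_alpha,
                 choice_epsilon = choice_epsilon,
                 rng_seed = as.integer(rng_seed)),
            class = "dd_population_config")
}

# Accept either the internal spillover parameterisation (out_shift,
# food_excess) or the natural (food_shift, out_shift); validate positivity
# and model constraints.
resolve_generative_params <- function(model, par) {
  if (model$name == "trait_only") return(numeric(0))
  if (model$name == "spillover" && all(c("food_shift", "out_shift") %in%
                                       names(par))) {
    if (par["food_shift"] <= par["out_shift"]) {
      stop("spillover requires food_shift > out_shift")
    }
    par <- c(out_shift = unname(par["out_shift"]),
             food_excess = unname(par["food_shift"] - par["out_shift"]))
  }
  need <- model$par_names
  if (!all(need %in% names(par))) {
    stop("generative model '", model$name, "' needs parameter(s): ",
         paste(need, collapse = ", "))
  }
  par <- par[need]
  if (any(par <= 0)) stop("generative free parameters must be positive")
  par
}

#' Generate a synthetic delta table with ground truth
#'
#' Draws per-participant changes in log discount rate
#' `delta[p, c] ~ Cauchy(location[c], scale)` independently, where the
#' locations come from the configured generative hypothesis model. Draws
#' with `|delta| > delta_cap` are resampled. Also draws correlated baseline
#' log(k) values per participant x commodity and records the exact
#' fasted-condition log(k) implied by each delta.
#'
#' @param config A [population_config()].
#' @return List with `deltas` (long data frame: `participant`,
#'   `commodity`, `delta_logk`) and `truth` (an object of class
#'   `dd_ground_truth`: long data frame of `participant`, `commodity`,
#'   `condition`, `true_logk` plus the generating model name, parameters
#'   and per-commodity locations as attributes).
#' @export
generate_delta_table <- function(config) {
  stopifnot(inherits(config, "dd_population_config"))
  P <- config$n_participants
  loc <- config$model$locations(config$generative_params)
  withr_seed(config$rng_seed, {
    deltas <- sapply(seq_len(3L), function(ci) {
      rcauchy_capped(P, loc[ci], config$cauchy_scale, config$delta_cap)
    })
    colnames(deltas) <- COMMODITIES
    baseline <- correlated_normal(P, 3L, config$baseline_logk_mean,
                                  config$baseline_logk_sd,
                                  config$baseline_cor)
    colnames(baseline) <- COMMODITIES
    long_delta <- data.frame(
      participant = rep(seq_len(P), times = 3L),
      commodity = rep(COMMODITIES, each = P),
      delta_logk = as.numeric(deltas))
    truth <- rbind(
      data.frame(participant = rep(seq_len(P), 3L),
                 commodity = rep(COMMODITIES, each = P),
                 condition = "control", true_logk = as.numeric(baseline)),
      data.frame(participant = rep(seq_len(P), 3L),
                 commodity = rep(COMMODITIES, each = P),
                 condition = "fasted",
                 true_logk = as.numeric(baseline + deltas)))
    attr(truth, "model") <- config$model$name
    attr(truth, "params") <- config$generative_params
    attr(truth, "locations") <- stats::setNames(loc, COMMODITIES)
    class(truth) <- c("dd_ground_truth", "data.frame")
    list(deltas = long_delta, truth = truth)
  })
}

rcauchy_capped <- function(n, location, scale, cap) {
  x <- stats::rcauchy(n, location, scale)
  while (any(bad <- abs(x) > cap)) {
    x[bad] <- stats::rcauchy(sum(bad), location, scale)
  }
  x
}

# n x p matrix of Normal(mean, sd) values with exchangeable correlation rho
# across columns, built from a shared and an idiosyncratic component.
correlated_normal <- function(n, p, mean, sd, rho) {
  shared <- stats::rnorm(n)
  idio <- matrix(stats::rnorm(n * p), n, p)
  z <- sqrt(rho) * shared + sqrt(1 - rho) * idio
  mean + sd * z
}

#' Ground-truth changes in log(k) as a delta table
#'
#' @param truth A `dd_ground_truth` table from [generate_delta_table()] or
#'   [simulate_study()].
#' @return Long delta data frame (`participant`, `commodity`,
#'   `delta_logk`) of exact fasted-minus-control differences.
#' @export
true_delta_table <- function(truth) {
  ctrl <- truth[truth$condition == "control", ]
  fast <- truth[truth$condition == "fasted", ]
  key <- function(d) paste(d$participant, d$commodity)
  fast <- fast[match(key(ctrl), key(fast)), ]
  data.frame(participant = ctrl$participant, commodity = ctrl$commodity,
             delta_logk = fast$true_logk - ctrl$true_logk)
}

#' Simulate a complete synthetic study
#'
#' Composes [generate_delta_table()] with [run_simulated_session()]: every
#' participant completes one adaptive session of
#' `trials_per_session` trials per condition x commodity (2 x 3 = 6
#' sessions), control sessions at the baseline log(k) and fasted sessions
#' at baseline plus the generated change.
#'
#' @param config A [population_config()].
#' @param priors A [prior_spec()] driving the adaptive chooser.
#' @param design `"adaptive"` or `"random"` trial selection.
#' @param n_particles Interim particle count per session.
#' @return List with `trials` (one long trial table for all sessions) and
#'   `truth` (as in [generate_delta_table()]).
#' @export
simulate_study <- function(config, priors = prior_spec(),
                           design = "adaptive", n_particles = 500L) {
  stopifnot(inherits(config, "dd_population_config"))
  gen <- generate_delta_table(config)
  truth <- gen$truth
  sessions <- vector("list", nrow(truth) / 1L)
  i <- 0L
  for (p in seq_len(config$n_participants)) {
    for (cc in COMMODITIES) {
      space <- commodity_design_space(cc)
      for (cond in CONDITIONS) {
        logk <- truth$true_logk[truth$participant == p &
                                  truth$commodity == cc &
                                  truth$condition == cond]
        params <- choice_params(log_k = logk, alpha = config$choice_alpha,
                                epsilon = config$choice_epsilon)
        seed <- session_seed(config$rng_seed, p, cc, cond)
        i <- i + 1L
        sessions[[i]] <- run_simulated_session(
          params, space, priors, rng_seed = seed, design = design,
          n_particles = n_particles, participant = p, condition = cond,
          commodity = cc)
      }
    }
  }
  list(trials = do.call(rbind, sessions[seq_len(i)]), truth = truth)
}

# distinct, reproducible per-session seed kept within 32-bit integer range
session_seed <- function(base, participant, commodity, condition) {
  ci <- match(commodity, COMMODITIES)
  di <- match(condition, CONDITIONS)
  as.integer((as.numeric(base) * 7919 + participant * 61 + ci * 13 + di) %%
               .Machine$integer.max)
}

#' Write ground truth to CSV
#'
#' Columns `participant, commodity, condition, true_logk`, with the
#' generating model recorded in `#` metadata lines.
#'
#' @param truth A `dd_ground_truth` table.
#' @param path File path.
#' @export
write_ground_truth <- function(truth, path) {
  meta <- c(generative_model = attr(truth, "model"),
            generative_params = paste(sprintf("%s=%g",
                                              names(attr(truth, "params")),
                                              attr(truth, "params")),
                                      collapse = " "))
  write_csv_with_meta(
    as.data.frame(truth)[c("participant", "commodity", "condition",
                           "true_logk")], path, meta)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}
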