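HYPOTHESIS_MODELS <- c("trait_only", "in_domain", "monetary_fungibility",
                       "negative_spillover", "spillover", "state_only")

#' Candidate models of state-induced change in log discount rate
#'
#' Each model maps a small set of strictly positive free parameters to a
#' per-commodity group-level change in log(k) (commodity order food, money,
#' music; food is the in-domain commodity), plus one Cauchy scale parameter
#' for participant-level scatter:
#'
#' * `trait_only`: no change, `(0, 0, 0)` — 1 parameter (scale only).
#' * `in_domain`: `(a, 0, 0)` — change for food only; 2 parameters.
#' * `monetary_fungibility`: `(b, b, 0)` — food and money change equally;
#'   2 parameters.
#' * `negative_spillover`: `(g, -d, -d)` with `g, d > 0` — food discounting
#'   rises while out-of-domain discounting falls; 3 parameters.
#' * `spillover`: `(e, z, z)` with `e > z > 0` — a large in-domain rise and
#'   a smaller positive spillover to both out-of-domain commodities;
#'   3 parameters.
#' * `state_only`: `(h, h, h)` — equal change everywhere; 2 parameters.
#'
#' Parameter counts include the scale parameter. Free parameters are
#' constrained positive; `spillover` additionally enforces that the
#' in-domain change exceeds the out-of-domain change.
#'
#' @param name One of the six model names.
#' @return An object of class `dd_hypothesis_model` with elements `name`,
#'   `label`, `n_params`, `par_names` (free location parameters, reported
#'   on the natural scale), and `locations(par)` mapping free parameters to
#'   the `(food, money, music)` change vector.
#' @export
hypothesis_model <- function(name = HYPOTHESIS_MODELS) {
  name <- match.arg(name)
  def <- switch(name,
    trait_only = list(
      label = "Trait only", par_names = character(0),
      locations = function(par) c(0, 0, 0)),
    in_domain = list(
      label = "In-domain", par_names = "food_shift",
      locations = function(par) c(par[1], 0, 0)),
    monetary_fungibility = list(
      label = "Monetary fungibility", par_names = "fungible_shift",
      locations = function(par) c(par[1], par[1], 0)),
    negative_spillover = list(
      label = "Negative spillover", par_names = c("food_shift", "out_drop"),
      locations = function(par) c(par[1], -par[2], -par[2])),
    spillover = list(
      # internally parameterised as (out_shift, food_excess); the in-domain
      # change out_shift + food_excess is then strictly above out_shift
      label = "Spillover", par_names = c("out_shift", "food_excess"),
      locations = function(par) c(par[1] + par[2], par[1], par[1])),
    state_only = list(
      label = "State only", par_names = "common_shift",
      locations = function(par) c(par[1], par[1], par[1]))
  )
  structure(c(list(name = name), def,
              list(n_params = length(def$par_names) + 1L)),
            class = "dd_hypothesis_model")
}

#' @export
print.dd_hypothesis_model <- function(x, ...) {
  cat(sprintf("Hypothesis model '%s' (%s): %d parameter(s) incl. scale\n",
              x$name, x$label, x$n_params))
  invisible(x)
}

#' Validate a table of per-participant changes in log discount rate
#'
#' A delta table holds one value per participant and commodity: the change
#' in log(k) from the control to the manipulated (fasted) condition.
#' Accepted as a long data frame (`participant`, `commodity`, `delta_logk`)
#' and converted internally to a participants x 3 matrix in commodity order
#' food, money, music.
#'
#' @param deltas Long data frame, or a numeric matrix with columns
#'   `food`, `money`, `music`.
#' @return Numeric matrix (participants x 3) with commodity columns.
#' @export
as_delta_matrix <- function(deltas) {
  if (is.matrix(deltas)) {
    if (!all(COMMODITIES %in% colnames(deltas))) {
      stop("delta matrix must have columns food, money, music")
    }
    m <- deltas[, COMMODITIES, drop = FALSE]
  } else {
    need <- c("participant", "commodity", "delta_logk")
    missing <- setdiff(need, names(deltas))
    if (length(missing) > 0L) {
      stop("delta table missing column(s): ", paste(missing, collapse = ", "))
    }
    if (!all(deltas$commodity %in% COMMODITIES)) {
      stop("commodity must be one of food, money, music")
    }
    tab <- table(deltas$participant, deltas$commodity)
    if (any(tab != 1L)) {
      stop("delta table must contain exactly one value per participant x commodity")
    }
    parts <- sort(unique(deltas$participant))
    m <- vapply(COMMODITIES, function(cc) {
      d <- deltas[deltas$commodity == cc, ]
      d$delta_logk[order(d$participant)]
    }, numeric(length(parts)))
    m <- matrix(m, nrow = length(parts),
                dimnames = list(parts, COMMODITIES))
  }
  if (nrow(m) < 2L) stop("need at least 2 participants")
  if (any(!is.finite(m))) stop("delta values must all be finite")
  m
}

#' Cauchy log-likelihood of a delta table
#'
#' Sums, over every participant x commodity cell, the log density of the
#' observed change in log(k) under a Cauchy distribution centred at that
#' commodity's group-level location with a shared scale:
#' `sum(log Cauchy(delta; location[c], scale))`.
#'
#' @param deltas Delta table (see [as_delta_matrix()]).
#' @param locations Length-3 numeric, per-commodity locations in order
#'   food, money, music.
#' @param scale Positive Cauchy scale.
#' @return The summed log-likelihood.
#' @export
cauchy_loglik <- function(deltas, locations, scale) {
  if (!is.numeric(scale) || length(scale) != 1L || !is.finite(scale) ||
      scale <= 0) {
    stop("`scale` must be strictly positive")
  }
  if (length(locations) != 3L) stop("`locations` must have length 3")
  m <- as_delta_matrix(deltas)
  sum(stats::dcauchy(m, location = rep(locations, each = nrow(m)),
                     scale = scale, log = TRUE))
}

# Unconstrained parameterisation: free locations and (scale - floor) on the
# log scale. The floor avoids likelihood singularities on degenerate tables.
SCALE_FLOOR <- 1e-6

model_loglik_factory <- function(m, model) {
  nfree <- length(model$par_names)
  n <- nrow(m)
  function(theta) {
    par <- exp(theta[seq_len(nfree)])
    scale <- SCALE_FLOOR + exp(theta[nfree + 1L])
    loc <- model$locations(par)
    sum(stats::dcauchy(m, location = rep(loc, each = n), scale = scale,
                       log = TRUE))
  }
}

#' Maximum-likelihood fit of one hypothesis model
#'
#' Maximises the Cauchy log-likelihood of the delta table under the model's
#' location map and constraints. Positivity is enforced by optimising on
#' the log scale; the spillover model's ordering constraint is enforced by
#' parameterising the in-domain change as out-of-domain change plus a
#' positive excess. Optimisation uses Nelder-Mead from `n_starts` random
#' starts (locations in `[0, 3]`, scale in `[0.05, 2]`) plus deterministic
#' near-boundary starts, so boundary optima (e.g. a vanishing out-of-domain
#' drop) are found; the best end point wins, ties broken by the smaller
#' parameter norm.
#'
#' @param deltas Delta table.
#' @param model A [hypothesis_model()] or its name.
#' @param n_starts Number of random multi-starts (>= 8 recommended).
#' @param rng_seed Seed for the random starts (fit is deterministic given
#'   it).
#' @return An object of class `dd_model_fit`: `model`, `ml_params` (named,
#'   natural scale, including `scale`), `locations` (fitted per-commodity
#'   changes), `LL`.
#' @export
fit_model_ml <- function(deltas, model, n_starts = 8L, rng_seed = 1L) {
  if (is.character(model)) model <- hypothesis_model(model)
  stopifnot(inherits(model, "dd_hypothesis_model"))
  m <- as_delta_matrix(deltas)
  nll_env <- model_loglik_factory(m, model)
  nfree <- length(model$par_names)
  obj <- function(theta) -nll_env(theta)

  scale_guess <- max(stats::mad(as.numeric(m)), 0.05)
  if (nfree == 0L) {
    # scale-only model: 1-D problem, solved by golden-section search
    opt <- stats::optimize(function(s) nll_env(s), interval = c(-30, 10),
                           maximum = TRUE, tol = 1e-12)
    scale <- SCALE_FLOOR + exp(opt$maximum)
    return(structure(list(model = model,
                          ml_params = c(scale = scale),
                          locations = stats::setNames(model$locations(NULL),
                                                      COMMODITIES),
                          LL = opt$objective, n_obs = length(m),
                          n_participants = nrow(m)),
                     class = "dd_model_fit"))
  }
  starts <- withr_seed(rng_seed, {
    rand <- replicate(n_starts, c(log(stats::runif(nfree, 0.01, 3)),
                                  log(stats::runif(1, 0.05, 2))),
                      simplify = FALSE)
    rand
  })
  # deterministic starts: data-driven scale, and near-boundary locations so
  # optima on the positivity boundary are reachable
  starts <- c(starts, list(c(rep(log(0.5), nfree), log(scale_guess))))
  if (nfree > 0L) {
    for (j in seq_len(nfree)) {
      s <- c(rep(log(0.5), nfree), log(scale_guess))
      s[j] <- -30
      starts <- c(starts, list(s))
    }
    starts <- c(starts, list(c(rep(-30, nfree), log(scale_guess))))
  }

  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      stats::optim(s, obj, method = "Nelder-Mead",
                   control = list(maxit = 2000L, reltol = 1e-12)),
      error = function(e) NULL)
    if (is.null(fit)) next
    # polish with a second pass from the first optimum
    fit2 <- tryCatch(
      stats::optim(fit$par, obj, method = "Nelder-Mead",
                   control = list(maxit = 2000L, reltol = 1e-12)),
      error = function(e) fit)
    cand <- list(par = fit2$par, value = fit2$value)
    if (is.null(best) || cand$value < best$value - 1e-10 ||
        (abs(cand$value - best$value) <= 1e-10 &&
         sum(exp(cand$par)^2) < sum(exp(best$par)^2))) {
      best <- cand
    }
  }
  if (is.null(best)) stop("optimisation failed from every start")

  free <- exp(best$par[seq_len(nfree)])
  names(free) <- model$par_names
  scale <- SCALE_FLOOR + exp(best$par[nfree + 1L])
  params <- c(free, scale = scale)
  if (model$name == "spillover") {
    # report the natural in-domain / out-of-domain changes
    params <- c(food_shift = unname(free["out_shift"] + free["food_excess"]),
                out_shift = unname(free["out_shift"]), scale = scale)
  }
  structure(list(model = model, ml_params = params,
                 locations = stats::setNames(model$locations(free),
                                             COMMODITIES),
                 LL = -best$value, n_obs = length(m),
                 n_participants = nrow(m)),
            class = "dd_model_fit")
}

#' @export
print.dd_model_fit <- function(x, ...) {
  cat(sprintf("%s fit: LL = %.3f\n", x$model$label, x$LL))
  cat("  locations (food, money, music):",
      paste(sprintf("%.3f", x$locations), collapse = ", "), "\n")
  cat("  params:", paste(sprintf("%s = %.4f", names(x$ml_params),
                                 x$ml_params), collapse = ", "), "\n")
  invisible(x)
}

#' Information criteria from a log-likelihood
#'
#' `AIC = 2 n - 2 LL` and `BIC = n log(N) - 2 LL`, with `n` the model's
#' parameter count (scale included) and `N` the sample size used for the
#' BIC penalty — here the number of participants.
#'
#' @param LL Maximised log-likelihood.
#' @param n_params Parameter count, `>= 1`.
#' @param n_bic Sample size for the BIC penalty, `>= 2`.
#' @return Named vector `c(AIC, BIC)`.
#' @export
information_criteria <- function(LL, n_params, n_bic) {
  if (!is.finite(LL)) stop("`LL` must be finite")
  if (n_params < 1L) stop("`n_params` must be >= 1")
  if (n_bic < 2L) stop("`n_bic` must be >= 2")
  c(AIC = 2 * n_params - 2 * LL, BIC = n_params * log(n_bic) - 2 * LL)
}

#' Akaike / Schwarz model weights
#'
#' Converts a set of information-criterion values to weights
#' `w_m = exp(-0.5 * d_m) / sum_i exp(-0.5 * d_i)` with
#' `d_m = IC_m - min(IC)`. Weights sum to 1 and are invariant to adding a
#' constant to every IC value, so raw IC values and pre-computed deltas
#' give the same answer.
#'
#' @param ic Numeric vector of IC values (or IC deltas), all finite.
#' @return Weights summing to 1.
#' @export
model_weights <- function(ic) {
  if (length(ic) < 1L || any(!is.finite(ic))) {
    stop("`ic` must be a nonempty finite numeric vector")
  }
  d <- ic - min(ic)
  w <- exp(-0.5 * d)
  w / sum(w)
}

#' Fit and compare all six hypothesis models
#'
#' Fits each candidate model to the delta table by maximum likelihood,
#' computes AIC and BIC (BIC sample size = number of participants unless
#' overridden), the deltas to the best model, and both weight sets.
#'
#' @param deltas Delta table.
#' @param n_bic BIC sample size; defaults to the number of participants.
#' @param n_starts,rng_seed Passed to [fit_model_ml()].
#' @return An object of class `dd_comparison`: a data frame with one row
#'   per model (`model`, `n`, `LL`, `AIC`, `BIC`, `dAIC`, `wAIC`, `dBIC`,
#'   `wBIC`) in fixed model order, with the fits attached as an attribute.
#' @export
compare_all <- function(deltas, n_bic = NULL, n_starts = 8L, rng_seed = 1L) {
  m <- as_delta_matrix(deltas)
  if (is.null(n_bic)) n_bic <- nrow(m)
  fits <- lapply(HYPOTHESIS_MODELS, function(nm) {
    fit_model_ml(m, nm, n_starts = n_starts, rng_seed = rng_seed)
  })
  names(fits) <- HYPOTHESIS_MODELS
  ll <- vapply(fits, `[[`, numeric(1), "LL")
  np <- vapply(fits, function(f) f$model$n_params, integer(1))
  ic <- mapply(information_criteria, ll, np, MoreArgs = list(n_bic = n_bic))
  out <- data.frame(model = HYPOTHESIS_MODELS, n = np, LL = ll,
                    AIC = ic["AIC", ], BIC = ic["BIC", ],
                    row.names = NULL)
  out$dAIC <- out$AIC - min(out$AIC)
  out$wAIC <- model_weights(out$AIC)
  out$dBIC <- out$BIC - min(out$BIC)
  out$wBIC <- model_weights(out$BIC)
  structure(out, fits = fits, n_bic = n_bic, class = c("dd_comparison",
                                                       "data.frame"))
}

#' @export
print.dd_comparison <- function(x, digits = 2, ...) {
  cat("Model comparison (Cauchy likelihood of per-participant changes in log k)\n")
  df <- data.frame(model = x$model, n = x$n,
                   LL = round(x$LL, digits),
                   dAIC = round(x$dAIC, digits),
                   wAIC = round(x$wAIC, 4),
                   dBIC = round(x$dBIC, digits),
                   wBIC = round(x$wBIC, 4))
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}

#' Paired Cohen's d effect size
#'
#' Standardised mean paired difference: `mean(y - x) / sd(y - x)` with the
#' usual `n - 1` denominator in the SD.
#'
#' @param x,y Paired measurements (e.g. control and fasted log k), equal
#'   length `>= 2`.
#' @return A single number.
#' @export
paired_cohens_d <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2L) {
    stop("`x` and `y` must be paired vectors of length >= 2")
  }
  d <- y - x
  s <- stats::sd(d)
  if (s == 0) stop("differences have zero variance; effect size undefined")
  mean(d) / s
}

#' Percentile bootstrap confidence interval for a mean
#'
#' @param diffs Numeric vector (length >= 2).
#' @param level Coverage level (default 0.95).
#' @param n_boot Number of resamples (>= 1000).
#' @param rng_seed Integer seed (interval reproducible given it).
#' @return Named vector `c(low, high)`.
#' @export
bootstrap_mean_ci <- function(diffs, level = 0.95, n_boot = 2000L,
                              rng_seed = 1L) {
  if (length(diffs) < 2L) stop("need at least 2 values")
  if (n_boot < 1000L) stop("`n_boot` must be >= 1000")
  means <- withr_seed(rng_seed, {
    vapply(seq_len(n_boot), function(i) {
      mean(sample(diffs, replace = TRUE))
    }, numeric(1))
  })
  q <- stats::quantile(means, c((1 - level) / 2, 1 - (1 - level) / 2),
                       names = FALSE)
  c(low = q[1], high = q[2])
}

#' Spillover ratio of out-of-domain to in-domain change
#'
#' The average change in log discount rate across participants and the two
#' out-of-domain commodities (money, music), as a percentage of the average
#' in-domain (food) change.
#'
#' @param deltas Delta table.
#' @return Percentage (100 = equal change everywhere).
#' @export
spillover_ratio <- function(deltas) {
  m <- as_delta_matrix(deltas)
  food <- mean(m[, "food"])
  if (food == 0) stop("in-domain (food) mean change is zero; ratio undefined")
  100 * mean(m[, c("money", "music")]) / food
}

#' Read / write delta tables
#'
#' Long CSV with header `participant, commodity, delta_logk`; `#` comment
#' lines carry metadata.
#'
#' @param path File path.
#' @param deltas Long delta data frame.
#' @param meta Optional named metadata written as header comments.
#' @export
read_delta_table <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  as_delta_matrix(df)  # validates
  df
}

#' @rdname read_delta_table
#' @export
write_delta_table <- function(deltas, path, meta = NULL) {
  as_delta_matrix(deltas)
  write_csv_with_meta(deltas[c("participant", "commodity", "delta_logk")],
                      path, meta)
  invisible(path)
}

#' Published six-model comparison table from the motivating hunger study
#'
#' The model-comparison table reported by the repeated-measures fasting
#' study that motivates this package (50 participants; food, money and
#' music commodities): per model, the parameter count `n` (scale included),
#' maximised log-likelihood `LL`, and the published `dAIC`, `wAIC`, `dBIC`,
#' `wBIC` columns. Useful as a worked example for [model_weights()] and
#' [information_criteria()], and as a fixture for consistency checks.
#'
#' @return Data frame with one row per model in standard order.
#' @export
reference_comparison_table <- function() {
  data.frame(
    model = HYPOTHESIS_MODELS,
    n  = c(1L, 2L, 2L, 3L, 3L, 2L),
    LL = c(-365.66, -347.37, -349.16, -347.37, -340.17, -348.44),
    dAIC = c(47.00, 12.41, 15.99, 14.41, 0.00, 14.56),
    wAIC = c(0.00, 0.00, 0.00, 0.00, 1.00, 0.00),
    dBIC = c(43.18, 10.50, 14.08, 14.41, 0.00, 12.65),
    wBIC = c(0.00, 0.01, 0.00, 0.00, 0.99, 0.00)
  )
}
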