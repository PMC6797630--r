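#' Prior specification for session-level inference
#'
#' Defaults reproduce the study-style priors: acuity
#' `alpha ~ Exponential(0.1)`, lapse `epsilon ~ Beta(1.1, 10.9)`, and
#' `log(k) ~ Normal(log(1/50), 2.5)` — a prior centred on a 50-day
#' half-life with a weak (SD 2.5 log-units) spread.
#'
#' @param alpha_rate Rate of the exponential prior on acuity.
#' @param epsilon_a,epsilon_b Beta shape parameters of the lapse prior.
#' @param logk_mean,logk_sd Normal prior on the log discount rate.
#' @return An object of class `dd_prior_spec`.
#' @export
prior_spec <- function(alpha_rate = 0.1, epsilon_a = 1.1, epsilon_b = 10.9,
                       logk_mean = log(1 / 50), logk_sd = 2.5) {
  vals <- c(alpha_rate = alpha_rate, epsilon_a = epsilon_a,
            epsilon_b = epsilon_b, logk_sd = logk_sd)
  if (any(!is.finite(vals)) || any(vals <= 0) || !is.finite(logk_mean)) {
    stop("prior hyperparameters must be finite; scales/shapes positive")
  }
  structure(list(alpha_rate = alpha_rate, epsilon_a = epsilon_a,
                 epsilon_b = epsilon_b, logk_mean = logk_mean,
                 logk_sd = logk_sd),
            class = "dd_prior_spec")
}

# Joint log prior density on (log_k, alpha, epsilon); used by the particle
# updater of the adaptive design module (the MCMC fit states it in JAGS).
log_prior_density <- function(log_k, alpha, epsilon, priors) {
  stats::dnorm(log_k, priors$logk_mean, priors$logk_sd, log = TRUE) +
    stats::dexp(alpha, priors$alpha_rate, log = TRUE) +
    stats::dbeta(epsilon, priors$epsilon_a, priors$epsilon_b, log = TRUE)
}

# Draw n joint samples from the prior.
sample_prior <- function(n, priors) {
  data.frame(
    log_k   = stats::rnorm(n, priors$logk_mean, priors$logk_sd),
    alpha   = stats::rexp(n, priors$alpha_rate),
    epsilon = stats::rbeta(n, priors$epsilon_a, priors$epsilon_b)
  )
}

JAGS_CHOICE_MODEL <- "model {
  for (t in 1:N) {
    VB[t] <- B[t] / (1 + exp(logk) * DB[t])
    VA[t] <- A[t] / (1 + exp(logk) * DA[t])
    P[t] <- eps + (1 - 2 * eps) * phi((VB[t] - VA[t]) / alpha)
    R[t] ~ dbern(P[t])
  }
  logk ~ dnorm(mu_logk, pow(sd_logk, -2))
  alpha ~ dexp(rate_alpha)
  eps ~ dbeta(a_eps, b_eps)
}"

#' Fit the per-session posterior over choice parameters
#'
#' Estimates the joint posterior of `(log_k, alpha, epsilon)` for one
#' session of binary inter-temporal choices under the lapse-contaminated
#' probit likelihood and the priors of [prior_spec()], by MCMC (JAGS;
#' 4 chains, 1000 post-warmup draws each by default). Convergence is
#' summarised by split-chain potential scale reduction (Rhat) and effective
#' sample size per parameter; `Rhat > 1.05` on any parameter sets
#' `converged = FALSE` in the diagnostics rather than failing.
#'
#' Draws with `epsilon >= 0.5` (where the choice rule would become
#' non-monotone) are dropped from the stored table; if they exceed 1% of
#' the posterior mass a fit warning is recorded in the diagnostics.
#'
#' @param trials Trial table for one session (must include responses).
#' @param priors A [prior_spec()].
#' @param rng_seed Integer seed (controls chain RNGs; fixed seed gives
#'   identical draws).
#' @param chains,iter,warmup Sampler settings: number of chains, post-warmup
#'   draws per chain, and adaptation/warmup iterations.
#' @return An object of class `dd_posterior`: list with `draws` (data frame
#'   of `log_k`, `alpha`, `epsilon`), `point_log_k` (posterior median),
#'   `diagnostics` (per-parameter `rhat` and `ess`, `converged`,
#'   `epsilon_tail_mass`), and the session `trials`.
#' @export
fit_posterior <- function(trials, priors = prior_spec(), rng_seed = 1L,
                          chains = 4L, iter = 1000L, warmup = 500L) {
  validate_trials(trials)
  stopifnot(inherits(priors, "dd_prior_spec"))
  data <- list(N = nrow(trials), A = trials$A, DA = trials$DA, B = trials$B,
               DB = trials$DB, R = as.integer(trials$R),
               mu_logk = priors$logk_mean, sd_logk = priors$logk_sd,
               rate_alpha = priors$alpha_rate, a_eps = priors$epsilon_a,
               b_eps = priors$epsilon_b)
  inits <- lapply(seq_len(chains), function(i) {
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = as.integer(rng_seed) * 1000L + i,
         logk = priors$logk_mean, alpha = 1 / priors$alpha_rate * 0.5,
         eps = 0.05)
  })
  model <- rjags::jags.model(textConnection(JAGS_CHOICE_MODEL), data = data,
                             inits = inits, n.chains = chains,
                             n.adapt = warmup, quiet = TRUE)
  samples <- rjags::coda.samples(model, c("logk", "alpha", "eps"),
                                 n.iter = iter, progress.bar = "none")
  per_chain <- lapply(samples, function(m) {
    data.frame(log_k = as.numeric(m[, "logk"]),
               alpha = as.numeric(m[, "alpha"]),
               epsilon = as.numeric(m[, "eps"]))
  })
  draws <- do.call(rbind, per_chain)
  rhat <- vapply(c("log_k", "alpha", "epsilon"), function(par) {
    split_rhat(vapply(per_chain, function(d) d[[par]], numeric(iter)))
  }, numeric(1))
  ess <- vapply(c("logk", "alpha", "eps"), function(par) {
    as.numeric(coda::effectiveSize(samples[, par]))
  }, numeric(1))
  names(ess) <- c("log_k", "alpha", "epsilon")
  eps_tail <- mean(draws$epsilon >= 0.5)
  if (eps_tail > 0) draws <- draws[draws$epsilon < 0.5, , drop = FALSE]
  diagnostics <- list(rhat = rhat, ess = ess,
                      converged = all(rhat <= 1.05),
                      epsilon_tail_mass = eps_tail,
                      epsilon_tail_warning = eps_tail > 0.01)
  structure(list(draws = draws,
                 point_log_k = stats::median(draws$log_k),
                 diagnostics = diagnostics,
                 trials = trials, priors = priors),
            class = "dd_posterior")
}

#' @export
print.dd_posterior <- function(x, ...) {
  cat(sprintf("Posterior over choice parameters (%d draws)\n", nrow(x$draws)))
  cat(sprintf("  log_k: median %.3f (SD %.3f); alpha median %.3f; epsilon median %.4f\n",
              x$point_log_k, stats::sd(x$draws$log_k),
              stats::median(x$draws$alpha), stats::median(x$draws$epsilon)))
  cat(sprintf("  max Rhat %.3f (%s); min ESS %.0f\n",
              max(x$diagnostics$rhat),
              if (x$diagnostics$converged) "converged" else "NOT converged",
              min(x$diagnostics$ess)))
  invisible(x)
}

# Split-chain potential scale reduction factor. `chains` is an iterations x
# chains matrix; each chain is split in half before the standard
# between/within variance ratio.
split_rhat <- function(chains) {
  n <- nrow(chains)
  half <- floor(n / 2)
  sub <- cbind(chains[seq_len(half), , drop = FALSE],
               chains[(n - half + 1):n, , drop = FALSE])
  m <- ncol(sub)
  means <- colMeans(sub)
  vars <- apply(sub, 2, stats::var)
  w <- mean(vars)
  b <- half * stats::var(means)
  if (w == 0) return(1)
  sqrt(((half - 1) / half * w + b / half) / w)
}

#' Posterior-predictive choice probabilities
#'
#' For each trial, the posterior mean over draws of the lapse-contaminated
#' probit choice probability — the model's prediction of the probability of
#' choosing the delayed reward on that trial.
#'
#' @param posterior A [fit_posterior()] result, or any list with a `draws`
#'   data frame of `log_k`, `alpha`, `epsilon`.
#' @param trials Trial table from the same session.
#' @param fun_family Discount function family used for the values.
#' @return Vector of probabilities in `(0, 1)`, one per trial.
#' @export
posterior_predictive_probs <- function(posterior, trials,
                                       fun_family = "hyperbolic") {
  draws <- posterior$draws
  if (is.null(draws) || nrow(draws) == 0L) stop("posterior has no draws")
  validate_trials(trials, require_response = FALSE)
  pm <- predictive_prob_matrix(draws, trials$A, trials$DB, trials$B,
                               fun_family)
  colMeans(pm)
}

# draws x trials matrix of choice probabilities (immediate option at delay 0).
predictive_prob_matrix <- function(draws, A, DB, B, fun_family = "hyperbolic") {
  k <- exp(draws$log_k)
  frac <- switch(fun_family,
    hyperbolic = 1 / (1 + outer(k, DB)),
    exponential = exp(-outer(k, DB)),
    stop("unsupported family for predictive matrix: ", fun_family)
  )
  vb <- sweep(frac, 2, B, "*")
  z <- sweep(sweep(vb, 2, A, "-"), 1, draws$alpha, "/")
  eps <- draws$epsilon
  sweep(sweep(stats::pnorm(z), 1, 1 - 2 * eps, "*"), 1, eps, "+")
}

#' Area under the ROC curve for binary choice predictions
#'
#' The Mann-Whitney construction: the fraction of (positive, negative)
#' response pairs in which the positive trial received the higher predicted
#' probability, ties counted 0.5. A value of 1 means perfect prediction and
#' 0.5 chance level. Invariant to any strictly monotone transform of the
#' probabilities.
#'
#' @param probs Predicted probabilities of choosing the delayed reward.
#' @param responses Observed 0/1 responses.
#' @return AUC in `[0, 1]`, or `NA` (with a warning) when only one response
#'   class is present.
#' @export
auc_roc <- function(probs, responses) {
  if (length(probs) != length(responses)) {
    stop("`probs` and `responses` must have equal length")
  }
  if (!all(responses %in% c(0, 1))) stop("`responses` must be 0/1")
  n1 <- sum(responses == 1)
  n0 <- sum(responses == 0)
  if (n1 == 0L || n0 == 0L) {
    warning("AUC undefined: responses contain a single class")
    return(NA_real_)
  }
  r <- rank(probs)  # average ranks give the 0.5 tie convention
  (sum(r[responses == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
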