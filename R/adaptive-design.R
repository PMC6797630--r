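#' The 19-delay grid of the measurement protocol
#'
#' Nineteen delays, geometrically (log-uniformly) spaced from 1 hour
#' (`1/24` day) to 1 year (365 days) inclusive, so consecutive delays share
#' a constant ratio of `(365 * 24)^(1/18)`.
#'
#' @return Numeric vector of 19 delays in days, strictly increasing.
#' @export
build_delay_grid <- function() {
  exp(seq(log(1 / 24), log(365), length.out = 19L))
}

#' Design space of a fixed-delayed-reward session
#'
#' The protocol holds the delayed reward `B` fixed per commodity and lets
#' the per-trial design vary over a grid of immediate amounts `A` and 19
#' log-spaced delays. Default immediate amounts are percent steps
#' `B/100, 2B/100, ..., 99B/100`.
#'
#' @param delayed_reward Fixed delayed reward magnitude `B` (> 0).
#' @param delays Delay grid in days; must be the 19-point log-spaced grid
#'   from 1 hour to 1 year (see [build_delay_grid()]).
#' @param immediate_amounts Candidate immediate amounts, each in `(0, B]`.
#' @param trials_per_session Number of trials in a session (default 35).
#' @return An object of class `dd_design_space`.
#' @export
design_space <- function(delayed_reward,
                         delays = build_delay_grid(),
                         immediate_amounts = delayed_reward * (1:99) / 100,
                         trials_per_session = 35L) {
  if (!is.numeric(delayed_reward) || length(delayed_reward) != 1L ||
      delayed_reward <= 0) {
    stop("`delayed_reward` must be a single positive number")
  }
  if (length(delays) != 19L || is.unsorted(delays, strictly = TRUE) ||
      !isTRUE(all.equal(min(delays), 1 / 24)) ||
      !isTRUE(all.equal(max(delays), 365))) {
    stop("`delays` must be 19 strictly increasing days from 1/24 to 365")
  }
  if (length(immediate_amounts) == 0L || any(immediate_amounts <= 0) ||
      any(immediate_amounts > delayed_reward)) {
    stop("immediate amounts must lie in (0, B]")
  }
  if (trials_per_session < 1L) stop("`trials_per_session` must be >= 1")
  structure(list(delayed_reward = delayed_reward, delays = delays,
                 immediate_amounts = sort(unique(immediate_amounts)),
                 trials_per_session = as.integer(trials_per_session)),
            class = "dd_design_space")
}

#' Design space for a study commodity
#'
#' Applies the protocol's fixed delayed rewards under the exchange rate
#' 20 money units = 20 song downloads = 10 food units: `B = 20` for money
#' and music, `B = 10` for food.
#'
#' @param commodity `"food"`, `"money"` or `"music"`.
#' @return A [design_space()].
#' @export
commodity_design_space <- function(commodity = c("food", "money", "music")) {
  commodity <- match.arg(commodity)
  design_space(delayed_reward = if (commodity == "food") 10 else 20)
}

# All candidate (A, DB) designs of a space, as a data frame. Rows are
# ordered delay-major so selection tie-breaks are reproducible.
candidate_designs <- function(space) {
  data.frame(
    A  = rep(space$immediate_amounts, times = length(space$delays)),
    DA = 0,
    B  = space$delayed_reward,
    DB = rep(space$delays, each = length(space$immediate_amounts))
  )
}

# Expected posterior entropy of log_k per candidate design, from weighted
# draws. Returns a data frame with the response-marginalised expected
# entropy `exp_entropy`, the predictive choice probability `pbar`, and the
# current entropy; the information gain of a candidate is
# `entropy_now - exp_entropy`.
candidate_entropy <- function(draws, weights, space, n_bins = 30L) {
  cand <- candidate_designs(space)
  n <- nrow(draws)
  w <- weights / sum(weights)
  # choice probability of every draw under every candidate
  pm <- t(predictive_prob_matrix(draws, cand$A, cand$DB, cand$B))
  rng <- range(draws$log_k)
  if (diff(rng) <= 0) {
    # degenerate (atomic) posterior: entropy is zero whatever we ask
    return(cbind(cand, exp_entropy = 0, entropy_now = 0,
                 pbar = as.numeric(pm %*% w)))
  }
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  bin <- findInterval(draws$log_k, edges, rightmost.closed = TRUE,
                      all.inside = TRUE)
  ind <- matrix(0, n, n_bins)
  ind[cbind(seq_len(n), bin)] <- w
  mass_now <- colSums(ind)
  entropy_now <- -sum(ifelse(mass_now > 0, mass_now * log(mass_now), 0))
  # joint mass over (response, log_k bin); rows are candidates
  m1 <- pm %*% ind
  m0 <- (1 - pm) %*% ind
  p1 <- rowSums(m1)
  h1 <- -rowSums(ifelse(m1 > 0, m1 * log(m1 / pmax(p1, 1e-300)), 0))
  p0 <- 1 - p1
  h0 <- -rowSums(ifelse(m0 > 0, m0 * log(m0 / pmax(p0, 1e-300)), 0))
  cbind(cand, exp_entropy = h1 + h0, entropy_now = entropy_now, pbar = p1)
}

#' Select the next trial design by expected information gain
#'
#' Chooses, from the candidate `(A, D_B)` designs of the space, the one
#' maximising the myopic expected reduction in Shannon entropy of the
#' (binned, response-marginalised) posterior over `log_k`, estimated from
#' posterior draws. Ties — including the degenerate case of an atomic
#' posterior, whose entropy cannot be reduced — are broken in favour of the
#' candidate whose predictive choice probability is closest to 0.5, then by
#' grid order, so the choice is deterministic for a fixed posterior and
#' seed.
#'
#' @param posterior A [fit_posterior()] result, or a data frame of draws
#'   with columns `log_k`, `alpha`, `epsilon` (optionally carrying a
#'   `weights` attribute).
#' @param space A [design_space()].
#' @param history Previously administered trials (validated, otherwise
#'   unused: designs may repeat).
#' @param rng_seed Integer seed; only used to subsample large draw sets.
#' @param max_draws Cap on draws used to score candidates.
#' @return One-row data frame with columns `A`, `DA`, `B`, `DB` (no
#'   response).
#' @export
select_next_trial <- function(posterior, space, history = NULL,
                              rng_seed = 1L, max_draws = 500L) {
  stopifnot(inherits(space, "dd_design_space"))
  draws <- if (is.data.frame(posterior)) posterior else posterior$draws
  if (is.null(draws) || nrow(draws) == 0L) stop("posterior has no draws")
  if (!is.null(history) && nrow(history) > 0L) {
    validate_trials(history, require_response = FALSE)
  }
  weights <- attr(posterior, "weights")
  if (is.null(weights)) weights <- rep(1, nrow(draws))
  if (nrow(draws) > max_draws) {
    idx <- withr_seed(rng_seed,
                      sample.int(nrow(draws), max_draws, prob = weights))
    draws <- draws[idx, , drop = FALSE]
    weights <- rep(1, max_draws)
  }
  sc <- candidate_entropy(draws, weights, space)
  gain <- sc$entropy_now - sc$exp_entropy
  best <- which(gain >= max(gain) - 1e-12)
  if (length(best) > 1L) best <- best[which.min(abs(sc$pbar[best] - 0.5))]
  sc[best[1L], c("A", "DA", "B", "DB")]
}

# One resample-move step of the interim particle representation: systematic
# resampling proportional to weights, then `n_moves` random-walk Metropolis
# steps targeting prior x likelihood(history).
particle_resample_move <- function(draws, weights, history, priors,
                                   n_moves = 2L) {
  n <- nrow(draws)
  w <- weights / sum(weights)
  u <- (stats::runif(1) + seq_len(n) - 1) / n
  idx <- findInterval(u, cumsum(w)) + 1L
  idx[idx > n] <- n
  draws <- draws[idx, , drop = FALSE]
  logpost <- function(d) {
    pm <- predictive_prob_matrix(d, history$A, history$DB, history$B)
    ll <- as.numeric(
      pm_loglik(pm, history$R)
    )
    ll + log_prior_density(d$log_k, d$alpha, d$epsilon, priors)
  }
  lp <- logpost(draws)
  step <- c(log_k = 0.5, log_alpha = 0.5, logit_eps = 0.5)
  for (m in seq_len(n_moves)) {
    prop <- data.frame(
      log_k   = draws$log_k + stats::rnorm(n, 0, step["log_k"]),
      alpha   = draws$alpha * exp(stats::rnorm(n, 0, step["log_alpha"])),
      epsilon = stats::plogis(stats::qlogis(pmin(pmax(draws$epsilon, 1e-9),
                                                 1 - 1e-9)) +
                                stats::rnorm(n, 0, step["logit_eps"]))
    )
    lp_prop <- logpost(prop)
    # proposal asymmetry corrections (log-normal on alpha, logit-normal on eps)
    jac <- log(prop$alpha) - log(draws$alpha) +
      log(prop$epsilon * (1 - prop$epsilon)) -
      log(draws$epsilon * (1 - draws$epsilon))
    accept <- log(stats::runif(n)) < (lp_prop - lp + jac)
    draws[accept, ] <- prop[accept, ]
    lp[accept] <- lp_prop[accept]
  }
  draws
}

# summed Bernoulli log-likelihood per draw from a draws x trials prob matrix
pm_loglik <- function(pm, responses) {
  pm <- pmin(pmax(pm, 1e-12), 1 - 1e-12)
  lik <- sweep(log(pm), 2, responses, "*") +
    sweep(log1p(-pm), 2, 1 - responses, "*")
  rowSums(lik)
}

#' Run one simulated session of the adaptive protocol
#'
#' Closes the loop between trial selection, response simulation and interim
#' posterior updating: starting from the prior, each of the
#' `trials_per_session` designs is chosen by [select_next_trial()] (or
#' uniformly at random for the `"random"` baseline), the response is drawn
#' from the simulated participant's true parameters, and the interim
#' posterior — a weighted particle representation refreshed by
#' resample-move steps — is updated with the new observation.
#'
#' @param true_params [choice_params()] of the simulated participant.
#' @param space A [design_space()].
#' @param priors A [prior_spec()] (start of the interim updater).
#' @param fun Discount function of the simulated participant; default
#'   hyperbolic at `exp(log_k)`.
#' @param rng_seed Integer seed; the whole session is reproducible.
#' @param design `"adaptive"` (information-gain chooser) or `"random"`.
#' @param n_particles Interim particle count.
#' @param participant,condition,commodity Session labels stored in the
#'   output table.
#' @return Trial data frame of `trials_per_session` rows in the standard
#'   column layout, responses included.
#' @export
run_simulated_session <- function(true_params, space, priors = prior_spec(),
                                  fun = NULL, rng_seed = 1L,
                                  design = c("adaptive", "random"),
                                  n_particles = 500L,
                                  participant = 1L, condition = "control",
                                  commodity = "money") {
  stopifnot(inherits(true_params, "dd_choice_params"),
            inherits(space, "dd_design_space"))
  design <- match.arg(design)
  if (is.null(fun)) {
    fun <- discount_function("hyperbolic", k = exp(true_params$log_k))
  }
  n_trials <- space$trials_per_session
  withr_seed(rng_seed, {
    particles <- sample_prior(n_particles, priors)
    weights <- rep(1, n_particles)
    rows <- vector("list", n_trials)
    history <- NULL
    for (t in seq_len(n_trials)) {
      if (design == "adaptive") {
        p_in <- particles
        attr(p_in, "weights") <- weights
        des <- select_next_trial(p_in, space, history,
                                 rng_seed = rng_seed + t,
                                 max_draws = n_particles)
      } else {
        des <- data.frame(
          A = sample(space$immediate_amounts, 1L), DA = 0,
          B = space$delayed_reward, DB = sample(space$delays, 1L))
      }
      p_choose <- choice_probability(des, true_params, fun)
      des$R <- stats::rbinom(1L, 1L, p_choose)
      history <- rbind(history, des)
      rows[[t]] <- des
      # weight update with the new observation
      pt <- as.numeric(predictive_prob_matrix(particles, des$A, des$DB,
                                              des$B))
      pt <- pmin(pmax(pt, 1e-12), 1 - 1e-12)
      weights <- weights * if (des$R == 1) pt else 1 - pt
      ess <- sum(weights)^2 / sum(weights^2)
      if (ess < n_particles / 2) {
        particles <- particle_resample_move(particles, weights, history,
                                            priors)
        weights <- rep(1, n_particles)
      }
    }
    out <- do.call(rbind, rows)
    data.frame(participant = participant, condition = condition,
               commodity = commodity, trial_index = seq_len(n_trials),
               A = out$A, DA = out$DA, B = out$B, DB = out$DB, R = out$R)
  })
}
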