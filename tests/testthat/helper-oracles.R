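# Independent oracles and fixture builders shared across the test files.

# Delta matrix with named commodity columns from per-commodity vectors.
delta_fixture <- function(food, money, music) {
  cbind(food = food, money = money, music = music)
}

# Brute-force refined grid search for the maximum Cauchy log-likelihood of a
# hypothesis model. Works in the same transformed coordinates as the fitted
# model (log free parameters, log scale) but explores them by exhaustive
# gridding, refining around the top-K grid points of each round (a beam, so
# multimodal likelihoods cannot trap it in one basin). Shares no code path
# with optim().
grid_search_oracle <- function(m, model_name, n_rounds = 8L, beam = 25L) {
  model <- hypothesis_model(model_name)
  nfree <- length(model$par_names)
  dim <- nfree + 1L
  n <- nrow(m)
  ll_fun <- function(theta) {
    par <- exp(theta[seq_len(nfree)])
    scale <- 1e-6 + exp(theta[nfree + 1L])
    loc <- model$locations(par)
    sum(stats::dcauchy(m, location = rep(loc, each = n), scale = scale,
                       log = TRUE))
  }
  eval_grid <- function(grid) apply(grid, 1L, ll_fun)
  # greedy diverse beam: best points at least min_sep apart (Chebyshev),
  # so several likelihood basins are refined in parallel
  pick_centers <- function(grid, vals, min_sep) {
    ord <- order(vals, decreasing = TRUE)
    kept <- integer(0)
    for (i in ord) {
      if (length(kept) == beam) break
      # at most 2 centers per (near-)identical LL: flat plateaus must not
      # crowd distinct basins out of the beam
      if (sum(abs(vals[kept] - vals[i]) < 1e-7) >= 2L) next
      if (length(kept) == 0L ||
          all(apply(abs(grid[kept, , drop = FALSE] -
                          matrix(grid[i, ], length(kept), dim,
                                 byrow = TRUE)), 1L, max) >= min_sep)) {
        kept <- c(kept, i)
      }
    }
    grid[kept, , drop = FALSE]
  }
  # round 1: full coverage of the transformed box, with extra axis points at
  # the log absolute data values (Cauchy location optima sit near data
  # points) and at deviation quantiles for the scale, plus the boundary
  # faces (subsets of location parameters pinned to ~zero) where the optima
  # of nested models live
  data_pts <- sort(unique(pmax(pmin(log(abs(as.numeric(m))[
    abs(as.numeric(m)) > 1e-10]), 3), -25)))
  dev <- abs(as.numeric(m) - stats::median(m))
  scale_pts <- sort(unique(pmax(pmin(log(stats::quantile(
    dev[dev > 1e-10], c(0.1, 0.25, 0.5, 0.75, 0.9))), 3), -25)))
  base_axis <- seq(-25, 3, length.out = 15L)
  axes <- c(replicate(nfree, sort(unique(c(base_axis, data_pts))),
                      simplify = FALSE),
            list(sort(unique(c(base_axis, scale_pts)))))
  grid <- as.matrix(expand.grid(axes))
  if (nfree > 0L) {
    subsets <- unlist(lapply(seq_len(nfree), function(sz) {
      utils::combn(seq_len(nfree), sz, simplify = FALSE)
    }), recursive = FALSE)
    for (sub in subsets) {
      free_axes <- axes
      for (j in sub) free_axes[[j]] <- -30
      grid <- rbind(grid, as.matrix(expand.grid(free_axes)))
    }
  }
  vals <- eval_grid(grid)
  best <- list(theta = grid[which.max(vals), ], LL = max(vals))
  half_width <- (3 - (-25)) / 14
  centers <- pick_centers(grid, vals, half_width * 1.5)
  for (round in seq_len(n_rounds)) {
    pieces <- lapply(seq_len(nrow(centers)), function(i) {
      axes <- lapply(seq_len(dim), function(j) {
        seq(centers[i, j] - half_width, centers[i, j] + half_width,
            length.out = 7L)
      })
      as.matrix(expand.grid(axes))
    })
    grid <- do.call(rbind, pieces)
    vals <- eval_grid(grid)
    if (max(vals) > best$LL) {
      best <- list(theta = grid[which.max(vals), ], LL = max(vals))
    }
    half_width <- half_width / 3
    centers <- pick_centers(grid, vals, half_width * 1.5)
  }
  best
}

# Importance-sampling posterior summary for one session: draws from the
# prior reweighted by the Bernoulli likelihood. An MCMC-free cross-check of
# fit_posterior() point estimates on informative sessions.
importance_posterior_logk <- function(trials, priors = prior_spec(),
                                      n = 200000L, seed = 99L) {
  set.seed(seed)
  draws <- data.frame(
    log_k = stats::rnorm(n, priors$logk_mean, priors$logk_sd),
    alpha = stats::rexp(n, priors$alpha_rate),
    epsilon = stats::rbeta(n, priors$epsilon_a, priors$epsilon_b))
  k <- exp(draws$log_k)
  ll <- numeric(n)
  for (t in seq_len(nrow(trials))) {
    vb <- trials$B[t] / (1 + k * trials$DB[t])
    p <- draws$epsilon + (1 - 2 * draws$epsilon) *
      stats::pnorm((vb - trials$A[t]) / draws$alpha)
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    ll <- ll + if (trials$R[t] == 1) log(p) else log1p(-p)
  }
  w <- exp(ll - max(ll))
  w <- w / sum(w)
  ord <- order(draws$log_k)
  cw <- cumsum(w[ord])
  list(median = draws$log_k[ord][which(cw >= 0.5)[1]],
       mean = sum(w * draws$log_k),
       ess = 1 / sum(w^2))
}

# A deliberately uninformative session: the immediate amount is negligible
# against the delayed reward at the shortest delay, so the delayed option is
# preferred under any plausible discount rate and the data barely constrain
# log(k).
uninformative_session <- function(n_trials = 35L) {
  data.frame(A = 0.2, DA = 0, B = 20, DB = 1 / 24, R = 1L,
             participant = 1L, condition = "control", commodity = "money",
             trial_index = seq_len(n_trials))
}

# Simulated session + fit, returning truth and posterior summaries.
recover_one <- function(log_k, alpha, epsilon, seed,
                        commodity = "money", n_particles = 500L) {
  tp <- choice_params(log_k, alpha, epsilon)
  sess <- run_simulated_session(tp, commodity_design_space(commodity),
                                rng_seed = seed, n_particles = n_particles)
  post <- fit_posterior(sess, rng_seed = seed + 1L)
  list(true = log_k, est = post$point_log_k,
       sd = stats::sd(post$draws$log_k), post = post, trials = sess)
}
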