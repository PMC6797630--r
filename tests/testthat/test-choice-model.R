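test_that("choice probability matches the lapse-contaminated probit by hand", {
  # at value indifference the rule gives exactly 0.5 for any lapse < 0.5
  ind <- data.frame(A = 20, DA = 0, B = 20, DB = 5)
  for (eps in c(0, 0.1, 0.49)) {
    p <- choice_probability(ind, choice_params(log_k = -30, alpha = 1,
                                               epsilon = eps))
    expect_equal(p, 0.5)
  }
  # value difference 2 with alpha 2, eps 0.05: 0.05 + 0.9 * pnorm(1)
  tr <- data.frame(A = 18, DA = 0, B = 20, DB = 5)
  p <- choice_probability(tr, choice_params(log_k = -30, alpha = 2,
                                            epsilon = 0.05))
  expect_equal(p, 0.05 + 0.9 * pnorm(1), tolerance = 1e-6)
  # saturating limit with no lapse
  tr_big <- data.frame(A = 0.001, DA = 0, B = 20, DB = 0.05)
  p <- choice_probability(tr_big, choice_params(log_k = -30, alpha = 0.001,
                                                epsilon = 0))
  expect_equal(p, 1.0)
})

test_that("probabilities are bounded by the lapse and mirror under sign flips", {
  set.seed(4)
  trials <- data.frame(A = runif(50, 1, 20), DA = 0, B = 20,
                       DB = runif(50, 0.1, 365))
  params <- choice_params(log_k = -3, alpha = 1.5, epsilon = 0.07)
  p <- choice_probability(trials, params)
  expect_true(all(p >= 0.07 & p <= 0.93))
  # negating the value difference maps P to 1 - P: with k = 0 the trial
  # below has value difference +8, and its sign-flipped counterpart is the
  # rule evaluated at -8
  t1 <- data.frame(A = 12, DA = 0, B = 20, DB = 3)
  eps <- 0.04
  p_plus <- choice_probability(t1, choice_params(-30, alpha = 3,
                                                 epsilon = eps))
  p_minus <- eps + (1 - 2 * eps) * pnorm(-8 / 3)
  expect_equal(p_plus + p_minus, 1)
})

test_that("choice probability is invariant under joint rescaling of values and acuity", {
  base <- data.frame(A = c(5, 12, 19), DA = 0, B = 20, DB = c(2, 30, 200))
  for (c_scale in c(0.5, 3, 10)) {
    scaled <- transform(base, A = A * c_scale, B = B * c_scale)
    p1 <- choice_probability(base, choice_params(-3, alpha = 1.2,
                                                 epsilon = 0.03))
    p2 <- choice_probability(scaled, choice_params(-3,
                                                   alpha = 1.2 * c_scale,
                                                   epsilon = 0.03))
    expect_equal(p1, p2, tolerance = 1e-12)
  }
})

test_that("simulated responses are reproducible Bernoulli draws with the right rate", {
  tr_big <- data.frame(A = 0.001, DA = 0, B = 20, DB = 0.05)
  params <- choice_params(log_k = -30, alpha = 0.001, epsilon = 0)
  expect_equal(simulate_response(tr_big[rep(1, 50), ], params,
                                 rng_seed = 3L), rep(1L, 50))
  # P = 0.5 trials: empirical mean within binomial standard error bounds
  ind <- data.frame(A = 20, DA = 0, B = 20, DB = 5)
  r <- simulate_response(ind[rep(1, 10000), ],
                         choice_params(-30, 1, 0.1), rng_seed = 11L)
  expect_lt(abs(mean(r) - 0.5), 0.015)
  r2 <- simulate_response(ind[rep(1, 10000), ],
                          choice_params(-30, 1, 0.1), rng_seed = 11L)
  expect_identical(r, r2)
})

test_that("the Bernoulli likelihood prefers the generating log_k", {
  set.seed(21)
  space_delays <- build_delay_grid()
  wins <- replicate(20, {
    true <- choice_params(log_k = runif(1, -5, -1), alpha = 0.5,
                          epsilon = 0.02)
    k <- exp(true$log_k)
    trials <- data.frame(
      DB = sample(space_delays, 35, replace = TRUE), DA = 0, B = 20)
    trials$A <- pmin(20, pmax(0.2, 20 / (1 + k * trials$DB) +
                                runif(35, -3, 3)))
    trials$R <- simulate_response(trials, true,
                                  rng_seed = sample.int(1e6, 1))
    ll_true <- choice_loglik(trials, true)
    ll_lo <- choice_loglik(trials, choice_params(true$log_k - 2, 0.5, 0.02))
    ll_hi <- choice_loglik(trials, choice_params(true$log_k + 2, 0.5, 0.02))
    ll_true > ll_lo & ll_true > ll_hi
  })
  expect_gt(mean(wins), 0.8)
})

test_that("trial invariants are enforced and the CSV dialect round-trips", {
  good <- data.frame(participant = 1L, condition = "control",
                     commodity = "money", trial_index = 1:2,
                     A = c(5, 10), DA = 0, B = 20, DB = c(1, 100),
                     R = c(0L, 1L))
  expect_silent(validate_trials(good))
  expect_error(validate_trials(transform(good, DA = 1)), "DA")
  expect_error(validate_trials(transform(good, DB = 0)), "DB")
  expect_error(validate_trials(transform(good, A = 25)), "exceed")
  expect_error(validate_trials(transform(good, R = 2)), "R")
  expect_error(validate_trials(good[0, ]), "empty")
  expect_error(validate_trials(good[, -5]), "missing")

  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  write_trials(good, path, meta = c(seed = "1", note = "fixture"))
  lines <- readLines(path)
  expect_true(all(startsWith(lines[1:2], "#")))
  back <- read_trials(path)
  expect_equal(back$A, good$A)
  expect_equal(back$R, good$R)
  expect_equal(back$DB, good$DB)
})

test_that("choice parameter validation rejects degenerate values", {
  expect_error(choice_params(-3, alpha = 0, epsilon = 0), "positive")
  expect_error(choice_params(-3, alpha = 1, epsilon = 0.5), "0.5")
  expect_error(choice_params(-3, alpha = 1, epsilon = -0.01), "0.5")
  expect_error(choice_params(NA, alpha = 1, epsilon = 0), "finite")
})
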