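test_that("the delay grid is 19 geometric steps from 1 hour to 1 year", {
  g <- build_delay_grid()
  expect_length(g, 19L)
  expect_equal(g[1], 1 / 24)
  expect_equal(g[19], 365)
  ratios <- g[-1] / g[-19]
  expect_lt(max(abs(ratios - (365 * 24)^(1 / 18))), 1e-9)
})

test_that("design spaces encode the fixed-delayed-reward protocol", {
  sp <- commodity_design_space("food")
  expect_equal(sp$delayed_reward, 10)
  expect_equal(commodity_design_space("money")$delayed_reward, 20)
  expect_equal(commodity_design_space("music")$delayed_reward, 20)
  expect_length(sp$immediate_amounts, 99L)
  expect_equal(sp$immediate_amounts, 10 * (1:99) / 100)
  expect_equal(sp$trials_per_session, 35L)
  expect_error(design_space(0), "positive")
  expect_error(design_space(20, delays = 1:19), "19 strictly increasing")
  expect_error(design_space(20, immediate_amounts = c(1, 25)), "\\(0, B\\]")
})

test_that("trial selection targets the indifference point of a concentrated posterior", {
  set.seed(31)
  draws <- data.frame(log_k = rnorm(300, -3, 0.01),
                      alpha = rep(0.5, 300), epsilon = rep(0.01, 300))
  sp <- commodity_design_space("money")
  des <- select_next_trial(draws, sp)
  k <- exp(-3)
  indiff <- 20 / (1 + k * des$DB)
  # the chosen immediate amount sits near the predicted indifference value
  expect_lt(abs(des$A - indiff), 1)
  p <- choice_probability(des, choice_params(-3, 0.5, 0.01))
  expect_gt(p, 0.2)
  expect_lt(p, 0.8)
})

test_that("an informative candidate beats one that is predictably answered", {
  set.seed(32)
  draws <- data.frame(log_k = rnorm(400, -3, 0.4), alpha = rep(0.5, 400),
                      epsilon = rep(0.01, 400))
  # two immediate amounts: one essentially free money (P ~ 1 under every
  # draw), one near the indifference region of the draws
  sp <- design_space(20, immediate_amounts = c(0.2, 10))
  des <- select_next_trial(draws, sp)
  expect_equal(des$A, 10)
})

test_that("trial selection is deterministic for fixed posterior and seed", {
  set.seed(33)
  draws <- data.frame(log_k = rnorm(600, -2, 0.8),
                      alpha = rexp(600, 1) + 0.1,
                      epsilon = rbeta(600, 1.1, 10.9))
  sp <- commodity_design_space("music")
  d1 <- select_next_trial(draws, sp, rng_seed = 4L)
  d2 <- select_next_trial(draws, sp, rng_seed = 4L)
  expect_identical(d1, d2)
  expect_error(select_next_trial(list(draws = NULL), sp), "no draws")
})

test_that("simulated sessions stay inside the design space and reproduce", {
  sp <- commodity_design_space("food")
  tp <- choice_params(-2, 0.4, 0.02)
  sess <- run_simulated_session(tp, sp, rng_seed = 77L)
  expect_equal(nrow(sess), 35L)
  expect_true(all(sess$B == 10))
  expect_true(all(sess$DA == 0))
  grid <- build_delay_grid()
  expect_true(all(vapply(sess$DB, function(d) min(abs(d - grid)) < 1e-9,
                         logical(1))))
  expect_true(all(sess$A > 0 & sess$A <= sess$B))
  expect_true(all(sess$R %in% c(0L, 1L)))
  expect_silent(validate_trials(sess))
  expect_identical(sess, run_simulated_session(tp, sp, rng_seed = 77L))
})

test_that("adaptive designs beat random designs in precision and error", {
  seeds <- 1:20
  run_pair <- function(seed) {
    true_logk <- runif(1, -4.5, -0.5)
    tp <- choice_params(true_logk, 0.5, 0.02)
    sp <- commodity_design_space("money")
    out <- sapply(c("adaptive", "random"), function(ds) {
      sess <- run_simulated_session(tp, sp, rng_seed = seed * 100L,
                                    design = ds)
      post <- fit_posterior(sess, rng_seed = seed)
      c(sd = stats::sd(post$draws$log_k),
        err = abs(post$point_log_k - true_logk))
    })
    out
  }
  set.seed(55)
  res <- lapply(seeds, run_pair)
  sd_adaptive <- vapply(res, function(r) r["sd", "adaptive"], numeric(1))
  sd_random <- vapply(res, function(r) r["sd", "random"], numeric(1))
  err_adaptive <- vapply(res, function(r) r["err", "adaptive"], numeric(1))
  err_random <- vapply(res, function(r) r["err", "random"], numeric(1))
  expect_lt(median(sd_adaptive), median(sd_random))
  expect_lt(median(err_adaptive), median(err_random))
})
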