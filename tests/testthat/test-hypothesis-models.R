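test_that("the six models carry the published parameter counts and location maps", {
  counts <- c(trait_only = 1L, in_domain = 2L, monetary_fungibility = 2L,
              negative_spillover = 3L, spillover = 3L, state_only = 2L)
  for (nm in names(counts)) {
    m <- hypothesis_model(nm)
    expect_equal(m$n_params, counts[[nm]], info = nm)
  }
  expect_equal(hypothesis_model("trait_only")$locations(NULL), c(0, 0, 0))
  expect_equal(hypothesis_model("in_domain")$locations(1.3), c(1.3, 0, 0))
  expect_equal(hypothesis_model("monetary_fungibility")$locations(0.7),
               c(0.7, 0.7, 0))
  expect_equal(hypothesis_model("negative_spillover")$locations(c(2, 0.4)),
               c(2, -0.4, -0.4))
  # spillover: in-domain change = out-of-domain change + positive excess
  expect_equal(hypothesis_model("spillover")$locations(c(0.5, 1.5)),
               c(2, 0.5, 0.5))
  expect_equal(hypothesis_model("state_only")$locations(0.9),
               c(0.9, 0.9, 0.9))
})

test_that("the Cauchy log-likelihood matches hand-computed densities", {
  m <- delta_fixture(food = c(1, 1), money = c(1, 1), music = c(1, 1))
  # every cell at the location: 6 * log(1/pi)
  expect_equal(cauchy_loglik(m, c(1, 1, 1), 1), 6 * log(1 / pi),
               tolerance = 1e-12)
  # one unit off the location at scale 1: log(1/(2*pi)) per cell
  m2 <- delta_fixture(food = c(2, 2), money = c(2, 2), music = c(2, 2))
  expect_equal(cauchy_loglik(m2, c(1, 1, 1), 1), 6 * log(1 / (2 * pi)),
               tolerance = 1e-12)
  # cell-additivity against dcauchy directly
  m3 <- delta_fixture(food = c(0.3, -1), money = c(2, 0.1),
                      music = c(-0.5, 4))
  loc <- c(0.5, 0.2, -0.1)
  manual <- sum(dcauchy(m3, location = rep(loc, each = 2), scale = 0.7,
                        log = TRUE))
  expect_equal(cauchy_loglik(m3, loc, 0.7), manual, tolerance = 1e-12)
  expect_error(cauchy_loglik(m3, loc, 0), "positive")
  expect_error(cauchy_loglik(m3, c(0, 0), 1), "length 3")
})

test_that("delta tables validate shape and convert between long and matrix form", {
  long <- data.frame(participant = rep(1:3, 3),
                     commodity = rep(c("food", "money", "music"), each = 3),
                     delta_logk = 1:9)
  m <- as_delta_matrix(long)
  expect_equal(dim(m), c(3L, 3L))
  expect_equal(m[, "food"], c(`1` = 1, `2` = 2, `3` = 3))
  expect_error(as_delta_matrix(long[-1, ]), "exactly one value")
  expect_error(as_delta_matrix(transform(long, delta_logk = c(Inf, 2:9))),
               "finite")
  one_p <- long[long$participant == 1, ]
  expect_error(as_delta_matrix(one_p), "2 participants")

  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  write_delta_table(long, path, meta = c(source = "fixture"))
  expect_equal(read_delta_table(path)$delta_logk, long$delta_logk)
})

test_that("the scale-only fit matches a dense one-dimensional grid search", {
  set.seed(41)
  m <- delta_fixture(food = rnorm(6, 1), money = rnorm(6), music = rnorm(6))
  fit <- fit_model_ml(m, "trait_only")
  grid <- exp(seq(log(0.01), log(10), length.out = 20000))
  ll_grid <- vapply(grid, function(s) cauchy_loglik(m, c(0, 0, 0), s),
                    numeric(1))
  expect_equal(fit$LL, max(ll_grid), tolerance = 1e-6)
  expect_equal(unname(fit$ml_params["scale"]), grid[which.max(ll_grid)],
               tolerance = 1e-3)
})

test_that("noiseless spillover data are recovered exactly", {
  m <- delta_fixture(food = rep(2, 6), money = rep(0.5, 6),
                     music = rep(0.5, 6))
  fit <- fit_model_ml(m, "spillover")
  expect_equal(unname(fit$locations), c(2, 0.5, 0.5), tolerance = 1e-3)
  expect_gt(fit$ml_params["food_shift"], fit$ml_params["out_shift"])
})

test_that("nested models respect the likelihood ordering, with boundary equality", {
  set.seed(42)
  for (rep in 1:3) {
    # positive out-of-domain mean change: the negative-spillover drop
    # parameter collapses to its boundary and the fit equals in-domain
    m <- delta_fixture(food = rnorm(12, 1.8, 0.6),
                       money = rnorm(12, 0.5, 0.6),
                       music = rnorm(12, 0.5, 0.6))
    ll <- vapply(c("trait_only", "in_domain", "monetary_fungibility",
                   "negative_spillover", "spillover", "state_only"),
                 function(nm) fit_model_ml(m, nm)$LL, numeric(1))
    expect_true(all(ll["trait_only"] <= ll + 1e-6))
    expect_lte(ll["in_domain"], ll["spillover"] + 1e-6)
    expect_lte(ll["state_only"], ll["spillover"] + 1e-6)
    expect_lte(ll["in_domain"], ll["negative_spillover"] + 1e-6)
    expect_equal(unname(ll["negative_spillover"]), unname(ll["in_domain"]),
                 tolerance = 1e-6)
  }
})

test_that("information criteria reproduce the standard definitions", {
  ic <- information_criteria(-340.17, 3, 50)
  expect_equal(unname(ic["AIC"]), 686.34)
  ic2 <- information_criteria(-347.37, 2, 50)
  expect_equal(unname(ic2["BIC"]), 2 * log(50) + 694.74, tolerance = 1e-9)
  expect_equal(unname(ic2["BIC"]), 702.565, tolerance = 1e-3)
  expect_error(information_criteria(0, 0, 50), "n_params")
  expect_error(information_criteria(0, 1, 1), "n_bic")
  expect_error(information_criteria(NaN, 1, 50), "finite")
})

test_that("model weights normalise exponentiated half-deltas", {
  expect_equal(model_weights(c(100, 100)), c(0.5, 0.5))
  expect_equal(model_weights(c(0, 2)), c(1 / (1 + exp(-1)),
                                         exp(-1) / (1 + exp(-1))),
               tolerance = 1e-4)
  expect_equal(round(model_weights(c(0, 2)), 4), c(0.7311, 0.2689))
  # invariance to a constant shift, normalisation for arbitrary inputs
  set.seed(43)
  ic <- runif(6, 600, 700)
  expect_equal(model_weights(ic), model_weights(ic + 123.4),
               tolerance = 1e-12)
  expect_equal(sum(model_weights(ic)), 1, tolerance = 1e-12)
  expect_error(model_weights(numeric(0)), "nonempty")
  expect_error(model_weights(c(1, Inf)), "finite")
})

test_that("compare_all produces a coherent six-row comparison table", {
  set.seed(44)
  m_spill <- delta_fixture(food = rcauchy(30, 2, 0.4),
                           money = rcauchy(30, 0.6, 0.4),
                           music = rcauchy(30, 0.6, 0.4))
  comp <- compare_all(m_spill)
  expect_equal(comp$model, c("trait_only", "in_domain",
                             "monetary_fungibility", "negative_spillover",
                             "spillover", "state_only"))
  expect_equal(comp$n, c(1L, 2L, 2L, 3L, 3L, 2L))
  expect_equal(min(comp$dAIC), 0)
  expect_equal(min(comp$dBIC), 0)
  expect_equal(sum(comp$wAIC), 1, tolerance = 1e-12)
  expect_equal(sum(comp$wBIC), 1, tolerance = 1e-12)
  expect_equal(comp$model[which.max(comp$wAIC)], "spillover")

  m_null <- delta_fixture(food = rnorm(30, 0, 0.05),
                          money = rnorm(30, 0, 0.05),
                          music = rnorm(30, 0, 0.05))
  comp0 <- compare_all(m_null)
  expect_equal(comp0$model[which.max(comp0$wBIC)], "trait_only")
})

test_that("paired effect size and bootstrap interval behave on hand cases", {
  expect_equal(paired_cohens_d(c(0, 0, 0), c(1, 2, 3)), 2.0)
  expect_equal(paired_cohens_d(c(1, -1), c(0, 0)), 0)
  expect_error(paired_cohens_d(1:3, 1:3), "zero variance")
  expect_error(paired_cohens_d(1:3, 1:2), "paired")

  expect_equal(unname(bootstrap_mean_ci(rep(3, 10), n_boot = 1000L)),
               c(3, 3))
  ci1 <- bootstrap_mean_ci(c(1, 2, 5, 9), rng_seed = 6L)
  expect_identical(ci1, bootstrap_mean_ci(c(1, 2, 5, 9), rng_seed = 6L))
  set.seed(45)
  x <- rnorm(50)
  ci <- bootstrap_mean_ci(x, level = 0.95, n_boot = 4000L, rng_seed = 2L)
  width <- ci["high"] - ci["low"]
  expect_lt(abs(width - 2 * 1.96 / sqrt(50)), 0.25 * 2 * 1.96 / sqrt(50))
  expect_gte(mean(x), ci["low"])
  expect_lte(mean(x), ci["high"])
  expect_error(bootstrap_mean_ci(c(1, 2), n_boot = 10L), "1000")
})

test_that("the spillover ratio is the out-of-domain share of the food effect", {
  expect_equal(spillover_ratio(delta_fixture(rep(2, 4), rep(0.5, 4),
                                             rep(0.5, 4))), 25.0)
  expect_equal(spillover_ratio(delta_fixture(rep(1.2, 4), rep(1.2, 4),
                                             rep(1.2, 4))), 100.0)
  expect_equal(spillover_ratio(delta_fixture(rep(2, 4), rep(0, 4),
                                             rep(0, 4))), 0.0)
  expect_error(spillover_ratio(delta_fixture(c(-1, 1), c(1, 1), c(1, 1))),
               "zero")
})
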