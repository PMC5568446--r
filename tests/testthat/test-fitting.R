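test_that("likelihood replay matches the brute-force oracle", {
  # exhaustive small-dataset check across models, feedback regimes and
  # random parameter draws
  set.seed(21)
  for (feedback in c("complete", "partial")) {
    for (i in 1:8) {
      dat <- make_tiny_dataset(n_trials = sample(3:10, 1),
                               seed = 100 + i, feedback = feedback)
      beta <- runif(1, 0, 8)
      al <- runif(4, 0, 1)
      piw <- runif(1, -2, 2)
      expect_equal(
        negative_log_likelihood(dat, "Full", c(beta, al)),
        oracle_nll(dat, beta, al[1], al[2], al[3], al[4]),
        tolerance = 1e-12)
      expect_equal(
        negative_log_likelihood(
          dat, "Perseveration",
          c(beta = beta, alpha_c = al[1], alpha_u = al[2], pi = piw)),
        oracle_nll(dat, beta, al[1], al[1], al[2], al[2], piw),
        tolerance = 1e-12)
    }
  }
})

test_that("a chance-level model yields n * log(2) and nll is monotone", {
  d <- default_design(seed = 1)
  dat <- simulate_agent("One", c(3, 0.3), d, seed = 3)
  expect_equal(negative_log_likelihood(dat, "One", c(0, 0.3)), 192 * log(2))
  nll_half <- negative_log_likelihood(dat[1:96, ], "One", c(3, 0.3))
  expect_gte(negative_log_likelihood(dat, "One", c(3, 0.3)), nll_half)
  expect_gte(nll_half, 0)
  expect_error(negative_log_likelihood(dat[, setdiff(names(dat), "choice")],
                                       "One", c(3, 0.3)),
               "missing column")
})

test_that("bic follows its closed form", {
  expect_equal(bic(100, 192, 3), 3 * log(192) + 200)
  expect_equal(bic(0, 10, 0), 0)
  expect_equal(bic(50, 192, 4) - bic(50, 192, 3), log(192))
  expect_error(bic(10, 0, 2))
})

test_that("log-posterior adds the stated priors to the log-likelihood", {
  dat <- make_tiny_dataset(n_trials = 10, seed = 5)
  free <- c(beta = 3, alpha_con = 0.4, alpha_dis = 0.2)
  lp <- log_posterior(dat, "Confirmation", free)
  expect_equal(lp,
               -negative_log_likelihood(dat, "Confirmation", free) +
                 dgamma(3, shape = 1.2, scale = 5, log = TRUE) +
                 sum(dbeta(c(0.4, 0.2), 1.1, 1.1, log = TRUE)))
  # Beta(1.1, 1.1) is maximal at 1/2 and vanishes at the boundary
  expect_equal(log_posterior(dat, "Confirmation", c(3, 0, 0.2)), -Inf)
  lp_mid <- log_posterior(dat, "One", c(3, 0.5))
  grid <- seq(0.01, 0.99, 0.01)
  dens <- dbeta(grid, 1.1, 1.1)
  expect_equal(grid[which.max(dens)], 0.5)
  # flat prior on the perseveration weight
  f1 <- c(beta = 2, alpha_c = .3, alpha_u = .3, pi = 0.5)
  f2 <- c(beta = 2, alpha_c = .3, alpha_u = .3, pi = 3)
  expect_equal(
    log_posterior(dat, "Perseveration", f1) -
      log_posterior(dat, "Perseveration", f2),
    -negative_log_likelihood(dat, "Perseveration", f1) +
      negative_log_likelihood(dat, "Perseveration", f2))
})

test_that("MLE fits recover generating parameters and respect nesting", {
  cfg <- task_config()
  opts <- fit_options(n_restarts = 5, seed = 2)
  set.seed(31)
  seeds <- sample.int(1e6, 12)
  a_hat <- vapply(seeds, function(s) {
    dat <- simulate_agent("One", c(5, 0.3), build_schedule(cfg, s), seed = s)
    fit_mle(dat, "One", opts)$free[["alpha"]]
  }, 0)
  expect_lt(abs(mean(a_hat) - 0.3), 0.05)
  # nesting: the Full model can never fit worse than a tied submodel
  dat <- simulate_agent("One", c(5, 0.3), build_schedule(cfg, 77), seed = 77)
  f_one <- fit_mle(dat, "One", opts)
  f_full <- fit_mle(dat, "Full", opts)
  expect_lte(f_full$nll, f_one$nll + 1e-4)
  # fitted nll beats the generating parameters (optimizer sanity)
  expect_lte(f_one$nll,
             negative_log_likelihood(dat, "One", c(5, 0.3)) + 1e-6)
  # determinism and invariants of the result object
  expect_equal(fit_mle(dat, "One", opts)$free, f_one$free)
  expect_equal(f_one$bic, log(192) * 2 + 2 * f_one$nll)
  expect_true(f_one$converged)
})

test_that("MAP estimates stay interior and shrink relative to MLE", {
  cfg <- task_config()
  opts <- fit_options(n_restarts = 5, seed = 3)
  set.seed(41)
  seeds <- sample.int(1e6, 8)
  ests <- t(vapply(seeds, function(s) {
    dat <- simulate_agent("One", c(6, 0.95), build_schedule(cfg, s), seed = s)
    c(mle = fit_mle(dat, "One", opts)$free[["alpha"]],
      map = fit_map(dat, "One", opts)$free[["alpha"]])
  }, c(mle = 0, map = 0)))
  expect_true(all(ests[, "map"] > 0.001 & ests[, "map"] < 0.999))
  # prior pulls extreme rates toward 0.5
  expect_lte(mean(ests[, "map"]), mean(ests[, "mle"]))
  # MAP is deterministic given the seed
  dat <- simulate_agent("One", c(6, 0.5), build_schedule(cfg, 9), seed = 9)
  expect_equal(fit_map(dat, "One", opts)$free,
               fit_map(dat, "One", opts)$free)
})

test_that("per-condition fits partition the data", {
  dat <- simulate_agent("Confirmation", c(4, .4, .15),
                        default_design(seed = 4), seed = 4)
  fits <- fit_per_condition(dat, "Confirmation",
                            fit_options(n_restarts = 3, seed = 1))
  expect_named(fits, c("Asymmetric", "Reversal", "Symmetric"))
  expect_equal(sum(vapply(fits, `[[`, 0, "n_trials")), 192)
  expect_equal(fits$Asymmetric$n_trials, 96)
  expect_error(fit_per_condition(dat[0, ], "One"), "empty")
})
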