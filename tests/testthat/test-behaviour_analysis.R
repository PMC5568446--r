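# hand-built two-option dataset helper: one Symmetric instance with a
# prescribed choice sequence
make_choice_data <- function(choices, label = "Symmetric",
                             p_a = 0.5, p_b = 0.5) {
  n <- length(choices)
  data.frame(subject = 1, session = 1, context_label = label,
             context_instance = paste0("s1.", label, ".1"),
             context_trial = seq_len(n), choice = choices,
             outcome_chosen = rep(1, n), outcome_unchosen = rep(-1, n),
             p_a = p_a, p_b = p_b, stringsAsFactors = FALSE)
}

test_that("preferred choice rate counts the modal option", {
  d <- make_choice_data(rep(c("A", "B"), times = c(28, 20)))
  expect_equal(as.numeric(preferred_choice_rate(d)), 28 / 48)
  expect_equal(as.numeric(preferred_choice_rate(
    make_choice_data(rep("B", 10)))), 1)
  tie <- preferred_choice_rate(make_choice_data(rep(c("A", "B"), 5)))
  expect_equal(as.numeric(tie), 0.5)
  expect_true(attr(tie, "tie"))
  expect_gte(as.numeric(preferred_choice_rate(d)), 0.5)
  expect_error(preferred_choice_rate(make_choice_data("A", label = "Reversal",
                                                      p_a = .83, p_b = .17)),
               "Symmetric")
})

test_that("correct choice rate respects the contingency in force", {
  d <- make_choice_data(rep(c("A", "B"), times = c(18, 6)),
                        label = "Asymmetric", p_a = 0.75, p_b = 0.25)
  expect_equal(correct_choice_rate(d, "Asymmetric"), 0.75)
  expect_error(correct_choice_rate(d, "Symmetric"))
  expect_error(correct_choice_rate(make_choice_data(rep("A", 4)),
                                   "Asymmetric"), "no Asymmetric")
  # reversal: correct option flips with the schedule
  rev <- make_choice_data(rep("A", 24), label = "Reversal")
  rev$p_a <- c(rep(0.83, 12), rep(0.17, 12))
  rev$p_b <- c(rep(0.17, 12), rep(0.83, 12))
  expect_equal(correct_choice_rate(rev, "Reversal", "first_half"), 1)
  expect_equal(correct_choice_rate(rev, "Reversal", "second_half"), 0)
  expect_equal(correct_choice_rate(rev, "Reversal", "all"), 0.5)
  # equal probabilities have no correct option
  expect_error(correct_choice_rate(make_choice_data(rep("A", 4),
                                                    label = "Asymmetric"),
                                   "Asymmetric"), "no correct option")
})

test_that("normalised bias indices follow their closed forms", {
  expect_equal(normalized_bias(parameter_set(5, 0.3, 0.3), 1), 0)
  expect_equal(normalized_bias(parameter_set(5, 0.6, 0.2), 1), 0.5)
  # pure confirmation pattern scores 1 on the experiment-2 index
  p <- parameter_set(5, 0.4, 0, 0, 0.4)
  expect_equal(normalized_bias(p, 2), 1)
  # pure disconfirmation pattern scores -1
  expect_equal(normalized_bias(parameter_set(5, 0, 0.4, 0.4, 0), 2), -1)
  # printed variant uses the counterfactual sum in the numerator
  p2 <- parameter_set(5, 0.4, 0.2, 0.1, 0.3)
  expect_equal(normalized_bias(p2, 2, form = "printed"),
               ((0.4 - 0.2) - (0.1 + 0.3)) / 1.0)
  expect_warning(nb <- normalized_bias(parameter_set(5, 0, 0), 1),
                 "denominator")
  expect_true(is.na(nb))
})

test_that("median split is balanced, rank-invariant and flags degeneracy", {
  x <- c(5, 1, 9, 3, 7, 2, 8, 4, 10, 6, 11, 0, 12, 13, 15, 14, 16, 17, 19, 18)
  g <- median_split(x)
  expect_equal(as.vector(table(g)), c(10, 10))
  expect_identical(median_split(exp(x)), g)  # monotone transform
  expect_warning(gd <- median_split(rep(1, 4)), "degenerate")
  expect_true(all(gd == "low"))
  expect_error(median_split(1), "2 subjects")
})

test_that("model estimate curves track the replayed probabilities", {
  d <- default_design(seed = 5)
  dat <- simulate_agent("Confirmation", c(4, 0.45, 0.1), d, seed = 5)
  cc <- model_estimate_curves(dat, "Confirmation",
                              list(biased = c(4, 0.45, 0.1),
                                   unbiased = c(4, 0.275, 0.275)))
  expect_s3_class(cc, "curve_comparison")
  expect_equal(nrow(cc), 192)
  expect_true(all(cc$pred_biased > 0 & cc$pred_biased < 1))
  expect_true(all(cc$observed %in% c(0, 1)))
  expect_true(all(cc$context_trial %in% 1:24))
  expect_false(identical(cc$pred_biased, cc$pred_unbiased))
  # deterministic given data + params
  cc2 <- model_estimate_curves(dat, "Confirmation",
                               list(biased = c(4, 0.45, 0.1),
                                    unbiased = c(4, 0.275, 0.275)))
  expect_identical(cc, cc2)
})

test_that("curve squared distance has its closed-form anchors", {
  d <- make_choice_data(rep("A", 24))
  cc <- model_estimate_curves(d, "One", c(0, 0.3))  # constant p = 0.5
  expect_equal(unname(curve_squared_distance(cc)), 0.25)
  # rate 1 + extreme scaling predicts a constant rewarded sequence
  # perfectly from trial 2; only the chance-level first trial contributes
  d2 <- make_choice_data(rep("A", 24))
  d2$outcome_chosen <- rep(1, 24)
  cc2 <- model_estimate_curves(d2, "One", c(100, 1))
  expect_equal(unname(curve_squared_distance(cc2)), 0.25 / 24,
               tolerance = 1e-8)
  expect_gte(min(curve_squared_distance(cc)), 0)
})

test_that("behavioural signatures separate high- from low-bias cohorts", {
  # matched confirmation-biased vs unbiased agents (same scaling, seeds)
  cfg <- task_config()
  n <- 14
  sum_of <- function(free) {
    dats <- lapply(seq_len(n), function(i) {
      simulate_agent("Confirmation", free, build_schedule(cfg, 300 + i),
                     seed = 300 + i, subject = i)
    })
    behavioural_summary(do.call(rbind, dats))
  }
  biased <- sum_of(c(5, 0.45, 0.08))
  unbiased <- sum_of(c(5, 0.265, 0.265))
  # higher preferred rate in Symmetric, worse post-reversal accuracy
  expect_gt(mean(biased$preferred_choice_rate),
            mean(unbiased$preferred_choice_rate))
  expect_lt(mean(biased$correct_reversal_second),
            mean(unbiased$correct_reversal_second))
  # complete feedback beats matched partial feedback in the Asymmetric
  # condition (counterfactual information advantage)
  cfg_p <- task_config(feedback = "partial")
  dats_p <- lapply(seq_len(n), function(i) {
    simulate_agent("Confirmation", c(5, 0.45, 0.08),
                   build_schedule(cfg_p, 300 + i), seed = 300 + i,
                   subject = i)
  })
  partial <- behavioural_summary(do.call(rbind, dats_p))
  expect_gt(mean(biased$correct_asymmetric), mean(partial$correct_asymmetric))
})

test_that("MAP bias indices recover the generating asymmetry sign", {
  cfg <- task_config()
  opts <- fit_options(n_restarts = 4, seed = 7)
  n <- 12
  signs <- vapply(seq_len(n), function(i) {
    s <- 500 + i
    dat <- simulate_agent("Confirmation", c(5, 0.45, 0.15),
                          build_schedule(cfg, s), seed = s)
    f <- fit_map(dat, "Confirmation", opts)
    sign(normalized_bias(f$params, 2))
  }, 0)
  expect_gte(mean(signs > 0), 0.9)
})

test_that("cohort CSV round-trips through the flat-file interface", {
  ch <- make_virtual_cohort("biased", 3, task_config(feedback = "partial"),
                            seed = 4)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(ch$data, path)
  back <- read_cohort(path)
  expect_equal(back, ch$data, ignore_attr = TRUE)
  expect_true(all(is.na(back$outcome_unchosen)))
})
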