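#' Simulate one agent on a materialised task
#'
#' Plays the schedule trial by trial: choices are drawn from the softmax
#' rule (with the perseveration bonus when `pi != 0`), the chosen option's
#' value is updated from the obtained outcome, and — under complete
#' feedback — the unchosen option's value from the forgone outcome.  Under
#' partial feedback the counterfactual module is inert (not an error) and
#' the forgone outcome is withheld from the returned dataset.  Q-values
#' start at 0 for every context instance (fresh stimuli each session).
#'
#' @param model A [model_spec()] or model name.
#' @param params A [parameter_set()] or a free-parameter vector for
#'   `model`.
#' @param design A [build_schedule()] result.
#' @param outcomes An outcome table from [draw_outcomes()]; drawn from
#'   `design` if omitted (seeded from `seed`).
#' @param seed Integer seed for the choice randomness.
#' @param subject Subject identifier stored in the output.
#' @return A data frame (one row per trial, in presentation order) with
#'   columns `subject`, `session`, `context_label`, `context_instance`,
#'   `context_trial`, `choice` ("A"/"B"), `outcome_chosen`,
#'   `outcome_unchosen` (NA under partial feedback), `p_a`, `p_b`.
#' @examples
#' d <- build_schedule(seed = 1)
#' dat <- simulate_agent("Confirmation", c(3, 0.4, 0.1), d, seed = 2)
#' @export
simulate_agent <- function(model, params, design, outcomes = NULL,
                           seed = 1L, subject = 1L) {
  if (is.character(model)) model <- model_spec(model)
  if (!inherits(params, "parameter_set")) {
    params <- resolve_parameters(model, params)
  }
  stopifnot(inherits(design, "task_design"))
  if (is.null(outcomes)) outcomes <- draw_outcomes(design, seed = seed)
  set.seed(as.integer(seed) + 1L)
  complete <- design$config$feedback == "complete"
  n <- nrow(outcomes)
  inst <- outcomes$context_instance
  q_a <- q_b <- new.env(parent = emptyenv())
  q <- new.env(parent = emptyenv())     # per-instance c(Q_A, Q_B)
  prev <- new.env(parent = emptyenv())  # per-instance previous choice
  choice <- character(n)
  r_c <- numeric(n)
  r_u <- rep(NA_real_, n)
  u <- stats::runif(n)
  for (t in seq_len(n)) {
    id <- inst[t]
    qs <- if (is.null(q[[id]])) c(0, 0) else q[[id]]
    b_a <- b_b <- 0
    if (!is.null(prev[[id]])) {
      if (prev[[id]] == "A") b_a <- params$pi else b_b <- params$pi
    }
    p_choose_a <- choice_probability(qs[1], qs[2], params$beta, b_a, b_b)
    ch <- if (u[t] < p_choose_a) "A" else "B"
    choice[t] <- ch
    rc <- if (ch == "A") outcomes$outcome_a[t] else outcomes$outcome_b[t]
    ru <- if (ch == "A") outcomes$outcome_b[t] else outcomes$outcome_a[t]
    r_c[t] <- rc
    if (complete) r_u[t] <- ru
    ci <- if (ch == "A") 1L else 2L
    ui <- 3L - ci
    qs[ci] <- factual_update(qs[ci], rc, params$alpha_c_plus,
                             params$alpha_c_minus)$value
    if (complete) {
      qs[ui] <- counterfactual_update(qs[ui], ru, params$alpha_u_plus,
                                      params$alpha_u_minus)$value
    }
    q[[id]] <- qs
    prev[[id]] <- ch
  }
  data.frame(subject = subject,
             session = outcomes$session,
             context_label = outcomes$context_label,
             context_instance = inst,
             context_trial = outcomes$context_trial,
             choice = choice,
             outcome_chosen = r_c,
             outcome_unchosen = r_u,
             p_a = outcomes$p_a, p_b = outcomes$p_b,
             stringsAsFactors = FALSE)
}

# discrete generating profiles: Full-model learning-rate slots
# (chosen+, chosen-, unchosen+, unchosen-) at softmax scaling 5
.profile_params <- function(profile) {
  switch(profile,
    unbiased     = parameter_set(5, 0.30, 0.30, 0.30, 0.30),
    `semi-biased` = parameter_set(5, 0.45, 0.15, 0.30, 0.30),
    # confirmation pattern: fast for choice-confirming events
    biased       = parameter_set(5, 0.45, 0.15, 0.15, 0.45),
    stop("unknown bias profile: ", profile, call. = FALSE)
  )
}

#' Simulate a cohort of virtual subjects
#'
#' Generates `n_subjects` datasets plus the table of generating
#' parameters, for recovery scoring.  The `"empirical-like"` profile
#' draws each subject's parameters from the fitting priors (learning
#' rates `Beta(1.1, 1.1)`, softmax scaling `Gamma(shape 1.2, scale 5)`)
#' under `model`'s tying map; the discrete profiles (`"unbiased"`,
#' `"semi-biased"`, `"biased"`) use fixed Full-model rates (0.30/0.30,
#' 0.45/0.15 with the counterfactual pattern for `"biased"`) at scaling 5.
#' Every subject receives a fresh schedule interleaving, outcome draw and
#' choice stream from a distinct derived seed.
#'
#' @param bias_profile One of `"empirical-like"`, `"unbiased"`,
#'   `"semi-biased"`, `"biased"`.
#' @param n_subjects Number of virtual subjects (`>= 2`).
#' @param design A [build_schedule()] result or a [task_config()] (a new
#'   interleaving is drawn per subject from a `task_config`).
#' @param seed Master seed; per-subject substreams are derived from it.
#' @param model Generating model for `"empirical-like"` draws (default
#'   `"Confirmation"`); ignored by the discrete profiles.
#' @return List with `data` (row-bound datasets, one subject per
#'   `subject` value) and `params` (data frame of generating parameters:
#'   `subject`, the model's free parameters, and the four resolved
#'   learning-rate slots).
#' @export
make_virtual_cohort <- function(bias_profile = c("empirical-like", "unbiased",
                                                 "semi-biased", "biased"),
                                n_subjects, design, seed = 1L,
                                model = "Confirmation") {
  bias_profile <- match.arg(bias_profile)
  if (n_subjects < 2L) {
    stop("need at least 2 subjects (correlations undefined otherwise)",
         call. = FALSE)
  }
  if (is.character(model)) model <- model_spec(model)
  set.seed(as.integer(seed))
  sub_seeds <- sample.int(.Machine$integer.max - 1L, n_subjects)
  dats <- vector("list", n_subjects)
  rows <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    if (bias_profile == "empirical-like") {
      n_alpha <- model$df - 1L - (model$name == "Perseveration")
      free <- c(stats::rgamma(1, shape = 1.2, scale = 5),
                stats::rbeta(n_alpha, 1.1, 1.1))
      if (model$name == "Perseveration") free <- c(free, 0)
      names(free) <- model$free
      ps <- resolve_parameters(model, free)
    } else {
      ps <- .profile_params(bias_profile)
      free <- NULL
    }
    des <- if (inherits(design, "task_config")) {
      build_schedule(design, seed = sub_seeds[i])
    } else design
    dats[[i]] <- simulate_agent(model, ps, des, seed = sub_seeds[i],
                                subject = i)
    row <- data.frame(subject = i, as.list(unlist(ps)),
                      stringsAsFactors = FALSE)
    if (!is.null(free)) {
      extra <- free[setdiff(names(free), names(row))]
      if (length(extra)) row <- cbind(row, as.data.frame(as.list(extra)))
    }
    rows[[i]] <- row
  }
  list(data = do.call(rbind, dats), params = do.call(rbind, rows))
}

#' Split a stacked cohort into per-subject datasets
#'
#' @param data A stacked cohort data frame (as from
#'   [make_virtual_cohort()] or [read_cohort()]).
#' @return Named list of single-subject data frames.
#' @export
split_subjects <- function(data) {
  split(data, data$subject)
}
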