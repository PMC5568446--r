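#' @useDynLib rlbias, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# validate a dataset and order it for replay: grouped by context instance,
# ordered by context trial (value updates and the perseveration state are
# local to a context instance, so replay order across instances is free)
.replay_vectors <- function(data) {
  need <- c("context_instance", "context_trial", "choice",
            "outcome_chosen", "outcome_unchosen")
  miss <- setdiff(need, names(data))
  if (length(miss)) {
    stop("malformed dataset, missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (!nrow(data)) stop("empty dataset", call. = FALSE)
  if (!all(data$choice %in% c("A", "B"))) {
    stop("malformed dataset: choice must be 'A' or 'B'", call. = FALSE)
  }
  ord <- order(data$context_instance, data$context_trial)
  d <- data[ord, , drop = FALSE]
  list(instance = as.integer(factor(d$context_instance)),
       choice = as.integer(d$choice == "B"),
       r_c = as.numeric(d$outcome_chosen),
       r_u = as.numeric(d$outcome_unchosen),
       order = ord)
}

#' Negative log-likelihood of a dataset under a model
#'
#' Replays the value updates over the observed choice/outcome sequence
#' and sums `-log` of the softmax probability of each observed choice.
#' Both updates run when the forgone outcome is present (complete
#' feedback); only the factual one when it is `NA`.
#'
#' @param data A single-subject dataset (see [simulate_agent()]).
#' @param model A [model_spec()] or model name.
#' @param params A [parameter_set()] or free-parameter vector for `model`.
#' @return Nonnegative negative log-likelihood.
#' @examples
#' d <- build_schedule(seed = 1)
#' dat <- simulate_agent("One", c(5, 0.3), d, seed = 2)
#' negative_log_likelihood(dat, "One", c(5, 0.3))
#' @export
negative_log_likelihood <- function(data, model, params) {
  if (is.character(model)) model <- model_spec(model)
  if (!inherits(params, "parameter_set")) {
    params <- resolve_parameters(model, params)
  }
  v <- .replay_vectors(data)
  nll_replay_cpp(v$instance, v$choice, v$r_c, v$r_u,
                 params$beta, params$alpha_c_plus, params$alpha_c_minus,
                 params$alpha_u_plus, params$alpha_u_minus, params$pi)
}

# free-parameter values implied by a resolved parameter set
.free_from_params <- function(model, p) {
  f <- switch(model$name,
    Full = c(p$beta, p$alpha_c_plus, p$alpha_c_minus,
             p$alpha_u_plus, p$alpha_u_minus),
    Information = c(p$beta, p$alpha_c_plus, p$alpha_u_plus),
    Valence = c(p$beta, p$alpha_c_plus, p$alpha_c_minus),
    Confirmation = c(p$beta, p$alpha_c_plus, p$alpha_c_minus),
    Perseveration = c(p$beta, p$alpha_c_plus, p$alpha_u_plus, p$pi),
    One = c(p$beta, p$alpha_c_plus)
  )
  stats::setNames(f, model$free)
}

# log prior density at a free-parameter vector: Gamma(shape 1.2, scale 5)
# on the softmax scaling, Beta(1.1, 1.1) on every free learning rate,
# improper flat prior on the perseveration weight
.log_prior <- function(model, free) {
  alphas <- free[grep("^alpha", model$free)]
  stats::dgamma(free[["beta"]], shape = 1.2, scale = 5, log = TRUE) +
    sum(stats::dbeta(alphas, 1.1, 1.1, log = TRUE))
}

#' Log-posterior objective (log-likelihood plus log prior)
#'
#' The maximum a posteriori objective: the replayed log-likelihood plus
#' the log prior density, with `Gamma(shape 1.2, scale 5)` on the softmax
#' scaling, `Beta(1.1, 1.1)` on every free learning rate (the same prior
#' for all rates, so rate comparisons are unbiased) and a flat prior on
#' the perseveration weight.  `-Inf` when a learning rate sits exactly on
#' 0 or 1 (the Beta(1.1, 1.1) density vanishes there).
#'
#' @inheritParams negative_log_likelihood
#' @return The log-posterior value (to be maximised).
#' @export
log_posterior <- function(data, model, params) {
  if (is.character(model)) model <- model_spec(model)
  if (inherits(params, "parameter_set")) {
    free <- .free_from_params(model, params)
  } else {
    free <- .free_from_params(model, resolve_parameters(model, params))
  }
  -negative_log_likelihood(data, model, free) + .log_prior(model, free)
}

#' Bayesian Information Criterion
#'
#' `log(n_trials) * df + 2 * nll` (natural logarithm).
#'
#' @param nll Negative log-likelihood at the optimum.
#' @param n_trials Number of trials entering the likelihood.
#' @param df Number of free parameters.
#' @return BIC value.
#' @examples
#' bic(100, 192, 3)  # 3 * log(192) + 200
#' @export
bic <- function(nll, n_trials, df) {
  stopifnot(n_trials >= 1, df >= 0)
  log(n_trials) * df + 2 * nll
}

#' Optimiser options for model fitting
#'
#' @param n_restarts Random interior starting points per fit (the
#'   asymmetric-rate likelihoods can be multimodal).
#' @param seed Seed for the starting points.
#' @param beta_max Practical upper bound on the softmax scaling (the
#'   theoretical range is unbounded).
#' @param pi_max Bound on the perseveration weight, `[-pi_max, pi_max]`.
#' @param maxit Iteration cap per `optim` run.
#' @return List of class `"fit_options"`.
#' @export
fit_options <- function(n_restarts = 10L, seed = 1L, beta_max = 100,
                        pi_max = 10, maxit = 500L) {
  structure(list(n_restarts = as.integer(n_restarts),
                 seed = as.integer(seed), beta_max = beta_max,
                 pi_max = pi_max, maxit = as.integer(maxit)),
            class = "fit_options")
}

.fit_bounds <- function(model, options, objective) {
  eps <- if (objective == "map") 1e-3 else 0
  lower <- upper <- numeric(model$df)
  for (i in seq_len(model$df)) {
    nm <- model$free[i]
    if (nm == "beta") {
      lower[i] <- if (objective == "map") 1e-4 else 0
      upper[i] <- options$beta_max
    } else if (nm == "pi") {
      lower[i] <- -options$pi_max
      upper[i] <- options$pi_max
    } else {
      lower[i] <- eps
      upper[i] <- 1 - eps
    }
  }
  list(lower = lower, upper = upper)
}

.fit <- function(data, model, options, objective) {
  if (is.character(model)) model <- model_spec(model)
  stopifnot(inherits(options, "fit_options"))
  v <- .replay_vectors(data)
  alpha_idx <- grep("^alpha", model$free)
  has_pi <- "pi" %in% model$free
  obj <- function(free) {
    names(free) <- model$free
    p <- resolve_parameters(model, free)
    nll <- nll_replay_cpp(v$instance, v$choice, v$r_c, v$r_u,
                          p$beta, p$alpha_c_plus, p$alpha_c_minus,
                          p$alpha_u_plus, p$alpha_u_minus, p$pi)
    if (objective == "map") nll - .log_prior(model, free) else nll
  }
  b <- .fit_bounds(model, options, objective)
  set.seed(options$seed)
  best <- NULL
  n_conv <- 0L
  for (r in seq_len(options$n_restarts)) {
    start <- numeric(model$df)
    start[1] <- stats::runif(1, 0.1, 10)                # beta
    start[alpha_idx] <- stats::runif(length(alpha_idx), 0.05, 0.95)
    if (has_pi) start[model$df] <- stats::runif(1, -1, 1)
    res <- tryCatch(
      stats::optim(start, obj, method = "L-BFGS-B",
                   lower = b$lower, upper = b$upper,
                   control = list(maxit = options$maxit)),
      error = function(e) NULL
    )
    if (is.null(res)) next
    if (res$convergence == 0) n_conv <- n_conv + 1L
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best)) {
    stop("all optimiser restarts failed for model ", model$name,
         call. = FALSE)
  }
  free <- stats::setNames(best$par, model$free)
  params <- resolve_parameters(model, free)
  nll <- negative_log_likelihood(data, model, params)
  structure(list(model = model$name, free = free, params = params,
                 nll = nll,
                 lpp = -nll + .log_prior(model, free),
                 bic = bic(nll, nrow(data), model$df),
                 n_trials = nrow(data), df = model$df,
                 objective = objective,
                 converged = n_conv > 0L, n_converged = n_conv,
                 n_restarts = options$n_restarts),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("%s fit of '%s' (%d trials): nll = %.2f, BIC = %.2f%s\n",
              toupper(x$objective), x$model, x$n_trials, x$nll, x$bic,
              if (!x$converged) " [NOT CONVERGED]" else ""))
  print(round(x$free, 4))
  invisible(x)
}

#' Maximum-likelihood fit of one subject
#'
#' Bounded multi-restart minimisation of the negative log-likelihood
#' (learning rates in `[0, 1]`, softmax scaling in `[0, beta_max]`).
#' Deterministic given identical data, seed and options.  If no restart
#' reports convergence the result is flagged (`converged = FALSE`), not
#' silently dropped.
#'
#' @param data A single-subject dataset.
#' @param model A [model_spec()] or model name.
#' @param options A [fit_options()] list.
#' @return A `"fit_result"` with the fitted parameters, `nll`, `lpp`,
#'   `bic`, and optimiser diagnostics.
#' @export
fit_mle <- function(data, model, options = fit_options()) {
  .fit(data, model, options, "mle")
}

#' Maximum a posteriori fit of one subject
#'
#' As [fit_mle()] but maximising the log-posterior of [log_posterior()];
#' the priors keep the learning-rate estimates off the 0/1 boundary, so
#' these estimates are the ones used for learning-rate analyses.
#'
#' @inheritParams fit_mle
#' @return A `"fit_result"`.
#' @export
fit_map <- function(data, model, options = fit_options()) {
  .fit(data, model, options, "map")
}

#' Fit each task condition separately
#'
#' Control analysis: independent fits on the Symmetric, Asymmetric and
#' Reversal subsets of one subject's data.
#'
#' @inheritParams fit_mle
#' @param objective `"mle"` or `"map"`.
#' @return Named list of `"fit_result"` objects, one per condition
#'   present in the data.
#' @export
fit_per_condition <- function(data, model, options = fit_options(),
                              objective = c("map", "mle")) {
  objective <- match.arg(objective)
  if (!nrow(data)) stop("empty dataset", call. = FALSE)
  parts <- split(data, data$context_label)
  if (any(!vapply(parts, nrow, 0L))) {
    stop("empty condition partition", call. = FALSE)
  }
  lapply(parts, function(d) .fit(d, model, options, objective))
}

#' Fit several models to every subject of a cohort
#'
#' @param data A stacked cohort data frame.
#' @param models Character vector of model names (default: all six).
#' @param objective `"mle"` (used for BIC-based model comparison) or
#'   `"map"` (used for learning-rate analyses).
#' @param options A [fit_options()] list; each subject/model fit derives
#'   its restart seed from `options$seed`.
#' @return Data frame with one row per subject and model: resolved
#'   learning-rate slots, `nll`, `lpp`, `bic`, `df`, `n_trials`,
#'   `converged`.
#' @export
fit_cohort <- function(data, models = model_names(),
                       objective = c("mle", "map"),
                       options = fit_options()) {
  objective <- match.arg(objective)
  subs <- split_subjects(data)
  rows <- list()
  for (s in names(subs)) {
    for (m in models) {
      opt <- options
      # distinct but reproducible restart seed per subject/model cell
      opt$seed <- (options$seed + 7919L * match(m, model_names()) +
                     31L * as.integer(s)) %% .Machine$integer.max
      f <- .fit(subs[[s]], m, opt, objective)
      rows[[length(rows) + 1L]] <- data.frame(
        subject = subs[[s]]$subject[1], model = m,
        beta = f$params$beta,
        alpha_c_plus = f$params$alpha_c_plus,
        alpha_c_minus = f$params$alpha_c_minus,
        alpha_u_plus = f$params$alpha_u_plus,
        alpha_u_minus = f$params$alpha_u_minus,
        pi = f$params$pi,
        nll = f$nll, lpp = f$lpp, bic = f$bic,
        df = f$df, n_trials = f$n_trials, converged = f$converged,
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}
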