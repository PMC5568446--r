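#' Define a single choice context
#'
#' A context is a fixed pair of cues with per-option reward probabilities.
#' Outcomes are +1 ("winning a point") with the scheduled probability and
#' -1 otherwise, independently for the two options on every trial.
#'
#' @param label Condition label: `"Symmetric"`, `"Asymmetric"` or
#'   `"Reversal"`.
#' @param p_a,p_b Reward probability of option A and option B, in `[0, 1]`.
#' @param reversal_trial Optional context-local trial index after which
#'   `(p_a, p_b)` swap (used by the Reversal condition; default 12 there).
#' @return A list of class `"context_spec"`.
#' @examples
#' context_spec("Asymmetric", 0.75, 0.25)
#' @export
context_spec <- function(label, p_a, p_b, reversal_trial = NULL) {
  label <- match.arg(label, c("Symmetric", "Asymmetric", "Reversal"))
  if (!is.numeric(p_a) || !is.numeric(p_b) ||
      p_a < 0 || p_a > 1 || p_b < 0 || p_b > 1) {
    stop("reward probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (!is.null(reversal_trial)) {
    reversal_trial <- as.integer(reversal_trial)
    if (reversal_trial < 1) stop("reversal_trial must be >= 1", call. = FALSE)
  }
  structure(list(label = label, p_a = p_a, p_b = p_b,
                 reversal_trial = reversal_trial),
            class = "context_spec")
}

#' Default set of contexts for one session
#'
#' One Symmetric (.50/.50), two Asymmetric (.75/.25) and one Reversal
#' (.83/.17, contingencies swapping after 12 context trials) context.
#'
#' @return List of [context_spec()] objects.
#' @export
default_contexts <- function() {
  list(
    context_spec("Symmetric",  0.50, 0.50),
    context_spec("Asymmetric", 0.75, 0.25),
    context_spec("Asymmetric", 0.75, 0.25),
    context_spec("Reversal",   0.83, 0.17, reversal_trial = 12L)
  )
}

#' Task configuration
#'
#' @param sessions Number of sessions; each session re-uses the same
#'   conditions with a fresh set of stimuli (values re-initialise per
#'   context instance).
#' @param trials_per_context Trials on which each context is presented
#'   within a session.
#' @param contexts List of [context_spec()] objects presented in every
#'   session.
#' @param feedback `"complete"` (forgone outcome displayed) or
#'   `"partial"` (obtained outcome only).
#' @return A list of class `"task_config"`.
#' @export
task_config <- function(sessions = 2L, trials_per_context = 24L,
                        contexts = default_contexts(),
                        feedback = c("complete", "partial")) {
  feedback <- match.arg(feedback)
  sessions <- as.integer(sessions)
  trials_per_context <- as.integer(trials_per_context)
  if (sessions < 1L) stop("need at least one session", call. = FALSE)
  if (trials_per_context < 1L) {
    stop("trials_per_context must be positive", call. = FALSE)
  }
  if (!length(contexts)) stop("need at least one context", call. = FALSE)
  for (ctx in contexts) {
    if (!inherits(ctx, "context_spec")) {
      stop("contexts must be context_spec objects", call. = FALSE)
    }
  }
  structure(list(sessions = sessions,
                 trials_per_context = trials_per_context,
                 contexts = contexts, feedback = feedback),
            class = "task_config")
}

#' Materialise a task schedule
#'
#' Builds the per-trial schedule: contexts are interleaved within each
#' session by a seeded uniform shuffle, each context appearing exactly
#' `trials_per_context` times.  The reward probabilities in force on each
#' trial already account for the contingency reversal of Reversal
#' contexts (applied at the context-local trial counter).
#'
#' @param config A [task_config()].
#' @param seed Integer seed controlling the interleaving; identical seeds
#'   give identical schedules.
#' @return An object of class `"task_design"`: a list with `config` and
#'   `schedule`, a data frame with one row per trial and columns
#'   `session`, `trial`, `context_label`, `context_instance`,
#'   `context_trial`, `p_a`, `p_b`.
#' @examples
#' d <- build_schedule(seed = 1)
#' nrow(d$schedule)   # 192 trials in the default design
#' @export
build_schedule <- function(config = task_config(), seed = 1L) {
  stopifnot(inherits(config, "task_config"))
  set.seed(as.integer(seed))
  n_ctx <- length(config$contexts)
  tpc <- config$trials_per_context
  out <- vector("list", config$sessions)
  for (s in seq_len(config$sessions)) {
    # instance ids disambiguate repeated labels (two Asymmetric contexts)
    labels <- vapply(config$contexts, `[[`, "", "label")
    inst_no <- stats::ave(seq_along(labels), labels, FUN = seq_along)
    inst_id <- sprintf("s%d.%s.%d", s, labels, inst_no)
    order_idx <- sample(rep(seq_len(n_ctx), each = tpc))
    ctx_trial <- stats::ave(order_idx, order_idx, FUN = seq_along)
    p_a <- numeric(length(order_idx))
    p_b <- numeric(length(order_idx))
    for (i in seq_along(order_idx)) {
      ctx <- config$contexts[[order_idx[i]]]
      swap <- !is.null(ctx$reversal_trial) && ctx_trial[i] > ctx$reversal_trial
      p_a[i] <- if (swap) ctx$p_b else ctx$p_a
      p_b[i] <- if (swap) ctx$p_a else ctx$p_b
    }
    out[[s]] <- data.frame(
      session = s,
      trial = seq_along(order_idx),
      context_label = labels[order_idx],
      context_instance = inst_id[order_idx],
      context_trial = ctx_trial,
      p_a = p_a, p_b = p_b,
      stringsAsFactors = FALSE
    )
  }
  structure(list(config = config, schedule = do.call(rbind, out)),
            class = "task_design")
}

#' @export
print.task_design <- function(x, ...) {
  cat(sprintf("Task design: %d session(s) x %d trials (%s feedback)\n",
              x$config$sessions, nrow(x$schedule) / x$config$sessions,
              x$config$feedback))
  invisible(x)
}

#' Probability that the two options' outcomes coincide
#'
#' With outcomes drawn independently per option, the obtained and forgone
#' outcomes agree with probability `p1*p2 + (1-p1)*(1-p2)`: 0.500 for the
#' Symmetric (.50/.50), 0.375 for the Asymmetric (.75/.25) and 0.2822 for
#' the Reversal (.83/.17) contingencies.
#'
#' @param p1,p2 Per-option reward probabilities in `[0, 1]`.
#' @return The concordance probability.
#' @examples
#' expected_concordance(0.75, 0.25)  # 0.375
#' @export
expected_concordance <- function(p1, p2) {
  if (any(p1 < 0 | p1 > 1) || any(p2 < 0 | p2 > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  p1 * p2 + (1 - p1) * (1 - p2)
}

#' Draw an outcome table for a schedule
#'
#' Each option's outcome is +1 with its scheduled probability in force on
#' that trial and -1 otherwise, drawn independently per option and trial.
#'
#' @param design A [build_schedule()] result.
#' @param seed Integer seed.
#' @return The schedule data frame with added columns `outcome_a`,
#'   `outcome_b` (each +1 or -1).
#' @export
draw_outcomes <- function(design, seed = 1L) {
  stopifnot(inherits(design, "task_design"))
  set.seed(as.integer(seed))
  sch <- design$schedule
  sch$outcome_a <- ifelse(stats::runif(nrow(sch)) < sch$p_a, 1, -1)
  sch$outcome_b <- ifelse(stats::runif(nrow(sch)) < sch$p_b, 1, -1)
  sch
}
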