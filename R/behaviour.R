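#' Preferred choice rate in the Symmetric condition
#'
#' Fraction of Symmetric-condition trials on which the subject chose
#' their modal option; `>= 0.5` by construction.  An exact 50/50 tie
#' returns 0.5 with attribute `tie = TRUE`.
#'
#' @param data A single-subject dataset containing Symmetric trials.
#' @return The preferred choice rate.
#' @export
preferred_choice_rate <- function(data) {
  d <- data[data$context_label == "Symmetric", ]
  if (!nrow(d)) stop("no Symmetric trials in data", call. = FALSE)
  n_a <- sum(d$choice == "A")
  rate <- max(n_a, nrow(d) - n_a) / nrow(d)
  attr(rate, "tie") <- n_a * 2L == nrow(d)
  rate
}

#' Correct choice rate in the Asymmetric or Reversal condition
#'
#' Fraction of trials on which the option with the higher reward
#' probability *in force on that trial* was chosen.  In the Reversal
#' condition the halves are defined by the reversal point, so the correct
#' option of the second half is the initially worse one.
#'
#' @param data A single-subject dataset with `p_a`/`p_b` columns.
#' @param condition `"Asymmetric"` or `"Reversal"` (the Symmetric
#'   condition has no correct option and is refused).
#' @param phase `"all"`, `"first_half"` or `"second_half"` (halves are
#'   only meaningful for the Reversal condition).
#' @return The correct choice rate.
#' @export
correct_choice_rate <- function(data,
                                condition = c("Asymmetric", "Reversal"),
                                phase = c("all", "first_half",
                                          "second_half")) {
  condition <- match.arg(condition)
  phase <- match.arg(phase)
  if (!all(c("p_a", "p_b") %in% names(data))) {
    stop("dataset lacks the scheduled probability columns p_a/p_b",
         call. = FALSE)
  }
  d <- data[data$context_label == condition, ]
  if (!nrow(d)) stop("no ", condition, " trials in data", call. = FALSE)
  if (phase != "all") {
    half <- max(d$context_trial) / 2
    d <- if (phase == "first_half") d[d$context_trial <= half, ]
         else d[d$context_trial > half, ]
  }
  if (any(d$p_a == d$p_b)) {
    stop("no correct option: equal scheduled probabilities", call. = FALSE)
  }
  correct <- ifelse(d$p_a > d$p_b, "A", "B")
  mean(d$choice == correct)
}

#' Normalised learning-rate bias index
#'
#' Experiment 1 (factual learning only):
#' `(alpha_c_plus - alpha_c_minus) / (alpha_c_plus + alpha_c_minus)`.
#' Experiment 2 (with counterfactual learning), default form:
#' `((alpha_c_plus - alpha_c_minus) - (alpha_u_plus - alpha_u_minus))`
#' over the sum of the four rates, which is +1 for a pure confirmation
#' pattern and -1 for a pure disconfirmation pattern.  `form =
#' "printed"` substitutes `(alpha_u_plus + alpha_u_minus)` for the
#' counterfactual difference in the numerator (an alternative reading of
#' the index; see the methods vignette).
#'
#' @param params A [parameter_set()] (typically MAP estimates).
#' @param experiment 1 or 2.
#' @param form `"difference"` (default) or `"printed"` (experiment 2
#'   only).
#' @return Index in `[-1, 1]`; `NA` with a warning when the denominator
#'   is zero.
#' @examples
#' normalized_bias(parameter_set(5, 0.6, 0.2), experiment = 1)  # 0.5
#' @export
normalized_bias <- function(params, experiment = 2L,
                            form = c("difference", "printed")) {
  form <- match.arg(form)
  experiment <- as.integer(experiment)
  stopifnot(experiment %in% c(1L, 2L))
  if (experiment == 1L) {
    num <- params$alpha_c_plus - params$alpha_c_minus
    den <- params$alpha_c_plus + params$alpha_c_minus
  } else {
    cf <- if (form == "printed") {
      params$alpha_u_plus + params$alpha_u_minus
    } else {
      params$alpha_u_plus - params$alpha_u_minus
    }
    num <- (params$alpha_c_plus - params$alpha_c_minus) - cf
    den <- params$alpha_c_plus + params$alpha_c_minus +
      params$alpha_u_plus + params$alpha_u_minus
  }
  if (den == 0) {
    warning("zero denominator: bias index undefined")
    return(NA_real_)
  }
  num / den
}

#' Median split into low- and high-bias groups
#'
#' High group: strictly above the median; low group: at or below.  Equal
#' group sizes for even N with distinct values.
#'
#' @param indices Numeric vector (>= 2 subjects).
#' @return Factor with levels `"low"`, `"high"`; attribute `degenerate =
#'   TRUE` (with a warning) when all indices are equal.
#' @export
median_split <- function(indices) {
  if (length(indices) < 2L) stop("need at least 2 subjects", call. = FALSE)
  med <- stats::median(indices)
  lab <- factor(ifelse(indices > med, "high", "low"),
                levels = c("low", "high"))
  if (length(unique(indices)) == 1L) {
    warning("all indices equal: degenerate split")
    attr(lab, "degenerate") <- TRUE
  }
  lab
}

# designated option per condition: Symmetric -> the subject's preferred
# option; Asymmetric -> the correct option; Reversal -> the initially
# more advantageous option
.designated_option <- function(data) {
  pref <- {
    d <- data[data$context_label == "Symmetric", ]
    if (nrow(d) && sum(d$choice == "A") * 2L >= nrow(d)) "A" else "B"
  }
  out <- character(nrow(data))
  for (i in seq_len(nrow(data))) {
    out[i] <- switch(data$context_label[i],
      Symmetric = pref,
      Asymmetric = if (data$p_a[i] > data$p_b[i]) "A" else "B",
      Reversal = {
        first <- data$context_label == "Reversal" &
          data$context_instance == data$context_instance[i] &
          data$context_trial == 1L
        if (data$p_a[first][1] > data$p_b[first][1]) "A" else "B"
      })
  }
  out
}

#' Trial-by-trial model estimates of choice probability
#'
#' Replays one or more fitted models over the subject's *actual*
#' choice/outcome sequence and records, per trial, the predicted
#' probability of the condition's designated option (Symmetric: the
#' subject's preferred option; Asymmetric: the correct option; Reversal:
#' the initially more advantageous option) next to the observed choice
#' indicator of that option.
#'
#' @param data A single-subject dataset.
#' @param model A [model_spec()] or model name.
#' @param params A [parameter_set()], free-parameter vector, or a
#'   *named list* of either (one predicted-probability column per entry,
#'   e.g. `list(biased = ..., unbiased = ...)`).
#' @return A data frame of class `"curve_comparison"`: `condition`,
#'   `context_instance`, `context_trial`, `observed` (0/1) and one
#'   `pred_<name>` column per parameter set (or `pred` for a single one).
#' @export
model_estimate_curves <- function(data, model, params) {
  if (is.character(model)) model <- model_spec(model)
  if (!is.list(params) || inherits(params, "parameter_set")) {
    params <- list(pred = params)
    single <- TRUE
  } else {
    single <- FALSE
    if (is.null(names(params)) || any(!nzchar(names(params)))) {
      stop("multiple parameter sets must be named", call. = FALSE)
    }
  }
  v <- .replay_vectors(data)
  d <- data[v$order, ]
  designated <- .designated_option(d)
  out <- data.frame(condition = d$context_label,
                    context_instance = d$context_instance,
                    context_trial = d$context_trial,
                    observed = as.numeric(d$choice == designated),
                    stringsAsFactors = FALSE)
  for (nm in names(params)) {
    p <- params[[nm]]
    if (!inherits(p, "parameter_set")) p <- resolve_parameters(model, p)
    p_a <- prob_replay_cpp(v$instance, v$choice, v$r_c, v$r_u,
                           p$beta, p$alpha_c_plus, p$alpha_c_minus,
                           p$alpha_u_plus, p$alpha_u_minus, p$pi)
    col <- if (single) "pred" else paste0("pred_", nm)
    out[[col]] <- ifelse(designated == "A", p_a, 1 - p_a)
  }
  class(out) <- c("curve_comparison", "data.frame")
  out
}

#' Mean squared distance between model estimates and choices
#'
#' For each predicted-probability column of a [model_estimate_curves()]
#' result: the mean over trials of the squared difference between the
#' predicted probability and the observed 0/1 choice indicator of the
#' designated option, computed per condition and then averaged over
#' conditions (so each condition weighs equally for the subject).
#'
#' @param comparison A `"curve_comparison"` data frame.
#' @return Named numeric vector, one distance per model variant.
#' @export
curve_squared_distance <- function(comparison) {
  pred_cols <- grep("^pred", names(comparison), value = TRUE)
  out <- vapply(pred_cols, function(cl) {
    per_cond <- tapply((comparison[[cl]] - comparison$observed)^2,
                       comparison$condition, mean)
    mean(per_cond)
  }, 0)
  names(out) <- sub("^pred_?", "", names(out))
  names(out)[!nzchar(names(out))] <- "pred"
  out
}

#' Per-subject behavioural summary of a cohort
#'
#' @param data A stacked cohort data frame.
#' @return Data frame with one row per subject: `preferred_choice_rate`
#'   (Symmetric), `correct_asymmetric`, `correct_reversal_first`,
#'   `correct_reversal_second`.
#' @export
behavioural_summary <- function(data) {
  subs <- split_subjects(data)
  do.call(rbind, lapply(subs, function(d) {
    data.frame(
      subject = d$subject[1],
      preferred_choice_rate = as.numeric(preferred_choice_rate(d)),
      correct_asymmetric = correct_choice_rate(d, "Asymmetric"),
      correct_reversal_first = correct_choice_rate(d, "Reversal",
                                                   "first_half"),
      correct_reversal_second = correct_choice_rate(d, "Reversal",
                                                    "second_half"),
      row.names = NULL)
  }))
}
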