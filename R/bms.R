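#' BIC approximation to the log model evidence
#'
#' @param bic BIC value(s).
#' @return `-bic / 2`.
#' @export
log_evidence_from_bic <- function(bic) {
  if (any(!is.finite(bic))) stop("bic must be finite", call. = FALSE)
  -bic / 2
}

#' Random-effects group Bayesian model selection
#'
#' Treats the model generating each subject's data as a random effect
#' drawn from an unknown population distribution with a Dirichlet prior,
#' and estimates it with the standard variational scheme: subject-wise
#' responsibility (attribution) updates alternate with Dirichlet
#' concentration updates until convergence.  Exceedance probabilities
#' (the probability that each model is the most frequent in the
#' population) are estimated by Monte-Carlo sampling of the fitted
#' Dirichlet.
#'
#' @param log_evidence Subject-by-model matrix of log model evidences
#'   (e.g. [log_evidence_from_bic()] of per-subject BICs).
#' @param alpha0 Dirichlet prior concentration (uniform, default 1).
#' @param n_samples Dirichlet samples for the exceedance estimate; the
#'   default keeps the Monte-Carlo standard error below 0.005.
#' @param seed Seed for the exceedance sampler.
#' @param max_iter,tol Convergence controls for the variational loop.
#' @return A list of class `"bms_result"`: `attributions` (subject-by-
#'   model posterior probabilities, rows summing to 1),
#'   `model_frequencies` (their column means), `expected_r` (Dirichlet
#'   mean population frequencies), `xp` (exceedance probabilities,
#'   summing to 1), `dirichlet_counts`, `converged`, `n_iter`.
#' @examples
#' le <- matrix(0, nrow = 5, ncol = 4)  # identical evidences
#' rfx_bms(le, seed = 1)$attributions[1, ]  # all 0.25
#' @export
rfx_bms <- function(log_evidence, alpha0 = 1, n_samples = 1e6, seed = 1L,
                    max_iter = 500L, tol = 1e-8) {
  le <- as.matrix(log_evidence)
  if (nrow(le) < 2L || ncol(le) < 2L) {
    stop("need at least 2 subjects and 2 models", call. = FALSE)
  }
  if (any(!is.finite(le))) stop("log evidences must be finite", call. = FALSE)
  n <- nrow(le)
  k <- ncol(le)
  alpha <- rep(alpha0, k)
  g <- matrix(1 / k, n, k)
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    # responsibilities: evidence weighted by E[log r] under the Dirichlet
    lw <- sweep(le, 2, digamma(alpha) - digamma(sum(alpha)), `+`)
    lw <- lw - apply(lw, 1, max)
    g_new <- exp(lw) / rowSums(exp(lw))
    alpha_new <- alpha0 + colSums(g_new)
    if (max(abs(alpha_new - alpha)) < tol) {
      alpha <- alpha_new
      g <- g_new
      converged <- TRUE
      break
    }
    alpha <- alpha_new
    g <- g_new
  }
  if (!converged) {
    warning("rfx_bms did not converge within max_iter iterations")
  }
  dimnames(g) <- dimnames(le)
  xp <- .exceedance_mc(alpha, n_samples, seed)
  names(xp) <- colnames(le)
  structure(list(attributions = g,
                 model_frequencies = colMeans(g),
                 expected_r = alpha / sum(alpha),
                 xp = xp,
                 dirichlet_counts = stats::setNames(alpha, colnames(le)),
                 converged = converged, n_iter = it),
            class = "bms_result")
}

# Monte-Carlo exceedance: frequency with which each model has the largest
# sampled population frequency under Dirichlet(alpha); sampled in chunks
# to bound memory
.exceedance_mc <- function(alpha, n_samples, seed) {
  set.seed(as.integer(seed))
  k <- length(alpha)
  counts <- integer(k)
  left <- as.integer(n_samples)
  chunk <- 250000L
  while (left > 0L) {
    m <- min(chunk, left)
    x <- matrix(stats::rgamma(m * k, shape = rep(alpha, each = m)), m, k)
    counts <- counts + tabulate(max.col(x, ties.method = "random"), k)
    left <- left - m
  }
  counts / as.integer(n_samples)
}

#' @export
print.bms_result <- function(x, ...) {
  tab <- rbind(`mean attribution` = x$model_frequencies, XP = x$xp)
  print(round(tab, 3))
  invisible(x)
}

#' Population model frequencies from attributions
#'
#' Column means of the per-subject posterior model attributions; chance
#' level for a K-model space is `1/K`.
#'
#' @param attributions Subject-by-model attribution matrix.
#' @return Named vector of frequencies (summing to 1 when rows do).
#' @export
model_frequencies <- function(attributions) {
  colMeans(as.matrix(attributions))
}

#' Model-comparison table for a cohort of fits
#'
#' Runs BIC-based random-effects model selection on a cohort fit table
#' and returns one row per model: mean BIC, mean posterior attribution
#' (comparable to chance `1/K`), and exceedance probability.
#'
#' @param fits A [fit_cohort()] data frame (`subject`, `model`, `bic`).
#' @param models Models to compare (default: all present).
#' @param seed Seed for the exceedance sampler.
#' @param n_samples Dirichlet samples for the exceedance estimate.
#' @return List with `table` (data frame) and the full `"bms_result"`.
#' @export
compare_models <- function(fits, models = NULL, seed = 1L, n_samples = 1e6) {
  if (is.null(models)) models <- unique(fits$model)
  fits <- fits[fits$model %in% models, ]
  wide <- stats::reshape(fits[, c("subject", "model", "bic")],
                         idvar = "subject", timevar = "model",
                         direction = "wide")
  bics <- as.matrix(wide[, paste0("bic.", models), drop = FALSE])
  colnames(bics) <- models
  res <- rfx_bms(log_evidence_from_bic(bics), seed = seed,
                 n_samples = n_samples)
  tab <- data.frame(model = models,
                    mean_bic = colMeans(bics),
                    mean_attribution = res$model_frequencies,
                    xp = res$xp,
                    chance = 1 / length(models),
                    row.names = NULL)
  list(table = tab, bms = res)
}
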