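# Independent oracles, coded from first principles and deliberately not
# sharing any code path with the package internals.

# Brute-force likelihood replay: plain-R trial loop over each context
# instance with named Q-vectors and an explicit softmax.
oracle_nll <- function(data, beta, acp, acm, aup, aum, piw = 0) {
  nll <- 0
  for (id in unique(data$context_instance)) {
    d <- data[data$context_instance == id, ]
    d <- d[order(d$context_trial), ]
    q <- c(A = 0, B = 0)
    prev <- NULL
    for (t in seq_len(nrow(d))) {
      b <- c(A = 0, B = 0)
      if (!is.null(prev)) b[prev] <- piw
      z <- exp(beta * (q + b))
      p <- z / sum(z)
      nll <- nll - log(p[[d$choice[t]]])
      ch <- d$choice[t]
      un <- setdiff(c("A", "B"), ch)
      pe <- d$outcome_chosen[t] - q[[ch]]
      q[[ch]] <- q[[ch]] + (if (pe > 0) acp else acm) * pe
      if (!is.na(d$outcome_unchosen[t])) {
        peu <- d$outcome_unchosen[t] - q[[un]]
        q[[un]] <- q[[un]] + (if (peu > 0) aup else aum) * peu
      }
      prev <- ch
    }
  }
  nll
}

# Exact random-effects model posterior for K = 2 models under a uniform
# Dirichlet prior, by numerical integration over the population frequency
# r1 of model 1.  Returns the subject-by-2 attribution matrix.
oracle_bms_attributions <- function(log_evidence) {
  stopifnot(ncol(log_evidence) == 2)
  lik <- exp(log_evidence - max(log_evidence))  # scale cancels
  n <- nrow(lik)
  grid <- seq(1e-6, 1 - 1e-6, length.out = 20001)
  mix <- function(r1) lik[, 1] * r1 + lik[, 2] * (1 - r1)  # per subject
  marg <- vapply(grid, function(r1) prod(mix(r1)), 0)
  attr1 <- matrix(0, n, 2)
  for (s in seq_len(n)) {
    resp <- vapply(grid, function(r1) {
      lik[s, 1] * r1 / (lik[s, 1] * r1 + lik[s, 2] * (1 - r1))
    }, 0)
    attr1[s, 1] <- sum(resp * marg) / sum(marg)
    attr1[s, 2] <- 1 - attr1[s, 1]
  }
  attr1
}

# small complete-feedback design + dataset used across tests
make_tiny_dataset <- function(n_trials = 8, seed = 42, feedback = "complete") {
  cfg <- task_config(sessions = 1, trials_per_context = n_trials,
                     contexts = list(context_spec("Asymmetric", 0.75, 0.25)),
                     feedback = feedback)
  d <- build_schedule(cfg, seed = seed)
  simulate_agent("Full", c(3, 0.4, 0.2, 0.1, 0.3), d, seed = seed)
}

default_design <- function(seed = 1, feedback = "complete") {
  build_schedule(task_config(feedback = feedback), seed = seed)
}
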