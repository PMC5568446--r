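#' Names of the candidate models
#'
#' @return Character vector of the six model names.
#' @export
model_names <- function() {
  c("Full", "Information", "Valence", "Confirmation", "Perseveration", "One")
}

# free-parameter layout per model (order is the canonical CLI/CSV order)
.model_free <- list(
  Full          = c("beta", "alpha_c_plus", "alpha_c_minus",
                    "alpha_u_plus", "alpha_u_minus"),
  Information   = c("beta", "alpha_c", "alpha_u"),
  Valence       = c("beta", "alpha_plus", "alpha_minus"),
  Confirmation  = c("beta", "alpha_con", "alpha_dis"),
  Perseveration = c("beta", "alpha_c", "alpha_u", "pi"),
  One           = c("beta", "alpha")
)

#' Model specification
#'
#' Defines a member of the model family by its learning-rate tying map.
#' The Full model keeps four free rates (chosen/unchosen crossed with
#' positive/negative prediction errors).  Information ties across valence
#' (`alpha_c`, `alpha_u`), Valence ties across information type
#' (`alpha_plus`, `alpha_minus`), Confirmation ties choice-confirming
#' events together (`alpha_con` = rate for positive chosen and negative
#' unchosen prediction errors, `alpha_dis` for the rest), One uses a
#' single rate, and Perseveration augments the Information tying with a
#' choice-repetition weight `pi`.
#'
#' @param name One of [model_names()].
#' @return A list of class `"model_spec"` with elements `name`,
#'   `free` (free-parameter names in canonical order) and `df`.
#' @examples
#' model_spec("Confirmation")$df  # 3
#' @export
model_spec <- function(name) {
  name <- match.arg(name, model_names())
  free <- .model_free[[name]]
  structure(list(name = name, free = free, df = length(free)),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("Model '%s' (%d df): %s\n", x$name, x$df,
              paste(x$free, collapse = ", ")))
  invisible(x)
}

#' Construct a full parameter set
#'
#' @param beta Softmax scaling, `>= 0`; larger values make choice more
#'   deterministic.
#' @param alpha_c_plus,alpha_c_minus Learning rates for positive/negative
#'   prediction errors of the chosen option, in `[0, 1]`.
#' @param alpha_u_plus,alpha_u_minus Learning rates for positive/negative
#'   prediction errors of the unchosen option, in `[0, 1]`.
#' @param pi Perseveration weight added to the previously chosen option's
#'   decision variable (0 disables it).
#' @return A list of class `"parameter_set"`.
#' @export
parameter_set <- function(beta, alpha_c_plus, alpha_c_minus,
                          alpha_u_plus = alpha_c_plus,
                          alpha_u_minus = alpha_c_minus, pi = 0) {
  al <- c(alpha_c_plus, alpha_c_minus, alpha_u_plus, alpha_u_minus)
  if (any(al < 0 | al > 1)) {
    stop("learning rates must lie in [0, 1]", call. = FALSE)
  }
  if (beta < 0) stop("beta must be >= 0", call. = FALSE)
  structure(list(beta = beta,
                 alpha_c_plus = alpha_c_plus, alpha_c_minus = alpha_c_minus,
                 alpha_u_plus = alpha_u_plus, alpha_u_minus = alpha_u_minus,
                 pi = pi),
            class = "parameter_set")
}

#' Expand a model's free parameters into the four learning-rate slots
#'
#' @param model A [model_spec()] or model name.
#' @param free_params Numeric vector of length `model$df`, in the order
#'   given by `model_spec(name)$free` (names, if present, are checked).
#' @return A [parameter_set()].
#' @examples
#' resolve_parameters("Confirmation", c(beta = 3, alpha_con = 0.4,
#'                                      alpha_dis = 0.1))
#' @export
resolve_parameters <- function(model, free_params) {
  if (is.character(model)) model <- model_spec(model)
  stopifnot(inherits(model, "model_spec"))
  if (length(free_params) != model$df) {
    stop(sprintf("model '%s' expects %d free parameters, got %d",
                 model$name, model$df, length(free_params)), call. = FALSE)
  }
  if (!is.null(names(free_params)) && any(nzchar(names(free_params)))) {
    if (!setequal(names(free_params), model$free)) {
      stop("free parameter names do not match the model specification",
           call. = FALSE)
    }
    free_params <- free_params[model$free]
  }
  pv <- as.numeric(free_params)
  names(pv) <- model$free
  p <- function(nm) unname(pv[nm])
  switch(model$name,
    Full = parameter_set(p("beta"), p("alpha_c_plus"), p("alpha_c_minus"),
                         p("alpha_u_plus"), p("alpha_u_minus")),
    Information = parameter_set(p("beta"), p("alpha_c"), p("alpha_c"),
                                p("alpha_u"), p("alpha_u")),
    Valence = parameter_set(p("beta"), p("alpha_plus"), p("alpha_minus"),
                            p("alpha_plus"), p("alpha_minus")),
    Confirmation = parameter_set(p("beta"), p("alpha_con"), p("alpha_dis"),
                                 p("alpha_dis"), p("alpha_con")),
    Perseveration = parameter_set(p("beta"), p("alpha_c"), p("alpha_c"),
                                  p("alpha_u"), p("alpha_u"), pi = p("pi")),
    One = parameter_set(p("beta"), p("alpha"), p("alpha"),
                        p("alpha"), p("alpha"))
  )
}

.delta_update <- function(q, r, alpha_plus, alpha_minus) {
  pe <- r - q
  rate <- if (pe > 0) alpha_plus else if (pe < 0) alpha_minus else 0
  list(value = q + rate * pe, pe = pe)
}

#' Factual (chosen-option) value update
#'
#' Delta rule with valence-dependent rates: `Q <- Q + alpha * PE` with
#' `PE = R - Q`, using `alpha_c_plus` when `PE > 0` and `alpha_c_minus`
#' when `PE < 0` (no change at `PE = 0`).
#'
#' @param q_c Current chosen-option value in `[-1, 1]`.
#' @param r_c Obtained outcome, +1 or -1.
#' @param alpha_c_plus,alpha_c_minus Learning rates in `[0, 1]`.
#' @return List with `value` (updated Q) and `pe` (prediction error).
#' @examples
#' factual_update(0.5, -1, 0.3, 0.2)  # PE = -1.5, value = 0.2
#' @export
factual_update <- function(q_c, r_c, alpha_c_plus, alpha_c_minus) {
  .delta_update(q_c, r_c, alpha_c_plus, alpha_c_minus)
}

#' Counterfactual (unchosen-option) value update
#'
#' Same delta rule applied to the forgone outcome with the unchosen-option
#' rates; only runs under complete feedback.
#'
#' @param q_u Current unchosen-option value in `[-1, 1]`.
#' @param r_u Forgone outcome, +1 or -1.
#' @param alpha_u_plus,alpha_u_minus Learning rates in `[0, 1]`.
#' @return List with `value` and `pe`.
#' @export
counterfactual_update <- function(q_u, r_u, alpha_u_plus, alpha_u_minus) {
  .delta_update(q_u, r_u, alpha_u_plus, alpha_u_minus)
}

#' Softmax choice probability
#'
#' Probability of selecting the first option under the scaled softmax
#' `exp(beta*(q_c + b_c)) / (exp(beta*(q_c + b_c)) + exp(beta*(q_u + b_u)))`,
#' computed with max-subtraction so large `beta * Q` cannot overflow.  The
#' bonus terms carry the perseveration weight of the previously chosen
#' option (0 on a context's first trial).
#'
#' @param q_c,q_u Option values.
#' @param beta Softmax scaling `>= 0`.
#' @param bonus_c,bonus_u Additive decision-variable bonuses (default 0).
#' @return Probability in `(0, 1)`.
#' @examples
#' choice_probability(1, -1, 1)  # 1 / (1 + exp(-2))
#' @export
choice_probability <- function(q_c, q_u, beta, bonus_c = 0, bonus_u = 0) {
  if (any(beta < 0)) stop("beta must be >= 0", call. = FALSE)
  dc <- beta * (q_c + bonus_c)
  du <- beta * (q_u + bonus_u)
  m <- pmax(dc, du)
  exp(dc - m) / (exp(dc - m) + exp(du - m))
}
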