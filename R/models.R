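#' Softmax response selection
#'
#' Turns a preference row (Q-values, ideal-observer probabilities, binarized
#' probabilities, or a degenerate response-pattern row) into selection
#' probabilities. For noise tau > 0 the probability of response j is
#' proportional to exp(pref_j / tau). The noise-free limit tau = 0 selects
#' uniformly among the responses with maximal preference.
#'
#' @param prefs Numeric preference vector, one entry per response.
#' @param tau Response-selection noise, tau >= 0 (softmax temperature).
#' @return Numeric probability vector summing to 1.
#' @examples
#' softmax_select(c(1, 0, 0, 0), tau = 0)  # deterministic
#' softmax_select(c(1, 0, 0, 0), tau = 1)  # e/(e+3), 1/(e+3), ...
#' @export
softmax_select <- function(prefs, tau) {
  if (tau < 0) stop("tau must be >= 0")
  if (tau == 0) {
    best <- prefs >= max(prefs) - 1e-12
    return(best / sum(best))
  }
  e <- exp((prefs - max(prefs)) / tau)  # shift for numerical stability
  e / sum(e)
}

#' Q-learning value update
#'
#' Exponential-smoothing update of the tried stimulus-response pair towards
#' +1 on positive feedback and -1 on negative feedback:
#' q <- (1 - alpha) q + alpha on reward, q <- (1 - alpha) q - alpha on error.
#' Only the (stimulus, response) entry changes; Q-learning draws no
#' inference about the other pairs.
#'
#' @param q Q-value matrix (stimuli x responses), initialised at zero.
#' @param stimulus,response Trial indices.
#' @param feedback 1 or 0.
#' @param alpha Learning rate in (0, 1].
#' @return Updated Q-value matrix.
#' @export
q_update <- function(q, stimulus, response, feedback, alpha) {
  if (alpha <= 0 || alpha > 1) stop("alpha must be in (0, 1]")
  target <- if (feedback == 1L) 1 else -1
  q[stimulus, response] <- (1 - alpha) * q[stimulus, response] + alpha * target
  q
}

#' Binarize an ideal-observer probability row
#'
#' Binarized play discards the graded probability information of the ideal
#' observer and keeps only the zero/nonzero distinction: all nonzero entries
#' are made uniform.
#'
#' @param row Probability row summing to 1.
#' @return Row with nonzero entries replaced by 1/(number of nonzero
#'   entries).
#' @examples
#' bp_transform(c(0.6, 0, 0.3, 0.1))  # (1/3, 0, 1/3, 1/3)
#' @export
bp_transform <- function(row) {
  nz <- row > 0
  if (!any(nz)) stop("all-zero probability row")
  ifelse(nz, 1 / sum(nz), 0)
}

#' Model parameters
#'
#' @param family One of `"q"`, `"fop"`, `"bp"`, `"drp"`.
#' @param tau Response-selection noise, >= 0.
#' @param alpha Learning rate in (0, 1]; Q-learning only.
#' @param order Response-order string (e.g. `"dfkl"`); deterministic
#'   response patterns only.
#' @param config A [task_config()].
#' @return An object of class `srl_params`.
#' @export
model_params <- function(family, tau = 0, alpha = NULL, order = NULL,
                         config = task_config()) {
  family <- match.arg(family, c("q", "fop", "bp", "drp"))
  if (tau < 0) stop("tau must be >= 0")
  if (family == "q") {
    if (is.null(alpha)) stop("Q-learning requires alpha")
    if (alpha <= 0 || alpha > 1) stop("alpha must be in (0, 1]")
  }
  if (family == "drp") {
    if (is.null(order)) stop("a response pattern requires an order string")
    parse_order(order, config)  # validates
  }
  structure(list(family = family, tau = tau,
                 alpha = if (family == "q") alpha,
                 order = if (family == "drp") order),
            class = "srl_params")
}

#' @export
print.srl_params <- function(x, ...) {
  extra <- c(if (!is.null(x$alpha)) sprintf("alpha = %g", x$alpha),
             if (!is.null(x$order)) sprintf("order = %s", x$order))
  cat(sprintf("%s model (tau = %g%s)\n", toupper(x$family), x$tau,
              if (length(extra)) paste0(", ", paste(extra, collapse = ", ")) else ""))
  invisible(x)
}

#' Initialise a model's internal state
#'
#' Q-learning starts from all-zero values; free optimal play and binarized
#' play from the full consistency set; a deterministic response pattern from
#' the full consistency set plus its response order.
#'
#' @param params An [model_params()] object.
#' @param config A [task_config()].
#' @return A state object of class `srl_state`.
#' @export
model_init <- function(params, config = task_config()) {
  n <- config$n_stimuli
  st <- switch(params$family,
    q   = list(q = matrix(0, n, n)),
    fop = list(set = consistency_init(n)),
    bp  = list(set = consistency_init(n)),
    drp = list(set = consistency_init(n),
               order = parse_order(params$order, config)))
  st$family <- params$family
  class(st) <- "srl_state"
  st
}

#' Preference row of a model for a stimulus
#'
#' The row fed into the softmax: the stimulus's Q-value row (Q-learning),
#' its ideal-observer probability row (free optimal play), that row
#' binarized (binarized play), or a degenerate one-hot row on the currently
#' designated response (deterministic response pattern).
#'
#' @param state An `srl_state` from [model_init()] or [model_update()].
#' @param stimulus Stimulus index.
#' @return Numeric preference vector over responses.
#' @export
model_prefs <- function(state, stimulus) {
  switch(state$family,
    q   = state$q[stimulus, ],
    fop = marginal_row(state$set, stimulus),
    bp  = bp_transform(marginal_row(state$set, stimulus)),
    drp = {
      row <- marginal_row(state$set, stimulus)
      designated <- state$order[which(row[state$order] > 0)[1L]]
      p <- numeric(length(row))
      p[designated] <- 1
      p
    })
}

#' Update a model's internal state after a trial
#'
#' Q-learning updates the tried pair only. Free optimal play and binarized
#' play condition their consistency set on every trial: deterministic
#' feedback is always valid evidence, whether or not the response was the
#' model's preferred one. A deterministic response pattern conditions on
#' trials where the selected response was its designated response; when
#' selection noise produced a deviating response, only positive feedback
#' updates the state and negative feedback leaves it unchanged.
#'
#' @param state An `srl_state`.
#' @param stimulus,response,feedback The trial.
#' @param params The [model_params()] the state was built with.
#' @return Updated `srl_state`.
#' @export
model_update <- function(state, stimulus, response, feedback, params) {
  switch(state$family,
    q = {
      state$q <- q_update(state$q, stimulus, response, feedback, params$alpha)
      state
    },
    fop = ,
    bp = {
      state$set <- consistency_update(state$set, stimulus, response, feedback)
      state
    },
    drp = {
      row <- marginal_row(state$set, stimulus)
      designated <- state$order[which(row[state$order] > 0)[1L]]
      if (response == designated || feedback == 1L)
        state$set <- consistency_update(state$set, stimulus, response, feedback)
      state
    })
}

#' One step of a model policy
#'
#' Convenience wrapper giving the response-selection distribution for the
#' current stimulus (preference row passed through [softmax_select()] at the
#' model's noise level) plus an updater closure for the observed outcome.
#'
#' @param state An `srl_state`.
#' @param params The matching [model_params()].
#' @param stimulus Stimulus index.
#' @return List with `probs` (selection distribution), `prefs` (the
#'   preference row), and `update(response, feedback)` returning the next
#'   state.
#' @export
model_step <- function(state, params, stimulus) {
  if (!identical(state$family, params$family))
    stop("state/params family mismatch")
  prefs <- model_prefs(state, stimulus)
  list(probs = softmax_select(prefs, params$tau),
       prefs = prefs,
       update = function(response, feedback)
         model_update(state, stimulus, response, feedback, params))
}
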