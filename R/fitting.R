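#' Parameter grid for maximum-likelihood fitting
#'
#' The models are fitted by exhaustive grid search. The noise grid is
#' tau in {0, 1/6.0, 1/5.8, ..., 1/0.2} (31 values, i.e. inverse
#' temperatures 6.0 down to 0.2 plus the noise-free limit); the learning
#' rate grid for Q-learning is alpha in {0.05, 0.10, ..., 1.00} (20
#' values).
#'
#' @param tau Noise values, enumerated in fitting order (ties broken
#'   towards the first value).
#' @param alpha Learning-rate values (Q-learning only).
#' @return An object of class `parameter_grid`.
#' @export
parameter_grid <- function(tau = c(0, 1 / seq(6.0, 0.2, by = -0.2)),
                           alpha = seq(0.05, 1.00, by = 0.05)) {
  if (any(tau < 0)) stop("tau values must be >= 0")
  if (any(alpha <= 0 | alpha > 1)) stop("alpha values must be in (0, 1]")
  structure(list(tau = tau, alpha = alpha), class = "parameter_grid")
}

#' @export
print.parameter_grid <- function(x, ...) {
  cat(sprintf("Fitting grid: %d tau values [%g .. %g], %d alpha values\n",
              length(x$tau), min(x$tau), max(x$tau), length(x$alpha)))
  invisible(x)
}

#' End of the initial learning phase
#'
#' The initial learning phase starts at trial 1 and ends at the trial in
#' which the last of the stimuli is answered correctly for the first
#' time. Models are fitted on this window only; the subsequent practice
#' phase is excluded.
#'
#' @param block An `srl_block`.
#' @return 1-based index of the phase-ending trial, or `NA_integer_` if some
#'   stimulus was never answered correctly (possible only when the trial cap
#'   was reached first); such blocks are fitted on their full length.
#' @export
initial_phase_end <- function(block) {
  n <- length(block$mapping)
  first_correct <- vapply(seq_len(n), function(s) {
    hit <- which(block$stimulus == s & block$feedback == 1L)
    if (length(hit)) hit[1L] else NA_integer_
  }, integer(1))
  if (anyNA(first_correct)) NA_integer_ else max(first_correct)
}

## likelihood window: initial phase, or the whole block if the phase never
## completed (trial cap hit with an unsolved stimulus)
likelihood_window <- function(block) {
  e <- initial_phase_end(block)
  if (is.na(e)) length(block$stimulus) else e
}

## preference-row trajectory of a model evaluated against the subject's
## actual responses and feedback (trials 1..end_trial); rows are the
## preference vector *before* each trial. The trajectory is independent of
## tau, and for Q-learning depends on alpha only -- the key fact that makes
## the grid search cheap.
trial_prefs <- function(params, block, end_trial, config = task_config()) {
  n <- config$n_stimuli
  state <- model_init(params, config)
  P <- matrix(0, end_trial, n)
  for (t in seq_len(end_trial)) {
    P[t, ] <- model_prefs(state, block$stimulus[t])
    state <- model_update(state, block$stimulus[t], block$response[t],
                          block$feedback[t], params)
  }
  P
}

## log-likelihood of the observed responses for each tau, given the
## tau-independent preference trajectory
ll_for_taus <- function(P, responses, taus) {
  idx <- cbind(seq_along(responses), responses)
  mx <- apply(P, 1L, max)
  chosen <- P[idx]
  vapply(taus, function(tau) {
    if (tau == 0) {
      in_max <- chosen >= mx - 1e-12
      k <- rowSums(P >= mx - 1e-12)
      sum(log(ifelse(in_max, 1 / k, 0)))
    } else {
      Z <- P / tau
      zm <- mx / tau
      sum(Z[idx] - zm - log(rowSums(exp(Z - zm))))
    }
  }, numeric(1))
}

#' Log-likelihood of one block under a model
#'
#' Sum over trials of the log selection probability of the subject's actual
#' response, with the model state evolved along the subject's actual
#' responses and feedback (not the model's preferred ones). A trial the
#' model gives probability zero (possible only at tau = 0) contributes
#' -Inf, which is a valid ordering value in the grid search.
#'
#' @param params A [model_params()].
#' @param block An `srl_block`.
#' @param end_trial Last trial included; defaults to the initial-phase
#'   window.
#' @param config A [task_config()].
#' @return Log-likelihood (natural log).
#' @export
block_loglik <- function(params, block, end_trial = NULL,
                         config = task_config()) {
  if (is.null(end_trial)) end_trial <- likelihood_window(block)
  if (end_trial > length(block$stimulus)) stop("end_trial beyond block length")
  P <- trial_prefs(params, block, end_trial, config)
  ll_for_taus(P, block$response[seq_len(end_trial)], params$tau)
}

#' The constrained five-model comparison set
#'
#' The response patterns dfkl (left to right on the keyboard) and lkfd
#' (right to left), free optimal play, binarized play, and Q-learning.
#'
#' @param config A [task_config()].
#' @return Named list of model templates for [fit_models()].
#' @export
default_model_set <- function(config = task_config()) {
  list(drp_dfkl = list(family = "drp", order = "dfkl"),
       drp_lkfd = list(family = "drp", order = "lkfd"),
       fop = list(family = "fop"),
       bp = list(family = "bp"),
       q = list(family = "q"))
}

#' All 27 models of the preliminary comparison
#'
#' Every deterministic response pattern (all 24 response orders) plus free
#' optimal play, binarized play and Q-learning.
#'
#' @param config A [task_config()].
#' @return Named list of model templates for [fit_models()].
#' @export
full_model_set <- function(config = task_config()) {
  perms <- enumerate_mappings(config$n_responses)
  orders <- apply(perms, 1L, order_label, config = config)
  drps <- lapply(orders, function(o) list(family = "drp", order = o))
  names(drps) <- paste0("drp_", orders)
  c(drps, list(fop = list(family = "fop"), bp = list(family = "bp"),
               q = list(family = "q")))
}

## fit one subject x one model template by exhaustive grid search;
## returns best tau/alpha and the per-block LL vector at the optimum
fit_one <- function(template, subject, grid, block_ids, config) {
  blocks <- Filter(function(b) b$block_id %in% block_ids, subject$blocks)
  if (length(blocks) == 0L) stop("subject has none of the requested blocks")
  n_tau <- length(grid$tau)
  if (template$family == "q") {
    best <- NULL
    for (a in grid$alpha) {
      params <- model_params("q", tau = grid$tau[1], alpha = a, config = config)
      ll <- vapply(blocks, function(b) {
        e <- likelihood_window(b)
        P <- trial_prefs(params, b, e, config)
        ll_for_taus(P, b$response[seq_len(e)], grid$tau)
      }, numeric(n_tau))                      # n_tau x n_blocks
      ll <- matrix(ll, nrow = n_tau)
      tot <- rowSums(ll)
      i <- which.max(tot)
      if (is.null(best) || tot[i] > best$ll_total) {
        best <- list(tau = grid$tau[i], alpha = a, order = NA_character_,
                     ll_blocks = ll[i, ], ll_total = tot[i])
      }
    }
    best
  } else {
    params <- model_params(template$family, tau = grid$tau[1],
                           alpha = NULL, order = template$order,
                           config = config)
    ll <- vapply(blocks, function(b) {
      e <- likelihood_window(b)
      P <- trial_prefs(params, b, e, config)
      ll_for_taus(P, b$response[seq_len(e)], grid$tau)
    }, numeric(n_tau))
    ll <- matrix(ll, nrow = n_tau)
    tot <- rowSums(ll)
    i <- which.max(tot)
    list(tau = grid$tau[i], alpha = NA_real_,
         order = if (is.null(template$order)) NA_character_ else template$order,
         ll_blocks = ll[i, ], ll_total = tot[i])
  }
}

#' Fit behavioural models to a trial-log dataset
#'
#' Per-subject maximum-likelihood estimation of each model by exhaustive
#' grid search, on the initial-learning-phase trials of the requested
#' blocks (by default blocks 6 to 20, leaving out the first five blocks in
#' which learning strategies are still stabilising). Parameters are fitted
#' jointly across the blocks -- one (tau[, alpha]) per subject per model --
#' and the per-block log-likelihoods at the optimum are retained so that
#' models can later be compared block-wise. Ties are broken towards the
#' first grid point in enumeration order.
#'
#' @param data An `srl_data` dataset (e.g. from [simulate_cohort()] or
#'   [read_trial_log()]).
#' @param models Named list of model templates (family and, for response
#'   patterns, the order string); default [default_model_set()].
#' @param grid A [parameter_grid()].
#' @param blocks Block ids entering the fit.
#' @return An object of class `srl_fit`: `$fits` is a data frame with one
#'   row per subject x model (best tau, alpha, order, total log-likelihood)
#'   and `$ll_blocks[[subject_id]]` the per-block log-likelihood matrix
#'   (models x blocks) at the optimum.
#' @examples
#' spec <- cohort_spec(data.frame(family = "drp", n = 1, tau = 0,
#'                                order = "dfkl"), n_blocks = 8, seed = 1)
#' fit <- fit_models(simulate_cohort(spec), blocks = 6:8)
#' summary(fit)
#' @export
fit_models <- function(data, models = default_model_set(data$config),
                       grid = parameter_grid(), blocks = 6:20) {
  stopifnot(inherits(data, "srl_data"))
  if (is.null(names(models)) || anyDuplicated(names(models)))
    stop("models must be a uniquely named list")
  config <- data$config
  rows <- list()
  ll_blocks <- list()
  for (subject in data$subjects) {
    have <- vapply(subject$blocks, `[[`, integer(1), "block_id")
    use <- intersect(blocks, have)
    llb <- matrix(NA_real_, length(models), length(use),
                  dimnames = list(names(models), paste0("block_", use)))
    for (m in seq_along(models)) {
      res <- fit_one(models[[m]], subject, grid, use, config)
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = subject$subject_id, model = names(models)[m],
        family = models[[m]]$family, tau = res$tau, alpha = res$alpha,
        order = res$order, ll_total = res$ll_total,
        stringsAsFactors = FALSE)
      llb[m, ] <- res$ll_blocks
    }
    ll_blocks[[subject$subject_id]] <- llb
  }
  structure(list(fits = do.call(rbind, rows), ll_blocks = ll_blocks,
                 models = models, grid = grid, blocks = blocks,
                 config = config, data = data),
            class = "srl_fit")
}

#' @export
print.srl_fit <- function(x, ...) {
  cat(sprintf("Grid maximum-likelihood fits: %d subject(s) x %d model(s), blocks %s\n",
              length(x$ll_blocks), length(x$models),
              paste(range(x$blocks), collapse = "-")))
  cat("Models:", paste(names(x$models), collapse = ", "), "\n")
  invisible(x)
}

#' @describeIn fit_models Best model per subject by total log-likelihood,
#'   with the winning parameters.
#' @param object,x An `srl_fit`.
#' @param ... Unused.
#' @export
summary.srl_fit <- function(object, ...) {
  best <- do.call(rbind, lapply(split(object$fits, object$fits$subject_id),
                                function(d) d[which.max(d$ll_total), ]))
  best <- best[order(best$subject_id), ]
  rownames(best) <- NULL
  structure(list(best = best, n_models = length(object$models)),
            class = "summary.srl_fit")
}

#' @export
print.summary.srl_fit <- function(x, ...) {
  cat(sprintf("Best of %d models per subject (by total log-likelihood):\n",
              x$n_models))
  print(table(x$best$model))
  invisible(x)
}

#' @describeIn fit_models Fitted parameters, one row per subject x model.
#' @export
coef.srl_fit <- function(object, ...) {
  object$fits[, c("subject_id", "model", "tau", "alpha", "order")]
}

#' @describeIn fit_models Total log-likelihood over all subjects and
#'   models (matrix subjects x models).
#' @export
logLik.srl_fit <- function(object, ...) {
  with(object$fits,
       tapply(ll_total, list(subject_id, model), identity))
}
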