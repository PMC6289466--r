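#' Classify one error trial
#'
#' Errors (negative-feedback trials) are categorised against the ideal
#' observer run on the trial's history prefix -- the same reference for
#' human and model data alike, independent of whatever internal state the
#' behaving agent had:
#' \itemize{
#'   \item `optimal`: the chosen response had maximal probability of being
#'     correct under noise-free free optimal play;
#'   \item `suboptimal`: nonzero but not maximal probability;
#'   \item `repeatedly_wrong`: this stimulus-response pair had already
#'     received negative feedback;
#'   \item `correct_for_different_stimulus`: the response had already been
#'     confirmed for another stimulus;
#'   \item `both_rw_and_cfds`: both of the above;
#'   \item `neither_rw_nor_cfds`: zero-probability error that is neither --
#'     an indirect inference across stimulus-response pairs would have
#'     yielded the correct response;
#'   \item `after_first_correct`: the stimulus had already been answered
#'     correctly before.
#' }
#' A trial can carry several labels; `optimal`, `suboptimal` and the
#' zero-probability group partition all errors.
#'
#' @param block An `srl_block`.
#' @param trial 1-based index of a negative-feedback trial.
#' @param set Optional `consistency_set` already conditioned on trials
#'   `1..trial-1` (saves the replay when classifying many trials).
#' @return Character vector of applicable category labels.
#' @export
classify_error <- function(block, trial, set = NULL) {
  if (block$feedback[trial] != 0L)
    stop("classify_error expects a negative-feedback trial")
  if (is.null(set)) {
    pre <- seq_len(trial - 1L)
    set <- consistency_init(length(block$mapping))
    for (t in pre)
      set <- consistency_update(set, block$stimulus[t], block$response[t],
                                block$feedback[t])
  }
  s <- block$stimulus[trial]
  r <- block$response[trial]
  row <- marginal_row(set, s)
  p <- row[r]
  mx <- max(row)
  pre <- seq_len(trial - 1L)
  rw <- any(block$stimulus[pre] == s & block$response[pre] == r &
              block$feedback[pre] == 0L)
  cfds <- any(block$stimulus[pre] != s & block$response[pre] == r &
                block$feedback[pre] == 1L)
  labels <- c(
    if (p == mx) "optimal",
    if (p > 0 && p < mx) "suboptimal",
    if (rw) "repeatedly_wrong",
    if (cfds) "correct_for_different_stimulus",
    if (rw && cfds) "both_rw_and_cfds",
    if (p == 0 && !rw && !cfds) "neither_rw_nor_cfds",
    if (any(block$stimulus[pre] == s & block$feedback[pre] == 1L))
      "after_first_correct")
  labels
}

#' The seven error categories
#' @return Character vector of category labels in canonical order.
#' @export
error_categories <- function() {
  c("optimal", "suboptimal", "repeatedly_wrong",
    "correct_for_different_stimulus", "both_rw_and_cfds",
    "neither_rw_nor_cfds", "after_first_correct")
}

## classify all initial-phase errors of one block; returns counts per category
block_error_counts <- function(block, window = likelihood_window(block)) {
  counts <- setNames(numeric(length(error_categories())), error_categories())
  set <- consistency_init(length(block$mapping))
  for (t in seq_len(window)) {
    if (block$feedback[t] == 0L) {
      labs <- classify_error(block, t, set = set)
      counts[labs] <- counts[labs] + 1
    }
    set <- consistency_update(set, block$stimulus[t], block$response[t],
                              block$feedback[t])
  }
  counts
}

#' Per-subject error profile
#'
#' Counts errors of each category on the initial-learning-phase trials of
#' the requested blocks and averages the counts across blocks, giving one
#' mean count per category per subject.
#'
#' @param data An `srl_data` dataset.
#' @param blocks Block ids to include (default 6 to 20).
#' @return Data frame: subject_id, category, mean_count.
#' @export
error_profile <- function(data, blocks = 6:20) {
  stopifnot(inherits(data, "srl_data"))
  rows <- lapply(data$subjects, function(subject) {
    use <- Filter(function(b) b$block_id %in% blocks, subject$blocks)
    if (length(use) == 0L) return(NULL)
    counts <- rowMeans(vapply(use, block_error_counts,
                              numeric(length(error_categories()))))
    data.frame(subject_id = subject$subject_id,
               category = error_categories(),
               mean_count = as.numeric(counts),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Learning curves
#'
#' Probability of a correct response per within-block trial index, with the
#' standard error of the mean across contributing blocks (pooled over
#' subjects).
#'
#' @param data An `srl_data` dataset.
#' @param blocks Block ids to include.
#' @param window `"initial"` restricts each block to its initial learning
#'   phase; `"full"` uses whole blocks.
#' @param truncate_at Last trial index of the curve; the default 17 is the
#'   third quartile of initial-phase lengths; use 32 for the extended
#'   initial-phase view or `NULL` for no truncation.
#' @return Data frame of class `learning_curve`: trial, mean, sem, n.
#' @export
learning_curves <- function(data, blocks = 6:20,
                            window = c("initial", "full"),
                            truncate_at = 17L) {
  stopifnot(inherits(data, "srl_data"))
  window <- match.arg(window)
  vals <- list()
  for (subject in data$subjects) {
    for (b in Filter(function(b) b$block_id %in% blocks, subject$blocks)) {
      last <- if (window == "initial") likelihood_window(b)
              else length(b$stimulus)
      if (!is.null(truncate_at)) last <- min(last, truncate_at)
      if (last >= 1L)
        vals[[length(vals) + 1L]] <- cbind(seq_len(last),
                                           b$feedback[seq_len(last)])
    }
  }
  if (length(vals) == 0L) stop("no blocks selected")
  m <- do.call(rbind, vals)
  trial <- sort(unique(m[, 1L]))
  stats <- vapply(trial, function(t) {
    x <- m[m[, 1L] == t, 2L]
    c(mean(x), stats::sd(x) / sqrt(length(x)), length(x))
  }, numeric(3))
  out <- data.frame(trial = trial, mean = stats[1, ], sem = stats[2, ],
                    n = as.integer(stats[3, ]))
  class(out) <- c("learning_curve", "data.frame")
  out
}

#' @export
print.learning_curve <- function(x, ...) {
  cat(sprintf("Learning curve over trials %d-%d (n = %d blocks at trial 1)\n",
              min(x$trial), max(x$trial), x$n[1L]))
  print.data.frame(x, row.names = FALSE, digits = 3)
  invisible(x)
}

#' @export
plot.learning_curve <- function(x, ...) {
  graphics::plot(x$trial, x$mean, type = "b", ylim = c(0, 1),
                 xlab = "Trial", ylab = "P(correct)", ...)
  graphics::arrows(x$trial, x$mean - x$sem, x$trial, x$mean + x$sem,
                   angle = 90, code = 3, length = 0.03)
  graphics::abline(h = 0.25, lty = 3)
  invisible(x)
}

#' Generative replay of a fitted subject
#'
#' Simulates response data from a subject's maximum-likelihood model: for
#' each of the subject's fitted blocks, `n_reps` blocks are regenerated
#' with the block's true mapping (stimulus sequences redrawn under the
#' sequencing policy) and the subject-specific fitted parameters. The
#' result feeds [learning_curves()] and [error_profile()] for generative
#' model checks.
#'
#' @param fit An [fit_models()] result.
#' @param subject_id Subject to replay.
#' @param model Model name within the fit; defaults to the subject's
#'   best-likelihood model.
#' @param n_reps Replications per block.
#' @param seed Optional seed for reproducibility.
#' @return An `srl_data` dataset whose subjects are the replicates.
#' @export
generative_replay <- function(fit, subject_id, model = NULL, n_reps = 1000L,
                              seed = NULL) {
  stopifnot(inherits(fit, "srl_fit"))
  d <- fit$fits[fit$fits$subject_id == subject_id, ]
  if (nrow(d) == 0L) stop("unknown subject_id: ", subject_id)
  if (is.null(model)) model <- d$model[which.max(d$ll_total)]
  row <- d[d$model == model, ]
  if (nrow(row) != 1L) stop("unknown model: ", model)
  params <- model_params(row$family, tau = row$tau,
                         alpha = if (!is.na(row$alpha)) row$alpha,
                         order = if (!is.na(row$order)) row$order,
                         config = fit$config)
  idx <- vapply(fit$data$subjects, `[[`, character(1), "subject_id")
  subject <- fit$data$subjects[[match(subject_id, idx)]]
  use <- Filter(function(b) b$block_id %in% fit$blocks, subject$blocks)
  if (!is.null(seed)) set.seed(seed)
  reps <- lapply(seq_len(n_reps), function(r) {
    blocks <- lapply(use, function(b)
      simulate_block(params, b$mapping, b$block_id, fit$config))
    srl_subject(sprintf("%s_rep%04d", subject_id, r), blocks)
  })
  srl_data(reps, fit$config)
}

#' @describeIn generative_replay `simulate()` method: generative replay of
#'   one fitted subject (`nsim` replications per block).
#' @param object An `srl_fit`.
#' @param nsim Replications per block.
#' @param ... Passed on to `generative_replay()` (`subject_id`, `model`).
#' @export
simulate.srl_fit <- function(object, nsim = 1L, seed = NULL, ...) {
  generative_replay(object, n_reps = nsim, seed = seed, ...)
}

#' Count optimal errors of a block
#'
#' Number of negative-feedback trials on which the chosen response
#' nevertheless had maximal probability of being correct under noise-free
#' free optimal play given the history prefix.
#'
#' @param block An `srl_block`.
#' @return Named numeric: `optimal` and `total` error counts.
#' @export
count_optimal_errors <- function(block) {
  set <- consistency_init(length(block$mapping))
  optimal <- 0L; total <- 0L
  for (t in seq_along(block$stimulus)) {
    if (block$feedback[t] == 0L) {
      total <- total + 1L
      row <- marginal_row(set, block$stimulus[t])
      if (row[block$response[t]] == max(row)) optimal <- optimal + 1L
    }
    set <- consistency_update(set, block$stimulus[t], block$response[t],
                              block$feedback[t])
  }
  c(optimal = optimal, total = total)
}

## simulate a noise-free response-pattern block with the stimulus draws
## taken from a shared uniform stream, so different response orders can be
## run on the same underlying sequence randomness
simulate_block_stream <- function(params, mapping, u, config = task_config()) {
  n <- config$n_stimuli
  state <- model_init(params, config)
  max_t <- config$max_trials
  stim <- integer(max_t); resp <- integer(max_t); fb <- integer(max_t)
  pos <- integer(n)
  t <- 0L
  repeat {
    t <- t + 1L
    open <- which(pos < config$correct_reps_to_finish)
    s <- open[min(length(open), floor(u[t] * length(open)) + 1L)]
    probs <- softmax_select(model_prefs(state, s), params$tau)
    r <- which.max(probs)  # noise-free deterministic policies only
    f <- feedback_for(mapping, s, r)
    stim[t] <- s; resp[t] <- r; fb[t] <- f
    if (f == 1L) pos[s] <- pos[s] + 1L
    state <- model_update(state, s, r, f, params)
    if (block_finished(stim[seq_len(t)], fb[seq_len(t)], config)) break
  }
  new_block(1L, mapping, stim[seq_len(t)], resp[seq_len(t)], fb[seq_len(t)])
}

#' Invariance of the optimal-error distribution under noise-free play
#'
#' Checks two properties of noise-free optimal play: (a) on any stimulus
#' sequence, the multiset of optimal-error counts produced by the 24
#' response orders is the same; (b) the distribution of optimal-error
#' counts under noise-free free optimal play converges to that same
#' distribution. Response orders within one sequence replicate share the
#' stimulus-randomness stream.
#'
#' @param n_sequences Number of random stimulus sequences for the 24-order
#'   check.
#' @param n_reps Number of free-optimal-play replays.
#' @param seed Seed.
#' @param config A [task_config()].
#' @return List of class `s4_check`: `order_counts` (sequences x 24 matrix
#'   of optimal-error counts, each row sorted), `invariant` (were all rows
#'   identical?), `fop_counts` (per-replay counts), `tv` (total-variation
#'   distance between the two distributions).
#' @export
s4_check <- function(n_sequences = 20L, n_reps = 1e4L, seed = 1L,
                     config = task_config()) {
  set.seed(seed)
  perms <- enumerate_mappings(config$n_responses)
  orders <- apply(perms, 1L, order_label, config = config)
  oc <- matrix(NA_integer_, n_sequences, nrow(perms))
  for (k in seq_len(n_sequences)) {
    u <- stats::runif(config$max_trials)
    mapping <- perms[sample.int(nrow(perms), 1L), ]
    for (j in seq_along(orders)) {
      params <- model_params("drp", tau = 0, order = orders[j],
                             config = config)
      b <- simulate_block_stream(params, mapping, u, config)
      oc[k, j] <- count_optimal_errors(b)[["optimal"]]
    }
  }
  sorted <- t(apply(oc, 1L, sort))
  invariant <- all(apply(sorted, 2L, function(col) length(unique(col)) == 1L))
  fop_params <- model_params("fop", tau = 0, config = config)
  fop_counts <- integer(n_reps)
  for (r in seq_len(n_reps)) {
    mapping <- perms[sample.int(nrow(perms), 1L), ]
    b <- simulate_block(fop_params, mapping, 1L, config)
    fop_counts[r] <- count_optimal_errors(b)[["optimal"]]
  }
  vals <- 0:max(c(oc, fop_counts))
  p24 <- tabulate(factor(oc, levels = vals)) / length(oc)
  pfop <- tabulate(factor(fop_counts, levels = vals)) / length(fop_counts)
  structure(list(order_counts = sorted, invariant = invariant,
                 fop_counts = fop_counts,
                 reference = setNames(p24, vals),
                 tv = sum(abs(p24 - pfop)) / 2),
            class = "s4_check")
}

#' @export
print.s4_check <- function(x, ...) {
  cat("Optimal-error distribution under noise-free play\n")
  cat(sprintf("24-order multiset identical across %d sequences: %s\n",
              nrow(x$order_counts), x$invariant))
  cat("Reference distribution over error counts:\n")
  print(round(x$reference, 4))
  cat(sprintf("Total variation (free optimal play, %d replays): %.4f\n",
              length(x$fop_counts), x$tv))
  invisible(x)
}
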