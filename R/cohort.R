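#' Draw the next stimulus
#'
#' Stimuli are presented in randomized order: uniformly among the stimuli
#' that have not yet reached the required number of correct repetitions.
#' Immediate repeats are allowed.
#'
#' @param pos_counts Integer vector of positive-feedback counts per stimulus
#'   so far in the block.
#' @param config A [task_config()].
#' @return A stimulus index.
#' @export
simulate_stimulus <- function(pos_counts, config = task_config()) {
  open <- which(pos_counts < config$correct_reps_to_finish)
  if (length(open) == 0L) stop("block already finished")
  if (length(open) == 1L) open else open[sample.int(length(open), 1L)]
}

#' Simulate one learning block from a model
#'
#' Runs the model policy against a true mapping with deterministic feedback:
#' each trial draws a stimulus among the unfinished ones, samples a response
#' from the model's softmax distribution, delivers feedback from the
#' mapping, and updates the model state, until the block termination rule
#' fires. Uses the current RNG state.
#'
#' @param params A [model_params()] object.
#' @param mapping True mapping for the block (integer permutation).
#' @param block_id Block number.
#' @param config A [task_config()].
#' @return An `srl_block`.
#' @export
simulate_block <- function(params, mapping, block_id = 1L,
                           config = task_config()) {
  n <- config$n_stimuli
  state <- model_init(params, config)
  max_t <- config$max_trials
  stim <- integer(max_t); resp <- integer(max_t); fb <- integer(max_t)
  pos <- integer(n)
  t <- 0L
  repeat {
    t <- t + 1L
    s <- simulate_stimulus(pos, config)
    probs <- softmax_select(model_prefs(state, s), params$tau)
    r <- sample.int(n, 1L, prob = probs)
    f <- feedback_for(mapping, s, r)
    stim[t] <- s; resp[t] <- r; fb[t] <- f
    if (f == 1L) pos[s] <- pos[s] + 1L
    state <- model_update(state, s, r, f, params)
    if (block_finished(stim[seq_len(t)], fb[seq_len(t)], config)) break
  }
  new_block(block_id, mapping, stim[seq_len(t)], resp[seq_len(t)], fb[seq_len(t)])
}

## simulate one subject: fresh uniform-random mapping per block
simulate_subject <- function(subject_id, params, n_blocks = 20L,
                             config = task_config()) {
  perms <- enumerate_mappings(config$n_stimuli)
  blocks <- lapply(seq_len(n_blocks), function(b) {
    mapping <- perms[sample.int(nrow(perms), 1L), ]
    simulate_block(params, mapping, block_id = b, config = config)
  })
  srl_subject(subject_id, blocks)
}

#' Specify a synthetic cohort
#'
#' A cohort specification lists, per generative model family, how many
#' subjects to simulate and with what parameters. The default mirrors the
#' composition inferred for the human sample: 36 subjects following the
#' left-to-right response pattern dfkl, 7 the right-to-left pattern lkfd,
#' 18 free-optimal-play, 19 binarized-play and 5 Q-learning subjects
#' (85 in total), each with moderate selection noise tau = 1/4 and, for
#' Q-learning, learning rate alpha = 0.5.
#'
#' @param groups Data frame with columns `family` ("q", "fop", "bp",
#'   "drp"), `n` (subjects), `tau`, and optionally `alpha` and `order`.
#' @param n_blocks Blocks per subject.
#' @param config A [task_config()].
#' @param seed Master seed; per-subject streams are derived from it so
#'   cohorts are bit-reproducible and subjects independent.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(groups = NULL, n_blocks = 20L,
                        config = task_config(), seed = 1L) {
  if (is.null(groups))
    groups <- data.frame(
      family = c("drp", "drp", "fop", "bp", "q"),
      n      = c(36L, 7L, 18L, 19L, 5L),
      tau    = 0.25,
      alpha  = c(NA, NA, NA, NA, 0.5),
      order  = c("dfkl", "lkfd", NA, NA, NA),
      stringsAsFactors = FALSE)
  if (!all(c("family", "n", "tau") %in% names(groups)))
    stop("groups needs columns family, n, tau")
  if (is.null(groups$alpha)) groups$alpha <- NA_real_
  if (is.null(groups$order)) groups$order <- NA_character_
  if (sum(groups$n) < 1L) stop("cohort must contain at least one subject")
  ## validate each group's parameters up front
  for (g in seq_len(nrow(groups)))
    model_params(groups$family[g], tau = groups$tau[g],
                 alpha = if (!is.na(groups$alpha[g])) groups$alpha[g],
                 order = if (!is.na(groups$order[g])) groups$order[g],
                 config = config)
  structure(list(groups = groups, n_blocks = as.integer(n_blocks),
                 config = config, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Simulate a synthetic cohort
#'
#' Generates every subject described by the specification, each from its own
#' RNG stream derived from the master seed, with a fresh uniformly drawn
#' mapping per block. The returned dataset carries a ground-truth manifest
#' (subject, generating family, parameters, stream seed) as attribute
#' `"manifest"`.
#'
#' @param spec A [cohort_spec()].
#' @return An `srl_data` dataset with a `manifest` attribute.
#' @examples
#' spec <- cohort_spec(data.frame(family = "drp", n = 2, tau = 0,
#'                                order = "dfkl"), seed = 7)
#' dat <- simulate_cohort(spec)
#' attr(dat, "manifest")
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  g <- spec$groups
  fam <- rep(g$family, g$n)
  tau <- rep(g$tau, g$n)
  alpha <- rep(g$alpha, g$n)
  order <- rep(g$order, g$n)
  n_sub <- length(fam)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(spec$seed)
  sub_seeds <- sample.int(.Machine$integer.max, n_sub)
  subjects <- vector("list", n_sub)
  label <- character(n_sub)
  for (i in seq_len(n_sub)) {
    label[i] <- if (fam[i] == "drp") paste0("drp_", order[i]) else fam[i]
    params <- model_params(fam[i], tau = tau[i],
                           alpha = if (!is.na(alpha[i])) alpha[i],
                           order = if (!is.na(order[i])) order[i],
                           config = spec$config)
    set.seed(sub_seeds[i])
    subjects[[i]] <- simulate_subject(sprintf("sub%03d", i), params,
                                      spec$n_blocks, spec$config)
  }
  dat <- srl_data(subjects, spec$config)
  attr(dat, "manifest") <- data.frame(
    subject_id = vapply(subjects, `[[`, character(1), "subject_id"),
    family = fam, model = label, tau = tau, alpha = alpha, order = order,
    seed = sub_seeds, stringsAsFactors = FALSE)
  dat
}
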