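#' Task configuration
#'
#' Describes the stimulus-response learning task: `n_stimuli` novel stimuli
#' per block map one-to-one onto `n_responses` fixed response keys, feedback
#' is deterministic, and a block ends once every stimulus has been answered
#' correctly `correct_reps_to_finish` times or after `max_trials` trials,
#' whichever comes first.
#'
#' The default configuration is the four-alternative task: 4 stimuli, the
#' response keys d, f, k, l (left middle, left index, right index, right
#' middle finger), 8 correct repetitions per stimulus, 70-trial cap.
#'
#' @param n_stimuli Number of stimuli per block.
#' @param response_labels Ordered response labels; canonical keyboard order
#'   is `c("d","f","k","l")`. The number of responses equals
#'   `length(response_labels)` and must equal `n_stimuli`.
#' @param correct_reps_to_finish Correct repetitions per stimulus required to
#'   finish a block.
#' @param max_trials Hard cap on trials per block.
#' @return An object of class `srl_task`.
#' @examples
#' cfg <- task_config()
#' cfg$response_labels
#' @export
task_config <- function(n_stimuli = 4L,
                        response_labels = c("d", "f", "k", "l"),
                        correct_reps_to_finish = 8L,
                        max_trials = 70L) {
  n_stimuli <- as.integer(n_stimuli)
  correct_reps_to_finish <- as.integer(correct_reps_to_finish)
  max_trials <- as.integer(max_trials)
  if (n_stimuli < 1L) stop("n_stimuli must be >= 1")
  if (length(response_labels) != n_stimuli)
    stop("one-to-one task: need exactly one response label per stimulus")
  if (anyDuplicated(response_labels))
    stop("response labels must be distinct")
  if (correct_reps_to_finish < 1L) stop("correct_reps_to_finish must be >= 1")
  if (max_trials < n_stimuli) stop("max_trials must be >= n_stimuli")
  structure(
    list(n_stimuli = n_stimuli,
         n_responses = n_stimuli,
         response_labels = as.character(response_labels),
         stimulus_labels = paste0("S", seq_len(n_stimuli)),
         correct_reps_to_finish = correct_reps_to_finish,
         max_trials = max_trials),
    class = "srl_task")
}

#' @export
print.srl_task <- function(x, ...) {
  cat(sprintf(
    "Trial-and-error learning task: %d stimuli -> responses {%s} (one-to-one),\n",
    x$n_stimuli, paste(x$response_labels, collapse = ",")))
  cat(sprintf("deterministic feedback; block ends at %d corrects/stimulus or %d trials.\n",
              x$correct_reps_to_finish, x$max_trials))
  invisible(x)
}

#' Deterministic feedback rule
#'
#' Positive feedback if and only if the response is the one the block's true
#' mapping assigns to the stimulus.
#'
#' @param mapping Integer vector: `mapping[i]` is the correct response index
#'   for stimulus `i`; must be a permutation.
#' @param stimulus Stimulus index (1-based).
#' @param response Response index (1-based).
#' @return 1L for positive feedback, 0L for negative.
#' @export
feedback_for <- function(mapping, stimulus, response) {
  n <- length(mapping)
  if (stimulus < 1L || stimulus > n || response < 1L || response > n)
    stop("stimulus/response index out of range")
  as.integer(mapping[stimulus] == response)
}

#' Block termination rule
#'
#' A block is finished once every stimulus has accumulated
#' `correct_reps_to_finish` positive-feedback trials, or once the trial count
#' reaches `max_trials`.
#'
#' @param stimulus,feedback Parallel integer vectors of the trials so far.
#' @param config A [task_config()] object.
#' @return Logical scalar.
#' @export
block_finished <- function(stimulus, feedback, config = task_config()) {
  n_trials <- length(stimulus)
  if (n_trials >= config$max_trials) return(TRUE)
  if (n_trials == 0L) return(FALSE)
  pos <- tabulate(stimulus[feedback == 1L], nbins = config$n_stimuli)
  all(pos >= config$correct_reps_to_finish)
}

## internal block constructor; column-vector trial storage
new_block <- function(block_id, mapping, stimulus, response, feedback) {
  structure(
    list(block_id = as.integer(block_id),
         mapping = as.integer(mapping),
         stimulus = as.integer(stimulus),
         response = as.integer(response),
         feedback = as.integer(feedback)),
    class = "srl_block")
}

#' Assemble and validate a learning block
#'
#' Checks that the mapping is a permutation, that the trial vectors are
#' aligned, and that every feedback value agrees with the deterministic
#' feedback rule under the block's mapping.
#'
#' @param block_id Block number (1-based).
#' @param mapping Integer permutation giving each stimulus its correct
#'   response index.
#' @param stimulus,response,feedback Parallel trial vectors.
#' @param config A [task_config()].
#' @return An object of class `srl_block`.
#' @export
srl_block <- function(block_id, mapping, stimulus, response, feedback,
                      config = task_config()) {
  mapping <- as.integer(mapping)
  if (length(mapping) != config$n_stimuli ||
      !identical(sort(mapping), seq_len(config$n_stimuli)))
    stop("mapping must be a permutation of 1..n_stimuli")
  n <- length(stimulus)
  if (length(response) != n || length(feedback) != n)
    stop("trial vectors must have equal length")
  if (n > config$max_trials)
    stop("block exceeds max_trials")
  bad <- which(as.integer(feedback) != as.integer(mapping[stimulus] == response))
  if (length(bad))
    stop(sprintf("feedback inconsistent with mapping at trial(s) %s",
                 paste(bad, collapse = ", ")))
  new_block(block_id, mapping, stimulus, response, feedback)
}

#' @export
print.srl_block <- function(x, ...) {
  cat(sprintf("Block %d: %d trials, %d errors; mapping %s\n",
              x$block_id, length(x$stimulus), sum(x$feedback == 0L),
              paste(x$mapping, collapse = "")))
  invisible(x)
}

#' Bundle blocks into a subject dataset
#'
#' @param subject_id Subject identifier (coerced to character).
#' @param blocks List of `srl_block` objects with distinct block ids.
#' @return An object of class `srl_subject`.
#' @export
srl_subject <- function(subject_id, blocks) {
  ids <- vapply(blocks, `[[`, integer(1), "block_id")
  if (anyDuplicated(ids)) stop("duplicate block ids")
  structure(list(subject_id = as.character(subject_id),
                 blocks = blocks[order(ids)]),
            class = "srl_subject")
}

#' Bundle subjects into a dataset
#'
#' @param subjects List of `srl_subject` objects.
#' @param config The shared [task_config()].
#' @return An object of class `srl_data`.
#' @export
srl_data <- function(subjects, config = task_config()) {
  ids <- vapply(subjects, `[[`, character(1), "subject_id")
  if (anyDuplicated(ids)) stop("duplicate subject ids")
  structure(list(subjects = subjects, config = config), class = "srl_data")
}

#' @export
print.srl_data <- function(x, ...) {
  nb <- vapply(x$subjects, function(s) length(s$blocks), integer(1))
  cat(sprintf("Trial-log dataset: %d subject(s), %s block(s) each\n",
              length(x$subjects),
              if (length(nb)) paste(range(nb), collapse = "-") else "0"))
  invisible(x)
}

## label helpers: internal integer indices <-> external labels
response_index <- function(labels, config) {
  idx <- match(labels, config$response_labels)
  if (anyNA(idx)) stop("unknown response label(s): ",
                       paste(unique(labels[is.na(idx)]), collapse = ", "))
  idx
}

#' Parse a response-order string
#'
#' A deterministic response pattern is named by the order in which it tests
#' the responses, e.g. `"dfkl"` (left to right on the keyboard) or `"lkfd"`.
#'
#' @param order Order string over the configured response alphabet.
#' @param config A [task_config()].
#' @return Integer permutation of response indices.
#' @export
parse_order <- function(order, config = task_config()) {
  chars <- strsplit(order, "")[[1]]
  if (length(chars) != config$n_responses ||
      !setequal(chars, config$response_labels))
    stop(sprintf("order must be a permutation of '%s'",
                 paste(config$response_labels, collapse = "")))
  match(chars, config$response_labels)
}

order_label <- function(order_idx, config = task_config()) {
  paste(config$response_labels[order_idx], collapse = "")
}
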