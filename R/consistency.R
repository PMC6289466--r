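#' Enumerate all one-to-one stimulus-response mappings
#'
#' With n stimuli and n responses and the one-to-one constraint there are n!
#' candidate mappings; for the four-alternative task, 4! = 24. Mappings are
#' returned in lexicographic order, one per row.
#'
#' @param n Number of stimuli (= responses).
#' @return Integer matrix with n! rows; row m gives, for each stimulus, its
#'   correct response index under candidate mapping m.
#' @examples
#' nrow(enumerate_mappings(4)) # 24
#' @export
enumerate_mappings <- function(n) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("n must be >= 1")
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- enumerate_mappings(n - 1L)
  out <- matrix(0L, nrow = factorial(n), ncol = n)
  k <- nrow(sub)
  for (first in seq_len(n)) {
    rows <- (first - 1L) * k + seq_len(k)
    rest <- seq_len(n)[-first]
    out[rows, 1L] <- first
    out[rows, -1L] <- matrix(rest[sub], k, n - 1L)
  }
  out
}

#' Initialise a consistency set
#'
#' The consistency set is the ideal observer's state: the subset of candidate
#' one-to-one mappings compatible with the stimulus-response-outcome history
#' observed so far. At the start of a block no mapping is ruled out, so each
#' of the n! candidates has prior probability 1/n!.
#'
#' @param n Number of stimuli.
#' @return An object of class `consistency_set`.
#' @export
consistency_init <- function(n = 4L) {
  perms <- enumerate_mappings(n)
  structure(list(n = as.integer(n), perms = perms,
                 keep = rep(TRUE, nrow(perms))),
            class = "consistency_set")
}

#' @export
print.consistency_set <- function(x, ...) {
  cat(sprintf("Consistency set: %d of %d candidate mappings remain\n",
              sum(x$keep), nrow(x$perms)))
  invisible(x)
}

#' Number of consistent mappings
#' @param set A `consistency_set`.
#' @return Integer count of remaining members.
#' @export
consistency_size <- function(set) sum(set$keep)

#' Condition a consistency set on one trial
#'
#' With deterministic feedback a trial is decisive evidence: negative
#' feedback excludes every mapping that assigns the tried response to the
#' stimulus; positive feedback retains only those mappings (which also blocks
#' that response for every other stimulus).
#'
#' @param set A `consistency_set`.
#' @param stimulus,response Trial indices (1-based).
#' @param feedback 1 (positive) or 0 (negative).
#' @return The conditioned `consistency_set`.
#' @export
consistency_update <- function(set, stimulus, response, feedback) {
  hit <- set$perms[, stimulus] == response
  keep <- if (feedback == 1L) set$keep & hit else set$keep & !hit
  if (!any(keep))
    stop("inconsistent history: no one-to-one mapping matches the observed trials")
  set$keep <- keep
  set
}

#' Per-stimulus response probabilities of the ideal observer
#'
#' Averages over the surviving mappings: entry (i, j) is the fraction of
#' consistent mappings that assign response j to stimulus i. This is the
#' probability table free optimal play acts on.
#'
#' @param set A `consistency_set`.
#' @return n x n numeric matrix; each row sums to 1.
#' @export
consistency_marginals <- function(set) {
  m <- set$perms[set$keep, , drop = FALSE]
  if (nrow(m) == 0L) stop("inconsistent history: empty consistency set")
  p <- vapply(seq_len(set$n),
              function(i) tabulate(m[, i], nbins = set$n),
              numeric(set$n))
  t(p) / nrow(m)
}

## marginal row for one stimulus -- hot path used by simulation and fitting
marginal_row <- function(set, stimulus) {
  m <- set$perms[set$keep, stimulus]
  tabulate(m, nbins = set$n) / length(m)
}

#' Replay a trial history through the consistency engine
#'
#' @param stimulus,response,feedback Parallel trial vectors of one block.
#' @param n Number of stimuli.
#' @return List of `consistency_set` objects of length `n_trials + 1`;
#'   element t+1 is the state after conditioning on trials 1..t, element 1
#'   the full prior set.
#' @export
replay_history <- function(stimulus, response, feedback, n = 4L) {
  set <- consistency_init(n)
  out <- vector("list", length(stimulus) + 1L)
  out[[1L]] <- set
  for (t in seq_along(stimulus)) {
    set <- consistency_update(set, stimulus[t], response[t], feedback[t])
    out[[t + 1L]] <- set
  }
  out
}
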