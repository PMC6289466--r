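# Independent oracles and shared fixtures for the test suite.

# The worked example of the response-pattern figure: order dfkl, true mapping
# S1->f, S2->d, S3->l, S4->k; six depicted trials.
fig3_mapping <- function() c(2L, 1L, 4L, 3L)
fig3_stimuli <- function() c(1L, 2L, 1L, 3L, 3L, 4L)
fig3_responses <- function() c(1L, 1L, 2L, 3L, 4L, 3L)
fig3_feedback <- function() c(0L, 1L, 1L, 0L, 1L, 1L)
fig3_block <- function() {
  srl_block(1L, fig3_mapping(), fig3_stimuli(), fig3_responses(),
            fig3_feedback())
}

# Independent enumeration of all one-to-one mappings of 4 stimuli, built via
# expand.grid rather than the package's recursive generator.
oracle_perm_table <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      g <- as.matrix(expand.grid(1:4, 1:4, 1:4, 1:4))
      tab <<- unname(g[apply(g, 1, function(r) length(unique(r)) == 4L), ,
                       drop = FALSE])
    }
    tab
  }
})

# Monte-Carlo rejection oracle for the ideal observer's marginals: sample
# uniform one-to-one mappings, keep those consistent with the history,
# tabulate where each stimulus maps.
mc_fop_oracle <- function(stimulus, response, feedback, n_samples = 1e5) {
  tab <- oracle_perm_table()
  draws <- tab[sample.int(nrow(tab), n_samples, replace = TRUE), ,
               drop = FALSE]
  ok <- rep(TRUE, n_samples)
  for (t in seq_along(stimulus))
    ok <- ok & ((draws[, stimulus[t]] == response[t]) == (feedback[t] == 1L))
  kept <- draws[ok, , drop = FALSE]
  stopifnot(nrow(kept) > 0L)
  t(vapply(1:4, function(i) tabulate(kept[, i], nbins = 4L), numeric(4))) /
    nrow(kept)
}

# Full 2^n enumeration of the one-sided signed-rank null (zeros dropped,
# midranks): exact tail probability of the observed positive-rank sum.
enum_signed_rank_p <- function(x, y) {
  d <- x - y
  d <- d[abs(d) > 1e-9]
  n <- length(d)
  if (n == 0L) return(1)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_null <- as.numeric(signs %*% r)
  mean(w_null >= w_obs - 1e-9)
}

# A noisy random trial history: the first k trials of a simulated block.
random_history <- function(k = 3L, tau = 0.5, family = "fop") {
  perms <- enumerate_mappings(4)
  mapping <- perms[sample.int(24, 1), ]
  params <- model_params(family, tau = tau,
                         alpha = if (family == "q") 0.5)
  b <- simulate_block(params, mapping)
  k <- min(k, length(b$stimulus))
  list(stimulus = b$stimulus[seq_len(k)], response = b$response[seq_len(k)],
       feedback = b$feedback[seq_len(k)])
}

# Small cohorts used by several test files.
tiny_cohort <- function(family = "drp", n = 2L, tau = 0, order = "dfkl",
                        alpha = NA, n_blocks = 8L, seed = 11L) {
  spec <- cohort_spec(data.frame(family = family, n = n, tau = tau,
                                 alpha = alpha,
                                 order = if (family == "drp") order else NA,
                                 stringsAsFactors = FALSE),
                      n_blocks = n_blocks, seed = seed)
  simulate_cohort(spec)
}
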