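test_that("error classification follows the ideal-observer reference", {
  # first trial of a block: every response is optimal
  b1 <- srl_block(1, fig3_mapping(), 1L, 1L, 0L)
  expect_true("optimal" %in% classify_error(b1, 1L))
  # the worked ideal-observer history: S1-d falsified, then S2-l is a
  # suboptimal error (d was more likely than l for S2)
  b2 <- srl_block(1, c(2L, 3L, 4L, 1L), c(1L, 2L), c(1L, 4L), c(0L, 0L))
  labs <- classify_error(b2, 2L)
  expect_true("suboptimal" %in% labs)
  expect_false("optimal" %in% labs)
  # responding d to S3 after d was confirmed for S2: zero probability,
  # correct for a different stimulus
  b3 <- srl_block(1, c(2L, 1L, 4L, 3L), c(2L, 3L), c(1L, 1L), c(1L, 0L))
  labs3 <- classify_error(b3, 2L)
  expect_true("correct_for_different_stimulus" %in% labs3)
  expect_false(any(c("optimal", "suboptimal", "repeatedly_wrong") %in% labs3))
  # repeating a falsified response is repeatedly wrong
  b4 <- srl_block(1, c(2L, 1L, 4L, 3L), c(1L, 1L), c(1L, 1L), c(0L, 0L))
  expect_true("repeatedly_wrong" %in% classify_error(b4, 2L))
  expect_error(classify_error(fig3_block(), 2L), "negative-feedback")
})

test_that("every error gets exactly one primary classification", {
  set.seed(97)
  perms <- enumerate_mappings(4)
  for (rep in 1:6) {
    mapping <- perms[sample.int(24, 1), ]
    b <- simulate_block(model_params("fop", tau = 0.8), mapping)
    for (t in which(b$feedback == 0L)) {
      labs <- classify_error(b, t)
      primary <- c("optimal" %in% labs, "suboptimal" %in% labs,
                   any(c("repeatedly_wrong", "correct_for_different_stimulus",
                         "neither_rw_nor_cfds") %in% labs))
      expect_equal(sum(primary), 1L)
    }
  }
})

test_that("noise-free optimal play produces only optimal errors", {
  dat <- tiny_cohort(family = "fop", n = 3L, tau = 0, n_blocks = 10L,
                     seed = 101L)
  prof <- error_profile(dat, blocks = 1:10)
  for (cat in c("suboptimal", "correct_for_different_stimulus",
                "repeatedly_wrong", "neither_rw_nor_cfds"))
    expect_equal(prof$mean_count[prof$category == cat],
                 rep(0, 3L))
  expect_true(all(prof$mean_count[prof$category == "optimal"] > 0))
})

test_that("Q-learners cannot exploit the one-to-one property", {
  dat <- tiny_cohort(family = "q", n = 3L, tau = 0.25, alpha = 0.5,
                     n_blocks = 10L, seed = 103L)
  prof <- error_profile(dat, blocks = 1:10)
  cfds <- prof$mean_count[prof$category == "correct_for_different_stimulus"]
  expect_true(all(cfds > 0))
})

test_that("realized pattern subjects vary more than averaged model replays", {
  # the generative-check contrast: single-realization subject means versus
  # replay-averaged model expectations
  drp <- tiny_cohort(family = "drp", n = 8L, tau = 0, order = "dfkl",
                     n_blocks = 10L, seed = 107L)
  prof <- error_profile(drp, blocks = 1:10)
  drp_means <- prof$mean_count[prof$category == "optimal"]
  fop <- tiny_cohort(family = "fop", n = 8L, tau = 0, n_blocks = 10L,
                     seed = 109L)
  fit <- fit_models(fop, models = list(fop = list(family = "fop")),
                    blocks = 1:10)
  set.seed(7)
  fop_means <- vapply(attr(fop, "manifest")$subject_id, function(sid) {
    rep_dat <- generative_replay(fit, sid, model = "fop", n_reps = 40L)
    p <- error_profile(rep_dat, blocks = 1:10)
    mean(p$mean_count[p$category == "optimal"])
  }, numeric(1))
  expect_gt(stats::var(drp_means), stats::var(fop_means))
})

test_that("learning curves have the right anchors and bookkeeping", {
  drp <- tiny_cohort(family = "drp", n = 5L, tau = 0, order = "dfkl",
                     n_blocks = 20L, seed = 113L)
  cv <- learning_curves(drp, blocks = 1:20, truncate_at = 17L)
  # first response is correct for exactly 1 of 4 equally likely mappings
  expect_lt(abs(cv$mean[cv$trial == 1] - 0.25), 0.1)
  expect_lte(max(cv$trial), 17L)
  expect_true(all(diff(cv$n) <= 0))
  expect_true(all(cv$mean >= 0 & cv$mean <= 1))
  # near-uniform responding gives a flat curve at chance
  noisy <- tiny_cohort(family = "q", n = 2L, tau = 1000, alpha = 0.5,
                       n_blocks = 10L, seed = 127L)
  cvn <- learning_curves(noisy, blocks = 1:10, window = "full",
                         truncate_at = NULL)
  expect_equal(mean(cvn$mean[cvn$n > 10]), 0.25, tolerance = 0.05)
})

test_that("Q-learning plateaus below the softmax ceiling", {
  dat <- tiny_cohort(family = "q", n = 3L, tau = 0.25, alpha = 0.5,
                     n_blocks = 10L, seed = 131L)
  cv <- learning_curves(dat, blocks = 1:10, window = "full",
                        truncate_at = NULL)
  late <- cv$mean[cv$trial >= 30 & cv$n >= 20]
  ceiling <- exp(4) / (exp(4) + 3 * exp(-4))  # q -> +1 vs three at -1
  expect_gt(mean(late), 0.6)
  expect_lt(mean(late), ceiling + 0.01)
})

test_that("generative replay is reproducible and well-formed", {
  dat <- tiny_cohort(family = "drp", n = 1L, tau = 0, order = "dfkl",
                     n_blocks = 8L, seed = 137L)
  fit <- fit_models(dat, blocks = 6:8)
  r1 <- generative_replay(fit, "sub001", model = "drp_dfkl", n_reps = 3L,
                          seed = 5L)
  r2 <- generative_replay(fit, "sub001", model = "drp_dfkl", n_reps = 3L,
                          seed = 5L)
  expect_identical(r1, r2)
  expect_length(r1$subjects, 3L)
  # replays reuse each block's true mapping
  orig <- dat$subjects[[1]]$blocks[[6]]$mapping
  expect_equal(r1$subjects[[1]]$blocks[[1]]$mapping, orig)
  # the simulate() method is the same operation
  r3 <- simulate(fit, nsim = 3L, seed = 5L, subject_id = "sub001",
                 model = "drp_dfkl")
  expect_identical(r1, r3)
})

test_that("the optimal-error multiset is invariant across sequences", {
  chk <- s4_check(n_sequences = 5L, n_reps = 400L, seed = 139L)
  expect_true(chk$invariant)
  expect_true(all(chk$order_counts >= 0 & chk$order_counts <= 6))
  expect_equal(sum(chk$reference), 1)
  expect_lt(chk$tv, 0.2)  # loose at this replay count; tight check elsewhere
})
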