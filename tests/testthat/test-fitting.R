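test_that("the default grid has 31 noise and 20 learning-rate values", {
  g <- parameter_grid()
  expect_length(g$tau, 31L)
  expect_length(g$alpha, 20L)
  expect_equal(g$tau[1], 0)
  expect_equal(g$tau[2], 1 / 6.0)
  expect_equal(g$tau[31], 1 / 0.2)
  expect_equal(g$alpha, seq(0.05, 1, by = 0.05))
})

test_that("the initial learning phase ends at the fourth first-correct", {
  # minimal case: four distinct stimuli, all correct
  b <- srl_block(1, 1:4, 1:4, 1:4, rep(1L, 4))
  expect_equal(initial_phase_end(b), 4L)
  # worked-example block: all four first correct only at the last trial
  expect_equal(initial_phase_end(fig3_block()), 6L)
  # last stimulus first correct at trial 12
  stim <- c(1L, 2L, 3L, rep(4L, 9))
  resp <- c(1L, 2L, 3L, rep(c(1L, 2L, 3L), 2), 1L, 2L, 4L)
  b2 <- srl_block(1, 1:4, stim, resp, as.integer(resp == c(1:4)[stim]))
  expect_equal(initial_phase_end(b2), 12L)
  # a stimulus never answered correctly: phase incomplete
  b3 <- srl_block(1, 1:4, c(1L, 2L, 3L, 4L), c(1L, 2L, 3L, 3L),
                  c(1L, 1L, 1L, 0L))
  expect_true(is.na(initial_phase_end(b3)))
})

test_that("block log-likelihoods match closed forms", {
  b <- fig3_block()
  # any Q-learner's first trial: all values zero, probability 1/4
  q <- model_params("q", tau = 0.5, alpha = 0.3)
  expect_equal(block_loglik(q, b, end_trial = 1L), log(0.25))
  # the noise-free pattern predicts its own block with certainty
  drp <- model_params("drp", tau = 0, order = "dfkl")
  expect_equal(block_loglik(drp, b, end_trial = 6L), 0)
  # large noise pushes every family towards uniform responding
  for (fam in c("fop", "bp", "q")) {
    p <- model_params(fam, tau = 5, alpha = if (fam == "q") 0.5)
    expect_equal(block_loglik(p, b, end_trial = 6L), 6 * log(0.25),
                 tolerance = 0.05)
  }
})

test_that("per-trial log-likelihood terms are never positive", {
  set.seed(41)
  dat <- tiny_cohort(family = "bp", n = 1L, tau = 0.4, n_blocks = 6L,
                     seed = 43L)
  b <- dat$subjects[[1]]$blocks[[6]]
  p <- model_params("fop", tau = 0.3)
  lls <- vapply(seq_len(length(b$stimulus)), function(e)
    block_loglik(p, b, end_trial = e), numeric(1))
  expect_true(all(diff(c(0, lls)) <= 1e-12))  # adding trials never helps
})

test_that("fits are exhaustive, tie-broken first, and block-additive", {
  dat <- tiny_cohort(family = "drp", n = 1L, tau = 0, order = "dfkl",
                     n_blocks = 20L, seed = 47L)
  fit <- fit_models(dat, blocks = 6:20)
  f <- fit$fits
  # 15 per-block values summing to the total
  llb <- fit$ll_blocks[[1]]
  expect_equal(ncol(llb), 15L)
  for (m in rownames(llb))
    expect_equal(sum(llb[m, ]), f$ll_total[f$model == m], tolerance = 1e-9)
  # a perfect predictor: tau = 0 (first grid point) and total zero
  expect_equal(f$tau[f$model == "drp_dfkl"], 0)
  expect_equal(f$ll_total[f$model == "drp_dfkl"], 0)
  expect_gt(0, f$ll_total[f$model == "fop"])
  expect_identical(summary(fit)$best$model, "drp_dfkl")
})

test_that("Q-learning estimates sit on the alpha/tau ridge and are consistent", {
  # on initial-phase windows the (alpha, tau) likelihood is flattest along
  # the ratio alpha/tau; the ratio is recovered tightly even where the
  # individual coordinates remain noisy
  spec <- cohort_spec(data.frame(family = "q", n = 5L, tau = 0.25,
                                 alpha = 0.5, order = NA),
                      n_blocks = 20L, seed = 53L)
  fit <- fit_models(simulate_cohort(spec),
                    models = list(q = list(family = "q")), blocks = 6:20)
  expect_lte(median(abs(fit$fits$alpha / fit$fits$tau - 2)), 0.4)
  expect_lte(median(abs(fit$fits$alpha - 0.5)), 0.2)
  # the grid MLE is consistent: many blocks pin both coordinates down
  spec_big <- cohort_spec(data.frame(family = "q", n = 1L, tau = 0.25,
                                     alpha = 0.5, order = NA),
                          n_blocks = 100L, seed = 67L)
  fit_big <- fit_models(simulate_cohort(spec_big),
                        models = list(q = list(family = "q")), blocks = 1:100)
  taus <- parameter_grid()$tau
  expect_lte(abs(match(fit_big$fits$tau, taus) - match(0.25, taus)), 2)
  expect_lte(abs(fit_big$fits$alpha - 0.5), 0.05 + 1e-9)
})

test_that("near-uniform responders are fitted at the high-noise grid edge", {
  # a maximally noisy Q-learner responds essentially uniformly
  spec <- cohort_spec(data.frame(family = "q", n = 1L, tau = 1000,
                                 alpha = 0.05, order = NA),
                      n_blocks = 10L, seed = 59L)
  dat <- simulate_cohort(spec)
  fit <- fit_models(dat, models = list(fop = list(family = "fop"),
                                       q = list(family = "q")),
                    blocks = 6:10)
  taus <- parameter_grid()$tau
  n_trials <- sum(vapply(dat$subjects[[1]]$blocks[6:10], function(b) {
    e <- initial_phase_end(b)
    if (is.na(e)) length(b$stimulus) else e
  }, integer(1)))
  for (m in c("fop", "q")) {
    expect_equal(fit$fits$tau[fit$fits$model == m], max(taus))
    expect_equal(fit$fits$ll_total[fit$fits$model == m],
                 n_trials * log(0.25), tolerance = 0.03 * n_trials)
  }
})

test_that("the generating family dominates rival families on average", {
  res <- list()
  for (fam in c("fop", "bp")) {
    dat <- tiny_cohort(family = fam, n = 3L, tau = 1 / 6, n_blocks = 20L,
                       seed = 61L + (fam == "bp"))
    fit <- fit_models(dat, blocks = 6:20)
    own <- fit$fits$ll_total[fit$fits$family == fam]
    rival_q <- fit$fits$ll_total[fit$fits$model == "q"]
    expect_true(mean(own) > mean(rival_q))
    res[[fam]] <- fit
  }
})
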