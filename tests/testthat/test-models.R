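test_that("softmax selection handles noise and the noise-free limit", {
  expect_equal(softmax_select(c(1, 0, 0, 0), 0), c(1, 0, 0, 0))
  expect_equal(softmax_select(rep(0.25, 4), 0), rep(0.25, 4))
  expect_equal(softmax_select(rep(0.25, 4), 2), rep(0.25, 4))
  e <- exp(1)
  expect_equal(softmax_select(c(1, 0, 0, 0), 1),
               c(e, 1, 1, 1) / (e + 3))
  # ties at tau = 0 are uniform over the maximizers
  expect_equal(softmax_select(c(1, 1, 0, 0), 0), c(0.5, 0.5, 0, 0))
  expect_error(softmax_select(c(1, 0, 0, 0), -1), ">= 0")
})

test_that("Q-value updates move the tried pair only, towards +/-1", {
  q <- matrix(0, 4, 4)
  q2 <- q_update(q, 1L, 2L, 1L, 0.5)
  expect_equal(q2[1, 2], 0.5)
  expect_equal(q2[-1, ], q[-1, ])   # other rows untouched
  expect_equal(q2[1, -2], q[1, -2])
  q3 <- matrix(1, 4, 4)
  expect_equal(q_update(q3, 2L, 2L, 1L, 0.7)[2, 2], 1)  # fixed point
  q4 <- matrix(0.5, 4, 4)
  expect_equal(q_update(q4, 3L, 3L, 0L, 0.1)[3, 3], 0.35)
  expect_error(q_update(q, 1L, 1L, 1L, 0), "alpha")
})

test_that("binarization makes the nonzero probabilities uniform", {
  expect_equal(bp_transform(c(0.6, 0, 0.3, 0.1)), c(1/3, 0, 1/3, 1/3))
  expect_equal(bp_transform(c(0, 1, 0, 0)), c(0, 1, 0, 0))
  expect_equal(bp_transform(rep(0.25, 4)), rep(0.25, 4))
  expect_error(bp_transform(rep(0, 4)), "all-zero")
})

test_that("the designated response walks the order, skipping taken responses", {
  params <- model_params("drp", tau = 0, order = "dfkl")
  st <- model_init(params)
  # fresh state: d designated for every stimulus
  for (s in 1:4) expect_equal(model_prefs(st, s), c(1, 0, 0, 0))
  # after S2 confirmed d (trial-2 state of the worked example):
  st2 <- model_update(model_update(st, 1L, 1L, 0L, params), 2L, 1L, 1L, params)
  expect_equal(model_prefs(st2, 3L), c(0, 1, 0, 0))  # next unoccupied: f
  # after trial 4 (S1=f confirmed, S3-k falsified): S3 must be l, S4 k
  st4 <- model_update(model_update(st2, 1L, 2L, 1L, params),
                      3L, 3L, 0L, params)
  expect_equal(model_prefs(st4, 3L), c(0, 0, 0, 1))
  expect_equal(model_prefs(st4, 4L), c(0, 0, 1, 0))
})

test_that("a deviating response updates the pattern state only when rewarded", {
  params <- model_params("drp", tau = 0.5, order = "dfkl")
  st <- model_init(params)
  st <- model_update(st, 2L, 1L, 1L, params)        # S2 = d confirmed
  expect_equal(model_prefs(st, 3L), c(0, 1, 0, 0))  # designated f
  # deviation (k instead of f) with negative feedback: state unchanged
  st_neg <- model_update(st, 3L, 3L, 0L, params)
  expect_identical(st_neg$set$keep, st$set$keep)
  expect_equal(model_prefs(st_neg, 3L), c(0, 1, 0, 0))
  # deviation with positive feedback: k logged in and blocked elsewhere
  st_pos <- model_update(st, 3L, 3L, 1L, params)
  expect_equal(model_prefs(st_pos, 3L), c(0, 0, 1, 0))
  p <- consistency_marginals(st_pos$set)
  expect_equal(p[, 3], c(0, 0, 1, 0))
})

test_that("fresh policies give the expected first-trial distributions", {
  cfg <- task_config()
  fop <- model_step(model_init(model_params("fop", tau = 0)),
                    model_params("fop", tau = 0), 1L)
  expect_equal(fop$probs, rep(0.25, 4))  # every response optimal at start
  drp <- model_step(model_init(model_params("drp", tau = 0, order = "dfkl")),
                    model_params("drp", tau = 0, order = "dfkl"), 2L)
  expect_equal(drp$probs, c(1, 0, 0, 0))
  q <- model_step(model_init(model_params("q", tau = 1, alpha = 0.5)),
                  model_params("q", tau = 1, alpha = 0.5), 3L)
  expect_equal(q$probs, rep(0.25, 4))
  expect_error(model_step(model_init(model_params("fop", tau = 0)),
                          model_params("q", tau = 1, alpha = 0.5), 1L),
               "mismatch")
})

test_that("the noise-free pattern replays the worked example deterministically", {
  params <- model_params("drp", tau = 0, order = "dfkl")
  st <- model_init(params)
  resp <- integer(6)
  for (t in seq_along(fig3_stimuli())) {
    s <- fig3_stimuli()[t]
    pr <- softmax_select(model_prefs(st, s), 0)
    expect_equal(max(pr), 1)  # fully deterministic
    resp[t] <- which.max(pr)
    f <- feedback_for(fig3_mapping(), s, resp[t])
    st <- model_update(st, s, resp[t], f, params)
  }
  expect_equal(resp, fig3_responses())
})

test_that("noise-free patterns make at most six errors per block", {
  set.seed(21)
  perms <- enumerate_mappings(4)
  for (m in 1:24) {
    for (rep in 1:4) {
      ord <- paste(c("d", "f", "k", "l")[perms[sample.int(24, 1), ]],
                   collapse = "")
      b <- simulate_block(model_params("drp", tau = 0, order = ord),
                          perms[m, ])
      expect_lte(sum(b$feedback == 0L), 6L)
    }
  }
})

test_that("noise-free structured policies never repeat a taken response", {
  set.seed(31)
  perms <- enumerate_mappings(4)
  for (family in c("fop", "bp", "drp")) {
    for (rep in 1:10) {
      mapping <- perms[sample.int(24, 1), ]
      b <- simulate_block(model_params(family, tau = 0,
                                       order = if (family == "drp") "dfkl"),
                          mapping)
      # no trial selects a response already confirmed for another stimulus
      for (t in seq_along(b$stimulus)) {
        pre <- seq_len(t - 1L)
        taken <- any(b$stimulus[pre] != b$stimulus[t] &
                       b$response[pre] == b$response[t] &
                       b$feedback[pre] == 1L)
        expect_false(taken)
      }
    }
  }
})
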