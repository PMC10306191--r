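test_that("parameter validation enforces the suppression invariants", {
  expect_s3_class(adaptation_params("exponential", 0.96, 0.7),
                  "adaptation_params")
  expect_error(adaptation_params("exponential", 1.0, 0.7), "\\[0, 1\\)")
  expect_error(adaptation_params("exponential", c(0.9, 0.5), 0.7),
               "exactly one alpha")
  expect_error(adaptation_params("exponential", 0.9, -1), "beta")
  none <- adaptation_params("none", alphas = 0.5, beta = 3)
  expect_identical(none$beta, 0)
  expect_length(none$alphas, 0)

  exp_p <- adaptation_preset("exponential")
  expect_equal(exp_p$alphas, 0.96)
  expect_equal(exp_p$beta, 0.7)
  pow_p <- adaptation_preset("powerlaw")
  expect_equal(pow_p$alphas, c(0.96, 0.75))
  expect_equal(pow_p$beta, 0.15)
  expect_error(adaptation_preset("nope"), "unknown adaptation preset")
})

test_that("exponential state update follows the stated recursion", {
  p <- adaptation_preset("exponential")
  s0 <- adapt_state_init(p, 1L)
  expect_equal(adapt_step(s0, 0, p)[1, 1], 0)
  expect_equal(adapt_step(s0, 1, p)[1, 1], 0.04)
  # geometric decay from s = 1 with zero activation
  s <- matrix(1, 1, 1)
  for (i in 1:10) s <- adapt_step(s, 0, p)
  expect_equal(s[1, 1], 0.96^10, tolerance = 1e-12)
  # pure-update contract: the input state is unmodified
  s_in <- matrix(0.3, 1, 1)
  invisible(adapt_step(s_in, 1, p))
  expect_equal(s_in[1, 1], 0.3)
  expect_error(adapt_step(s0, c(1, 2), p), "units")
})

test_that("power-law channels update independently and sum", {
  p <- adaptation_preset("powerlaw")
  s0 <- adapt_state_init(p, 1L)
  expect_equal(nrow(s0), 2L)
  s1 <- adapt_step(s0, 1, p)
  expect_equal(s1[, 1], c(0.04, 0.25))
  expect_equal(adapt_suppression(s1), 0.29)
  expect_equal(adapt_step(s0, 0, p), s0)
  expect_error(adapt_step(matrix(0, 1, 1), 1, p), "channel")
})

test_that("suppression is subtracted before rectification", {
  p <- adaptation_preset("exponential")
  s0 <- adapt_state_init(p, 1L)
  expect_equal(apply_suppression(1.0, s0, p), 1.0)
  expect_equal(apply_suppression(1.0, matrix(1, 1, 1), p), 0.3)
  expect_equal(apply_suppression(0.5, matrix(1, 1, 1), p), 0)
  expect_error(apply_suppression(NaN, s0, p), "finite")
})

test_that("open-loop recursion matches the geometric closed form", {
  p <- adaptation_params("exponential", 0.87, 0.4)
  a <- c(0.2, 1.4, 0, 0.7, 0.9)
  s <- adapt_state_init(p, 1L)
  for (t in seq_along(a)) s <- adapt_step(s, a[t], p)
  T_ <- length(a)
  closed <- (1 - 0.87) * sum(0.87^(T_ - seq_len(T_)) * a)
  expect_equal(s[1, 1], closed, tolerance = 1e-12)
})

test_that("closed-loop unit trace converges to x/(1+beta) and stays sane", {
  tr <- simulate_unit(rep(1, 400), adaptation_preset("exponential"))
  expect_equal(tail(tr$activation, 1), 1 / 1.7, tolerance = 1e-6)
  expect_true(all(lengths(unclass(tr)) == 400))
  # without adaptation, activation is the rectified drive at every step
  tr0 <- simulate_unit(rep(1, 50), adaptation_params("none"))
  expect_equal(tr0$activation, rep(1, 50))
  expect_equal(tr0$suppression, rep(0, 50))
  # suppression stays non-negative when driven by rectified activity
  set.seed(42)
  trr <- simulate_unit(runif(200, -0.5, 1.5), adaptation_preset("powerlaw"))
  expect_true(all(trr$suppression >= 0))
})

test_that("after stimulus offset suppression decays and activation recovers", {
  drive <- c(rep(1, 100), rep(0.2, 100))
  tr <- simulate_unit(drive, adaptation_preset("exponential"))
  post <- tr$suppression[101:200]
  expect_true(all(diff(post) < 0))            # monotone decay at offset
  act_post <- tr$activation[101:200]
  expect_true(all(diff(act_post) >= 0))       # activation recovers toward drive
  expect_lt(act_post[1], tail(act_post, 1))
})

test_that("single-alpha power-law reproduces exponential exactly", {
  pe <- adaptation_params("exponential", 0.96, 0.7)
  pp <- adaptation_params("powerlaw", 0.96, 0.7)
  set.seed(7)
  drive <- runif(150, 0, 2)
  expect_identical(simulate_unit(drive, pe)$activation,
                   simulate_unit(drive, pp)$activation)
})

test_that("power-law preset suppresses less than exponential over long drives", {
  horizon <- rep(1, 500)
  a_exp <- simulate_unit(horizon, adaptation_preset("exponential"))$activation
  a_pow <- simulate_unit(horizon, adaptation_preset("powerlaw"))$activation
  # terminal activation loss (1 - a) strictly smaller under power-law
  expect_lt(1 - tail(a_pow, 1), 1 - tail(a_exp, 1))
})

test_that("beta = 0 is indistinguishable from no adaptation", {
  p0 <- adaptation_params("exponential", 0.96, 0)
  set.seed(11)
  drive <- rnorm(100)
  expect_identical(simulate_unit(drive, p0)$activation,
                   simulate_unit(drive, adaptation_params("none"))$activation)
})
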