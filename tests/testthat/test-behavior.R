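test_that("noiseless exponential series is recovered essentially exactly", {
  N <- 1:500
  mt <- 1.0 + 2.0 * exp(-0.01 * N)
  fit <- fit_exponential(mt)
  expect_equal(unname(coef(fit)), c(1.0, 2.0, 0.01), tolerance = 1e-6)
  expect_lt(fit$residual_sse, 1e-12)
  expect_false(fit$unidentifiable)
  # truths off the multi-start grid are found by the refinement
  mt <- 0.6 + 1.3 * exp(-0.023 * N)
  expect_equal(unname(coef(fit_exponential(mt))), c(0.6, 1.3, 0.0023 * 10),
               tolerance = 1e-5)
})

test_that("degenerate series are flagged, short series are errors", {
  fit <- fit_exponential(rep(1.5, 100))
  expect_equal(unname(coef(fit)["A"]), 1.5)
  expect_equal(unname(coef(fit)["B"]), 0)
  expect_true(fit$unidentifiable)
  expect_error(fit_exponential(c(1, 2)), "insufficient")
  expect_error(fit_exponential(c(1, -2, 3)), "positive")
})

test_that("noisy recovery: median alpha error within 10 percent", {
  # seeded Monte-Carlo: truth A=1, B=2, alpha=0.01, noise sd = 0.1 B
  set.seed(601)
  N <- 1:1000
  mu <- 1 + 2 * exp(-0.01 * N)
  alphas <- replicate(100, {
    mt <- pmax(mu + rnorm(length(N), 0, 0.2), 1e-3)
    coef(fit_exponential(mt))["alpha"]
  })
  expect_lt(abs(median(alphas) - 0.01) / 0.01, 0.10)
})

test_that("successful-trial filtering and explicit indexing behave", {
  set.seed(602)
  tr <- make_trials(behavior_spec(noise_sd = 0, success_rate = 0.8, seed = 3))
  fit_all <- fit_exponential(tr, use_successful_only = FALSE)
  expect_equal(fit_all$n_trials, nrow(tr))
  fit_s <- fit_exponential(tr, use_successful_only = TRUE)
  expect_equal(fit_s$n_trials, sum(tr$success))
  # noiseless closed loop still recovers A exactly; B, alpha are rescaled by
  # the successful-trial renumbering convention
  expect_equal(unname(coef(fit_all)), c(1, 2, 0.01), tolerance = 1e-6)
})

test_that("time-shift identity: N -> N + k rescales B by exp(alpha k)", {
  N <- 1:400
  mt <- 0.8 + 1.5 * exp(-0.02 * N)
  f0 <- fit_exponential(mt, N = N)
  fk <- fit_exponential(mt, N = N + 25)
  expect_equal(coef(fk)["A"], f0$coefficients["A"], tolerance = 1e-5)
  expect_equal(coef(fk)["alpha"], f0$coefficients["alpha"], tolerance = 1e-4)
  expect_equal(unname(coef(fk)["B"]),
               unname(coef(f0)["B"] * exp(coef(f0)["alpha"] * 25)),
               tolerance = 1e-4)
})

test_that("refitting from the fitted curve reproduces the parameters", {
  set.seed(603)
  N <- 1:800
  mt <- pmax(1 + 2 * exp(-0.01 * N) + rnorm(800, 0, 0.1), 1e-3)
  f1 <- fit_exponential(mt)
  f2 <- fit_exponential(fitted(f1))     # noiseless image of the model
  expect_equal(coef(f2), coef(f1), tolerance = 1e-4)
})

test_that("improving series yield positive B", {
  set.seed(604)
  for (i in 1:5) {
    N <- 1:600
    mu <- runif(1, 0.5, 1.5) + runif(1, 0.5, 3) * exp(-runif(1, 0.003, 0.05) * N)
    mt <- pmax(mu + rnorm(600, 0, 0.15), 1e-3)
    expect_gt(coef(fit_exponential(mt))["B"], 0)
  }
})

test_that("bin_fit splits sessions 1-9 and 10 with renumbered trials", {
  # piecewise dynamics: late sessions decay faster
  spec <- behavior_spec(noise_sd = 0.05, seed = 5)
  tr <- make_trials(spec)
  late <- tr$session == 10
  n_late <- sum(late)
  tr$movement_time[late] <-
    pmax(1 + 1.0 * exp(-0.05 * seq_len(n_late)) +
           rnorm(n_late, 0, 0.05), 1e-3)
  res <- bin_fit(tr)
  expect_s3_class(res$early, "learning_curve")
  expect_s3_class(res$late, "learning_curve")
  expect_gt(coef(res$late)["alpha"], coef(res$early)["alpha"])
  # no session-10 trials: late slot carries the error, early still fits
  res2 <- bin_fit(tr[tr$session < 10, ])
  expect_s3_class(res2$early, "learning_curve")
  expect_s3_class(res2$late, "error")
  # identical dynamics across bins fit cleanly in both slots
  tr3 <- make_trials(behavior_spec(alpha = 0.002, noise_sd = 0.02, seed = 8))
  res3 <- bin_fit(tr3)
  expect_s3_class(res3$early, "learning_curve")
  expect_s3_class(res3$late, "learning_curve")
})

test_that("learning_curve methods are coherent", {
  N <- 1:300
  mt <- 1 + 2 * exp(-0.01 * N)
  fit <- fit_exponential(mt)
  expect_equal(predict(fit, newdata = c(1, 10)),
               1 + 2 * exp(-0.01 * c(1, 10)), tolerance = 1e-5)
  expect_equal(fitted(fit) + residuals(fit), mt)
  expect_output(print(fit), "alpha")
  expect_output(print(summary(fit)), "plateau")
  sim <- simulate(fit, nsim = 2, seed = 1)
  expect_equal(dim(sim), c(300L, 2L))
})

test_that("trial logs round-trip through CSV", {
  tr <- make_trials(behavior_spec(n_sessions = 2, blocks_per_session = 2,
                                  movements_per_block = 10, seed = 2))
  path <- file.path(tempdir(), "trials.csv")
  write_trials(tr, path)
  back <- read_trials(path)
  expect_equal(back$movement_time, tr$movement_time)
  expect_equal(back$success, tr$success)
  expect_named(back, c("session", "block", "trial", "movement_time", "success"))
})
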