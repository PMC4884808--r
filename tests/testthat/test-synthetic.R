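test_that("phantom spec validates pool fractions and is deterministic", {
  expect_error(phantom_spec(classes = list(bad = data.frame(
    t2 = c(20, 80), fraction = c(0.5, 0.4)))), "sum to 1")
  p1 <- make_phantom(phantom_spec(block_shape = c(3, 3, 2), seed = 42))
  p2 <- make_phantom(phantom_spec(block_shape = c(3, 3, 2), seed = 42))
  expect_identical(p1$volume$data, p2$volume$data)
  p3 <- make_phantom(phantom_spec(block_shape = c(3, 3, 2), seed = 43))
  expect_false(identical(p1$volume$data, p3$volume$data))
})

test_that("generators do not disturb the caller's RNG stream", {
  set.seed(99)
  a <- rnorm(1)
  set.seed(99)
  invisible(make_phantom(phantom_spec(block_shape = c(2, 2, 1), seed = 1)))
  invisible(make_trials(behavior_spec(n_sessions = 1, blocks_per_session = 1,
                                      movements_per_block = 5, seed = 1)))
  expect_identical(rnorm(1), a)
})

test_that("noiseless single-pool phantom is a pure exponential", {
  spec <- phantom_spec(classes = list(ie = data.frame(t2 = 80, fraction = 1)),
                       block_shape = c(2, 2, 2), flip_range = 180, snr = Inf)
  ph <- make_phantom(spec)
  te <- ph$volume$echo_times
  ref <- exp(-te / 80)
  for (x in 1:2) for (y in 1:2) for (z in 1:2)
    expect_equal(ph$volume$data[x, y, z, ], ref, tolerance = 1e-12)
  # truth MWF is zero everywhere for a pure 80 ms pool
  expect_true(all(ph$truth$mwf == 0))
})

test_that("default white-matter class carries true MWF 0.12", {
  ph <- make_phantom(phantom_spec(block_shape = c(2, 2, 1), snr = Inf))
  expect_true(all(ph$truth$mwf[ph$truth$label == 1] == 0.12))
  expect_true(all(ph$truth$mwf[ph$truth$label == 3] == 0))   # CSF
  # flip field spans the requested ramp
  expect_equal(range(ph$truth$flip_angle, na.rm = TRUE), c(140, 180))
})

test_that("phantom noise level follows the requested SNR", {
  spec0 <- phantom_spec(block_shape = c(6, 6, 3), snr = Inf)
  spec1 <- phantom_spec(block_shape = c(6, 6, 3), snr = 100,
                        noise_model = "gaussian", seed = 11)
  clean <- make_phantom(spec0)$volume$data
  noisy <- make_phantom(spec1)$volume$data
  resid <- (noisy - clean)[clean > 0.2]      # clamping-free region
  first <- clean[, , , 1]
  sigma_expected <- mean(first[first > 0]) / 100
  expect_equal(sd(resid), sigma_expected, tolerance = 0.05)
})

test_that("trial generator follows the training schedule exactly", {
  tr <- make_trials(behavior_spec())
  expect_equal(nrow(tr), 10000)              # 10 sessions x 5 blocks x 200
  expect_equal(unname(table(tr$session)), rep(1000L, 10),
               ignore_attr = TRUE)
  expect_equal(max(tr$block), 5)
  expect_true(all(diff(tr$trial) == 1))
  expect_true(all(tr$movement_time > 0))
})

test_that("noiseless trials close the loop with the curve fitter", {
  tr <- make_trials(behavior_spec(A = 1.2, B = 1.8, alpha = 0.004,
                                  noise_sd = 0, seed = 21))
  fit <- fit_exponential(tr, use_successful_only = FALSE)
  expect_equal(unname(coef(fit)), c(1.2, 1.8, 0.004), tolerance = 1e-6)
})

test_that("empirical success rate sits inside its binomial interval", {
  spec <- behavior_spec(success_rate = 0.813, seed = 31)
  tr <- make_trials(spec)
  n <- nrow(tr)
  phat <- mean(tr$success)
  half <- 1.96 * sqrt(0.813 * (1 - 0.813) / n)
  expect_gt(phat, 0.813 - half)
  expect_lt(phat, 0.813 + half)
})

test_that("cohort generator hits its marginal and joint targets", {
  # sigma = 0 pins every subject's change at mu
  coh0 <- make_cohort(8, rois = list(ips = c(mu = 5, sigma = 0)), seed = 1)
  expect_true(all(coh0$ips_pct_change == 5))
  expect_equal(percent_change(coh0$ips_pre, coh0$ips_post),
               coh0$ips_pct_change, tolerance = 1e-10)
  expect_error(make_cohort(8, true_r = 1), "true_r")
  # across replicates the mean one-sample t matches the analytic
  # noncentrality mu / (sigma / sqrt(n))
  ts <- vapply(1:200, function(s) {
    coh <- make_cohort(16, rois = list(ips = c(mu = 8.30, sigma = 13.90)),
                       seed = s)
    one_sample_t(coh$ips_pct_change)$t
  }, numeric(1))
  expect_equal(mean(ts), 8.30 / (13.90 / 4), tolerance = 0.15)
  # requested correlation is recovered in large samples
  coh <- make_cohort(4000, true_r = -0.6, seed = 77)
  expect_equal(cor(coh$ips_pct_change, coh$alpha), -0.6, tolerance = 0.05)
})

test_that("null cohorts give uniform p-values (KS check)", {
  ps <- vapply(1:300, function(s) {
    coh <- make_cohort(16, rois = list(ips = c(mu = 0, sigma = 10)),
                       true_r = 0, seed = 1000 + s)
    pearson(coh$ips_pct_change, coh$alpha)$p
  }, numeric(1))
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("phantom writes a NIfTI volume with a JSON truth sidecar", {
  ph <- make_phantom(phantom_spec(block_shape = c(2, 2, 1), seed = 3))
  prefix <- file.path(tempdir(), "ph_")
  paths <- write_phantom(ph, prefix)
  expect_true(all(file.exists(paths)))
  truth <- jsonlite::read_json(paths["truth"], simplifyVector = TRUE)
  expect_equal(truth$dim, dim(ph$truth$label))
  expect_equal(array(truth$mwf, truth$dim), ph$truth$mwf)
  vol <- read_multiecho_nifti(paths["volume"], truth$echo_times)
  expect_equal(vol$data, ph$volume$data, tolerance = 1e-6, ignore_attr = TRUE)
})
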