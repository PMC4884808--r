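test_that("partition implements the MWF definition and band conventions", {
  g <- c(15, 20, 40, 80, 200, 1500, 2000)
  # all amplitude in the short band
  expect_equal(unname(partition(t2_spectrum(g, c(0, 1, 0, 0, 0, 0, 0)))["short"]), 1)
  # 0.2 at 20 ms, 0.8 at 80 ms
  p <- partition(t2_spectrum(g, c(0, 0.2, 0, 0.8, 0, 0, 0)))
  expect_equal(unname(p["short"]), 0.2)
  expect_equal(unname(p["intermediate"]), 0.8)
  # boundary membership: 40 ms is short, 200 ms intermediate, 1500 ms long
  p <- partition(t2_spectrum(g, c(0, 0, 1, 0, 1, 1, 1)))
  expect_equal(unname(p["short"]), 0.25)
  expect_equal(unname(p["intermediate"]), 0.25)
  expect_equal(unname(p["long"]), 0.5)
  expect_equal(sum(p), 1)
  # zero spectrum: all fractions zero
  expect_equal(unname(partition(t2_spectrum(g, numeric(7)))), rep(0, 4))
  expect_error(partition_bounds(short_lo = 50, short_hi = 40))
})

test_that("MWF is invariant to overall signal scale", {
  sq <- seq_params()
  cfg <- mwf_config()
  set.seed(401)
  y <- add_rician(three_pool_signal(0.15, 155, sq), 0.002)
  f1 <- fit_voxel(y, sq, cfg, bases = default_bases())
  for (c in c(1e-3, 0.5, 7, 1e4)) {
    f2 <- fit_voxel(c * y, sq, cfg, bases = default_bases())
    expect_equal(f2$mwf, f1$mwf, tolerance = 1e-10)
  }
})

test_that("flip-angle estimation recovers the simulated angle", {
  sq <- seq_params()
  g <- t2_grid()
  # noiseless at 180: within 1 degree
  y <- three_pool_signal(0.12, 180, sq)
  expect_lt(abs(estimate_flip_angle(y, g, sq, bases = default_bases()) - 180), 1)
  # noiseless at an off-grid angle
  y <- three_pool_signal(0.12, 147.5, sq)
  expect_lt(abs(estimate_flip_angle(y, g, sq, bases = default_bases()) - 147.5), 1)
  # SNR 200 at 140 degrees: median of 50 seeded draws within 3 degrees
  set.seed(402)
  s0 <- three_pool_signal(0.12, 140, sq)
  est <- replicate(50, {
    y <- add_rician(s0, s0[1] / 200)
    estimate_flip_angle(y, g, sq, bases = default_bases())
  })
  expect_lt(abs(median(est) - 140), 3)
  expect_error(estimate_flip_angle(y, g, sq, candidate_angles = 90), "two")
  expect_error(estimate_flip_angle(y, g, sq, candidate_angles = c(0, 90)))
})

test_that("tied candidate misfits resolve to the smaller angle", {
  # a synthetic two-candidate situation with identical bases gives identical
  # misfits; the first (smaller) angle must win before refinement
  sq <- seq_params(n_echoes = 4)
  g <- c(20, 80, 2000)
  y <- epg_decay(80, 180, sq)$amplitudes
  B <- decay_basis(g, 180, sq)
  got <- estimate_flip_angle(y, g, sq, candidate_angles = c(120, 170),
                             bases = list(B, B))
  expect_equal(got, 120)
})

test_that("fit_voxel recovers pool structure on noiseless voxels", {
  sq <- seq_params()
  cfg <- mwf_config()
  # single pool at 80 ms: no short-T2 content
  f <- fit_voxel(epg_decay(80, 180, sq)$amplitudes, sq, cfg,
                 bases = default_bases())
  expect_lt(abs(f$mwf), 0.02)
  expect_true(f$valid)
  # three pools 0.12/0.83/0.05 at 160 degrees
  f <- fit_voxel(three_pool_signal(0.12, 160, sq), sq, cfg,
                 bases = default_bases())
  expect_lt(abs(f$mwf - 0.12), 0.02)
  expect_lt(abs(f$flip_angle - 160), 2)
  expect_equal(unname(sum(f$fractions)), 1, tolerance = 1e-10)
  # all-zero signal: invalid, MWF missing (not zero)
  f0 <- fit_voxel(numeric(32), sq, cfg)
  expect_false(f0$valid)
  expect_true(is.na(f0$mwf))
  expect_error(fit_voxel(numeric(8), sq, cfg), "samples")
})

test_that("noise floor flags weak voxels invalid", {
  sq <- seq_params()
  cfg <- mwf_config(noise_floor = 0.05)
  f <- fit_voxel(rep(0.01, 32), sq, cfg)
  expect_false(f$valid)
  expect_true(is.na(f$mwf))
})

test_that("voxel_fit methods are coherent", {
  sq <- seq_params()
  f <- fit_voxel(three_pool_signal(0.12, 165, sq), sq, mwf_config(),
                 bases = default_bases())
  expect_s3_class(f, "voxel_fit")
  expect_named(coef(f)[1:2], c("mwf", "flip_angle"))
  expect_equal(residuals(f), f$signal - fitted(f))
  expect_output(print(f), "MWF")
})

test_that("config round-trips through JSON and YAML", {
  cfg <- mwf_config(grid_n = 24, chi2_factor = 1.05,
                    angles = seq(90, 180, by = 5), noise_floor = 0.01)
  js <- file.path(tempdir(), "cfg.json")
  jsonlite::write_json(list(grid_n = 24, chi2_factor = 1.05,
                            angles = seq(90, 180, by = 5),
                            noise_floor = 0.01), js, auto_unbox = TRUE)
  got <- read_mwf_config(js)
  expect_equal(got$grid, cfg$grid)
  expect_equal(got$chi2_factor, 1.05)
  ym <- file.path(tempdir(), "cfg.yaml")
  writeLines(yaml::as.yaml(list(grid_n = 24, chi2_factor = 1.05)), ym)
  expect_equal(read_mwf_config(ym)$chi2_factor, 1.05)
})
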