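test_that("scattered fields superpose linearly and carry the model cross-section", {
  cfg <- test_config()
  px <- sample_pixel(cfg)
  b1 <- bead_spec(203, 1.43, row = 40, col = 40)
  b2 <- bead_spec(300, 1.45, row = 90, col = 80)
  f1 <- scattered_field(b1, cfg, "fs")
  f2 <- scattered_field(b2, cfg, "fs")
  scene <- sim_scene(list(b1, b2), visibility = c(fs = 0.25, bs = 0))

  # integrated squared SA equals the forward-model cross-section
  fm <- forward_model(1.43, 203, cfg)
  expect_equal(sum(Mod(f1$values)^2) * px^2, fm$sigma_fs, tolerance = 1e-10)

  # the rendered frame's carrier lobe is linear in the bead fields
  cam <- camera_model()
  fr12 <- render_hologram(scene, cfg, cam, poisson = FALSE, quantize = FALSE)
  frb <- render_hologram(sim_scene(list(), visibility = c(fs = 0.25, bs = 0)),
                         cfg, cam, poisson = FALSE, quantize = FALSE)
  rec <- demultiplex(fr12, cfg, "fs")$values - demultiplex(frb, cfg, "fs")$values
  expect_gt(field_correlation(rec, f1$values + f2$values), 0.999)
})

test_that("a 20-nm bead scatters equally into the two channels", {
  cfg <- test_config()
  b <- bead_spec(20, 1.43, row = 64, col = 64)
  f_fs <- scattered_field(b, cfg, "fs")
  f_bs <- scattered_field(b, cfg, "bs")
  r <- sum(Mod(f_fs$values)^2) / sum(Mod(f_bs$values)^2)
  expect_equal(r, 1, tolerance = 0.02)
})

test_that("focused PSF peak matches the pupil-integral closed form", {
  # Parseval: sum |psf|^2 = N_pupil / N^2 and the focused peak is
  # N_pupil / N^2, so peak SA = sqrt(sigma * N_pupil) / (N * px)
  cfg <- test_config()
  px <- sample_pixel(cfg)
  n <- prod(cfg$sensor_shape)
  f_na <- cfg$collection_na / cfg$wavelength
  g <- holoscat:::freq_grid(cfg$sensor_shape)
  n_pupil <- sum((g$fr / px)^2 + (g$fc / px)^2 <= f_na^2)
  b <- bead_spec(203, 1.43, row = 65, col = 65)  # on-pixel centre
  f <- scattered_field(b, cfg, "fs")
  sigma <- forward_model(1.43, 203, cfg)$sigma_fs
  peak_expected <- sqrt(sigma * n_pupil) / (sqrt(n) * px)
  expect_equal(max(Mod(f$values)), peak_expected, tolerance = 0.01)
})

test_that("defocus beyond the validity bound is rejected", {
  cfg <- test_config()
  b <- bead_spec(203, 1.43, row = 64, col = 64, z = 500)
  expect_error(scattered_field(b, cfg, "fs"), "validity")
})

test_that("rendering is deterministic and Poisson statistics are correct", {
  cfg <- test_config(c(64L, 64L))
  cam <- camera_model()
  scene <- sim_scene(list(), seed = 9)
  f1 <- render_hologram(scene, cfg, cam, frame_index = 5)
  f2 <- render_hologram(scene, cfg, cam, frame_index = 5)
  expect_identical(f1$dn, f2$dn)
  f3 <- render_hologram(scene, cfg, cam, frame_index = 6)
  expect_false(identical(f1$dn, f3$dn))

  # per-pixel variance ~= mean (in electrons) across a no-sample stack
  frames <- lapply(1:300, function(i) {
    render_hologram(scene, cfg, cam, frame_index = i, quantize = FALSE)
  })
  gain <- camera_gain(cam)
  arr <- simplify2array(lapply(frames, function(f) f$dn * gain))
  vr <- apply(arr, c(1, 2), var)
  mn <- apply(arr, c(1, 2), mean)
  expect_equal(mean(vr) / mean(mn), 1, tolerance = 0.05)
})

test_that("a flat no-fringe scene renders spatially constant expected electrons", {
  cfg <- test_config(c(64L, 64L))
  scene <- sim_scene(list(), visibility = c(fs = 0, bs = 0))
  fr <- render_hologram(scene, cfg, camera_model(), poisson = FALSE,
                        quantize = FALSE)
  expect_lt(diff(range(fr$dn)), 1e-9 * mean(fr$dn))
})

test_that("doubling the illumination doubles the expected electrons", {
  cfg <- test_config(c(64L, 64L))
  s1 <- sim_scene(list(), illumination_scale = c(fs = 1e4, bs = 1e4 / 0.07^2))
  s2 <- sim_scene(list(), illumination_scale = c(fs = 2e4, bs = 2e4 / 0.07^2))
  f1 <- render_hologram(s1, cfg, camera_model(), poisson = FALSE,
                        quantize = FALSE)
  f2 <- render_hologram(s2, cfg, camera_model(), poisson = FALSE,
                        quantize = FALSE)
  expect_equal(f2$dn, 2 * f1$dn, tolerance = 1e-12)
})

test_that("saturating scenes warn and clip", {
  cfg <- test_config(c(64L, 64L))
  scene <- sim_scene(list(), illumination_scale = c(fs = 9e4, bs = 9e4 / 0.07^2))
  expect_warning(
    fr <- render_hologram(scene, cfg, camera_model(), poisson = FALSE),
    "saturation")
  expect_true(all(fr$dn <= 4095))
})

test_that("visibility estimates round-trip through the renderer", {
  cfg <- test_config()
  cam <- camera_model()
  # single carrier
  s1 <- sim_scene(list(), visibility = c(fs = 0.5, bs = 0), seed = 2)
  f1 <- render_hologram(s1, cfg, cam, poisson = FALSE, quantize = FALSE)
  expect_equal(estimate_visibility(f1, cfg, "fs"), 0.5, tolerance = 0.01)
  # dual carrier, distinct visibilities
  s2 <- sim_scene(list(), visibility = c(fs = 0.3, bs = 0.6), seed = 2)
  f2 <- render_hologram(s2, cfg, cam, poisson = FALSE, quantize = FALSE)
  nu <- estimate_visibility(f2, cfg)
  expect_equal(unname(nu[["fs"]]), 0.3, tolerance = 0.02 * 0.3)
  expect_equal(unname(nu[["bs"]]), 0.6, tolerance = 0.02 * 0.6)
})

test_that("time series carry correct time stamps and ground truth", {
  cfg <- test_config(c(64L, 64L))
  scene <- sim_scene(list(bead_spec(203, 1.43, row = 32, col = 32)), seed = 4)
  ts <- simulate_timeseries(scene, cfg, camera_model(), n_frames = 50,
                            poisson = FALSE)
  expect_length(ts$frames, 50)
  # 500 fps: n frames span n / fps seconds
  span <- max(ts$truth$time_s) - min(ts$truth$time_s) + 1 / cfg$frame_rate
  expect_equal(span, 50 / 500)
  expect_equal(unique(ts$truth$diameter), 203)
})

test_that("flowing beads vacate the field of view outside the passage window", {
  cfg <- test_config(c(64L, 64L))
  scene <- sim_scene(list(bead_spec(300, 1.45, row = 32, col = 32)), seed = 4)
  expect_message(
    ts <- simulate_timeseries(scene, cfg, camera_model(), n_frames = 300,
                              motion = motion_flow(velocity = c(0, 1.5),
                                                   t0 = 150),
                              poisson = FALSE),
    "outside the FOV")
  tr <- ts$truth
  inside <- !is.na(tr$col)
  expect_true(all(abs(tr$frame[inside] - 150) <= 100))
  expect_true(any(inside))
})

test_that("Brownian trajectories recover their diffusion coefficient from the MSD", {
  b <- bead_spec(203, 1.43, row = 500, col = 500)
  D <- 0.5   # px^2 / frame
  tr <- holoscat:::build_trajectory(b, motion_brownian(D), 5000,
                                    c(1000L, 1000L), seed = 42)
  lags <- 1:20
  msd <- vapply(lags, function(lag) {
    mean((tr$row[(1 + lag):5000] - tr$row[1:(5000 - lag)])^2 +
         (tr$col[(1 + lag):5000] - tr$col[1:(5000 - lag)])^2)
  }, numeric(1))
  slope <- stats::coef(stats::lm(msd ~ lags))[["lags"]]
  expect_equal(slope, 4 * D, tolerance = 0.10)
})

test_that("noise-free reconstruction recovers the injected complex field", {
  cfg <- test_config()
  b <- bead_spec(250, 1.45, row = 60.5, col = 70.25)
  pair <- render_pair(list(b), cfg)
  rec <- demultiplex(pair$sample, cfg, "fs")$values -
    demultiplex(pair$background, cfg, "fs")$values
  inj <- scattered_field(b, cfg, "fs")$values
  expect_gt(field_correlation(rec, inj), 0.999)
})
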