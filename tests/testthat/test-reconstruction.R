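test_that("demultiplexing a constant frame yields null fields", {
  cfg <- test_config(c(64L, 64L))
  frame <- hologram_frame(matrix(1000, 64, 64))
  expect_warning(fs <- demultiplex(frame, cfg, "fs"), "carrier lobe")
  expect_warning(bs <- demultiplex(frame, cfg, "bs"), "carrier lobe")
  expect_lt(max(Mod(fs$values)), 1e-9 * 1000)
  expect_lt(max(Mod(bs$values)), 1e-9 * 1000)
})

test_that("demultiplexing recovers an injected object field up to a constant factor", {
  cfg <- test_config()
  b <- bead_spec(300, 1.45, row = 50, col = 80, z = 1)
  pair <- render_pair(list(b), cfg)
  for (ch in c("fs", "bs")) {
    rec <- demultiplex(pair$sample, cfg, ch)$values -
      demultiplex(pair$background, cfg, ch)$values
    inj <- scattered_field(b, cfg, ch)$values
    expect_gt(field_correlation(rec, inj), 0.999)
  }
})

test_that("demultiplex is linear in the hologram AC content", {
  cfg <- test_config()
  b1 <- bead_spec(203, 1.43, row = 40, col = 40)
  b2 <- bead_spec(300, 1.45, row = 90, col = 85)
  p1 <- render_pair(list(b1), cfg)
  p2 <- render_pair(list(b2), cfg)
  p12 <- render_pair(list(b1, b2), cfg)
  d <- function(pair) demultiplex(pair$sample, cfg, "fs")$values -
    demultiplex(pair$background, cfg, "fs")$values
  expect_gt(field_correlation(d(p12), d(p1) + d(p2)), 0.9999)
})

test_that("the spatial-frequency aperture retains the documented pixel count", {
  expect_identical(aperture_pixel_count(115), 41548)
  # the lattice mask agrees with the analytic area to O(1/radius)
  mask <- holoscat:::disc_mask(c(1024L, 1024L), c(0, 0), 115)
  expect_equal(sum(mask), 41548, tolerance = 0.005)
})

test_that("angular-spectrum propagation is unitary and invertible", {
  cfg <- test_config()
  b <- bead_spec(300, 1.45, row = 64, col = 64)
  f <- demultiplex(render_pair(list(b), cfg)$sample, cfg, "fs")  # band-limited
  expect_identical(propagate(f, 0)$values, f$values)
  back <- propagate(propagate(f, 3), -3)
  expect_lt(max(Mod(back$values - f$values)) / max(Mod(f$values)), 1e-10)
  e0 <- sum(Mod(f$values)^2)
  expect_equal(sum(Mod(propagate(f, 5)$values)^2), e0, tolerance = 1e-10)
  expect_error(propagate(f, 1e5), "validity")
})

test_that("a propagated Gaussian beam follows the analytic waist evolution", {
  px <- 0.05
  n_med <- 1.33
  lam <- 0.515
  w0 <- 1.0
  xy <- ((1:256) - 128.5) * px
  r2 <- outer(xy^2, rep(1, 256)) + t(outer(xy^2, rep(1, 256)))
  f <- complex_field(exp(-r2 / w0^2) + 0i, "fs", px, lam, n_med)
  zr <- pi * w0^2 * n_med / lam
  for (z in c(2, 5)) {
    I <- Mod(propagate(f, z)$values)^2
    # intensity exp(-2 r^2 / w^2): fit w from the log-intensity slope
    sel <- I > max(I) * 1e-3
    slope <- stats::coef(stats::lm(log(I[sel]) ~ r2[sel]))[[2]]
    w_num <- sqrt(-2 / slope)
    w_true <- w0 * sqrt(1 + (z / zr)^2)
    expect_equal(w_num, w_true, tolerance = 0.01)
  }
})

test_that("autofocus recovers the defocus of a simulated bead", {
  cfg <- test_config()
  b <- bead_spec(300, 1.45, row = 64, col = 64, z = 2)
  pair <- render_pair(list(b), cfg)
  e <- demultiplex(pair$sample, cfg, "fs")
  eb <- demultiplex(pair$background, cfg, "fs")
  z <- autofocus(e, eb, z_range = c(-5, 5), z_step = 0.5)
  expect_lte(abs(as.numeric(z) - (-2)), 0.5)  # refocus cancels the +2 defocus

  # an in-focus bead needs no refocus
  b0 <- bead_spec(300, 1.45, row = 64, col = 64, z = 0)
  pair0 <- render_pair(list(b0), cfg)
  z0 <- autofocus(demultiplex(pair0$sample, cfg, "fs"), eb,
                  z_range = c(-5, 5), z_step = 0.5)
  expect_lte(abs(as.numeric(z0)), 0.5)

  # the metric decays monotonically through the depth of field and the
  # focal plane dominates the whole scan
  inj <- scattered_field(b0, cfg, "fs")
  zs <- seq(0, 5, by = 1)
  m <- vapply(zs, function(z) {
    holoscat:::focus_metric(propagate(inj, z)$values, "kurtosis")
  }, numeric(1))
  expect_true(all(diff(m[1:4]) < 0))
  expect_true(all(m[1] > m[-1]))

  # flat field: warning and z = 0
  flat <- demultiplex(pair$background, cfg, "fs")
  expect_warning(zf <- autofocus(flat, flat, z_range = c(-2, 2), z_step = 0.5),
                 "flat")
  expect_equal(as.numeric(zf), 0)
})

test_that("phase-drift fitting removes offset and ramp exactly and under noise", {
  cfg <- test_config()
  shape <- c(128L, 128L)
  mask <- matrix(TRUE, shape[1], shape[2])
  rows <- matrix(0:(shape[1] - 1), shape[1], shape[2])
  cols <- matrix(0:(shape[2] - 1), shape[1], shape[2], byrow = TRUE)

  flat <- holoscat:::field_from_config(matrix(1 + 0i, shape[1], shape[2]),
                                       "fs", cfg)
  out0 <- correct_phase_drift(flat, mask)
  expect_equal(unname(attr(out0, "drift_coef")), c(0, 0, 0))
  expect_equal(out0$values, flat$values)

  truth <- c(0.2, 0.004, -0.002)
  drifted <- flat
  drifted$values <- exp(1i * (truth[1] + truth[2] * rows + truth[3] * cols))
  out <- correct_phase_drift(drifted, mask)
  expect_equal(unname(attr(out, "drift_coef")), truth, tolerance = 1e-12)
  expect_lt(max(Mod(out$values - 1)), 1e-12)

  # Gaussian phase noise: recovery within 3 standard errors (lm oracle)
  set.seed(10)
  noisy <- drifted
  phi_noise <- matrix(rnorm(prod(shape), 0, 0.05), shape[1], shape[2])
  noisy$values <- drifted$values * exp(1i * phi_noise)
  out_n <- correct_phase_drift(noisy, mask)
  fit <- stats::lm(as.numeric(Arg(noisy$values)) ~ as.numeric(rows) +
                     as.numeric(cols))
  se <- summary(fit)$coefficients[, "Std. Error"]
  expect_true(all(abs(attr(out_n, "drift_coef") - truth) < 3 * se))

  # degenerate masks are rejected
  tiny <- matrix(FALSE, shape[1], shape[2]); tiny[1:5, 1] <- TRUE
  expect_error(correct_phase_drift(drifted, tiny), "mask")
  line <- matrix(FALSE, shape[1], shape[2]); line[, 10] <- TRUE
  expect_error(correct_phase_drift(drifted, line, min_coverage = 0.005),
               "collinear")
})

test_that("SA obeys its defining identities and bounds", {
  cfg <- test_config(c(32L, 32L))
  mk <- function(vals) holoscat:::field_from_config(vals, "fs", cfg)
  bg <- mk(matrix(2 + 1i, 32, 32))

  expect_equal(compute_sa(bg, bg, alpha = 1)$values, matrix(0, 32, 32))

  neg <- mk(-bg$values)
  expect_equal(compute_sa(neg, bg, alpha = 1)$values, matrix(2, 32, 32))

  # alpha scales the unit-contrast ratio: |E_s| = |E_bg| gives SA = alpha
  zero <- mk(matrix(0i, 32, 32))
  expect_equal(compute_sa(zero, bg, alpha = 0.07)$values,
               matrix(0.07, 32, 32))

  # invariance under a global complex scale of both fields
  s <- mk(bg$values + 0.1i)
  sa1 <- compute_sa(s, bg, alpha = 1)$values
  cscale <- 3 * exp(1i * 0.8)
  sa2 <- compute_sa(mk(s$values * cscale), mk(bg$values * cscale),
                    alpha = 1)$values
  expect_equal(sa1, sa2, tolerance = 1e-12)

  # alpha misconfiguration is reported, not hidden
  expect_warning(compute_sa(neg, bg, alpha = 1.5), "alpha")

  # vanishing background pixels are flagged invalid
  bg2 <- bg; bg2$values[5, 5] <- 0
  sa <- compute_sa(s, bg2, alpha = 1)
  expect_true(is.na(sa$values[5, 5]))
  expect_equal(sa$provenance$n_invalid, 1)
})

test_that("end-to-end SA integrates to the forward-model cross-section", {
  cfg <- test_config()
  px <- sample_pixel(cfg)
  b <- bead_spec(203, 1.43, row = 64, col = 64)
  pair <- render_pair(list(b), cfg)
  for (ch in c("fs", "bs")) {
    e <- demultiplex(pair$sample, cfg, ch)
    eb <- demultiplex(pair$background, cfg, ch)
    sa <- compute_sa(e, eb, alpha = channel_alpha(cfg, ch))
    sig <- sum(sa$values^2, na.rm = TRUE) * px^2
    expect_equal(sig, forward_model(1.43, 203, cfg)[[paste0("sigma_", ch)]],
                 tolerance = 0.02)
    expect_true(all(sa$values >= 0 & sa$values <= 2, na.rm = TRUE))
  }
})

test_that("the pipeline reconstruction corrects drift and stays within SA bounds", {
  cfg <- test_config()
  cam <- camera_model()
  b <- bead_spec(300, 1.45, row = 64, col = 64)
  drift <- list(offset = 0.1, gradient = c(0.002, -0.001))
  fr <- render_hologram(sim_scene(list(b), drift = drift, seed = 3),
                        cfg, cam, frame_index = 2, poisson = FALSE,
                        quantize = FALSE)
  fr_bg <- render_hologram(sim_scene(list(), seed = 3), cfg, cam,
                           frame_index = 1, poisson = FALSE, quantize = FALSE)
  sa <- reconstruct_sa(fr, fr_bg, cfg, "fs")
  ref <- reconstruct_sa(render_pair(list(b), cfg)$sample, fr_bg, cfg, "fs",
                        drift_correct = FALSE)
  expect_equal(max(sa$values), max(ref$values), tolerance = 0.05)
  expect_true(all(sa$values >= 0 & sa$values <= 2, na.rm = TRUE))
})
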