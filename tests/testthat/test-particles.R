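test_that("flow background averages exactly the two flanking frame blocks", {
  const <- lapply(1:500, function(i) matrix(3 + 4i, 4, 4))
  expect_equal(flow_background(const, 250), matrix(3 + 4i, 4, 4))

  ramp <- lapply(1:500, function(i) matrix(i + 0i, 2, 2))
  bg <- flow_background(ramp, 250)
  expect_equal(Re(bg[1, 1]), mean(c(50:149, 351:450)))

  expect_error(flow_background(ramp, 150), "too short")
})

test_that("long averaging suppresses a phase-walking particle", {
  set.seed(8)
  a <- 0.05
  stack <- lapply(1:300, function(t) {
    matrix(1 + a * exp(1i * runif(1, 0, 2 * pi)), 8, 8)
  })
  bg <- static_background(stack)
  single_contrast <- Mod(stack[[1]][1, 1] - 1)
  residual <- Mod(bg[1, 1] - 1)
  expect_gt(single_contrast / residual, 10)

  same <- lapply(1:5, function(i) matrix(2 - 1i, 3, 3))
  expect_equal(static_background(same), matrix(2 - 1i, 3, 3))
  zero <- lapply(1:5, function(i) matrix(0i, 3, 3))
  expect_equal(static_background(zero), matrix(0i, 3, 3))
})

test_that("differential SA isolates a particle above static structure", {
  expect_equal(
    differential_sa(matrix(1 + 0i, 4, 4), matrix(1 + 0i, 4, 4),
                    matrix(1 + 0i, 4, 4), alpha = 1)$values,
    matrix(0, 4, 4))
  expect_equal(
    differential_sa(matrix(2 + 0i, 4, 4), matrix(1 + 0i, 4, 4),
                    matrix(1 + 0i, 4, 4), alpha = 1)$values,
    matrix(1, 4, 4))

  # simulated: bead over static roughness; the differential SA equals the
  # bead-only SA
  cfg <- test_config()
  cam <- camera_model()
  b <- bead_spec(300, 1.45, row = 64, col = 64)
  sc_rough <- sim_scene(list(b), background_roughness_rms = 0.02, seed = 6)
  sc_rough_bg <- sim_scene(list(), background_roughness_rms = 0.02, seed = 6)
  fr_p <- render_hologram(sc_rough, cfg, cam, poisson = FALSE, quantize = FALSE)
  fr_np <- render_hologram(sc_rough_bg, cfg, cam, poisson = FALSE,
                           quantize = FALSE)
  e_p <- demultiplex(fr_p, cfg, "fs")
  e_np <- demultiplex(fr_np, cfg, "fs")
  clean <- render_pair(list(b), cfg)
  e_clean <- demultiplex(clean$sample, cfg, "fs")
  e_bg_clean <- demultiplex(clean$background, cfg, "fs")
  d_sa <- differential_sa(e_p, e_np, e_np, alpha = 1)
  ref_sa <- compute_sa(e_clean, e_bg_clean, alpha = 1)
  expect_equal(max(d_sa$values, na.rm = TRUE),
               max(ref_sa$values, na.rm = TRUE), tolerance = 0.05)
})

test_that("particle detection localizes blobs with sub-pixel accuracy", {
  expect_equal(nrow(detect_particles(matrix(0, 32, 32), 0.01)), 0)

  rm <- outer(1:64, rep(1, 64)); cm <- t(rm)
  blob <- function(r0, c0, A) A * exp(-((rm - r0)^2 + (cm - c0)^2) / (2 * 4))
  one <- detect_particles(blob(20.3, 40.7, 0.2), 0.05)
  expect_equal(nrow(one), 1)
  expect_lt(sqrt((one$row - 20.3)^2 + (one$col - 40.7)^2), 0.5)

  two_img <- blob(30, 30, 0.2) + blob(30, 40, 0.15)
  two <- detect_particles(two_img, 0.05, min_separation = 5)
  expect_equal(nrow(two), 2)
})

test_that("cross-section estimators agree with the Gaussian closed form", {
  expect_equal(as.numeric(cross_section(matrix(0, 32, 32), c(16, 16),
                                        mode = "pixel")), 0)
  rm <- outer(1:41, rep(1, 41)); cm <- t(rm)
  A <- 0.1; s <- 2
  g <- A * exp(-((rm - 21)^2 + (cm - 21)^2) / (2 * s^2))
  cs <- cross_section(g, c(21, 21), mode = "gauss", roi_radius = 15)
  expect_equal(as.numeric(cs), A^2 * pi * s^2, tolerance = 0.005)
  expect_equal(unname(attr(cs, "fit")["width"]), s, tolerance = 1e-3)
  cs_px <- cross_section(g, c(21, 21), mode = "pixel", roi_radius = 15)
  expect_equal(as.numeric(cs_px), A^2 * pi * s^2, tolerance = 0.005)
  # physical units attach through the pixel size
  cs_um <- cross_section(g, c(21, 21), mode = "gauss", roi_radius = 15,
                         pixel_size = 0.0433)
  expect_equal(attr(cs_um, "sigma_physical"),
               as.numeric(cs_um) * 0.0433^2)
})

test_that("normalization maps the reference population to unity", {
  rec <- data.frame(sigma_fs = c(2, 4), sigma_bs = c(1, 3))
  out <- normalize_cross_sections(rec, 2, 1)
  expect_equal(out$sigma_fs_norm, c(1, 2))
  expect_equal(out$sigma_bs_norm, c(1, 3))
  empty <- normalize_cross_sections(rec[0, ], 2, 1)
  expect_equal(nrow(empty), 0)
  # temporal averaging per particle happens before normalization
  rep_rec <- data.frame(particle = c(1, 1, 2), frame = 1:3,
                        sigma_fs = c(1, 3, 4), sigma_bs = c(2, 2, 8))
  out2 <- normalize_cross_sections(rep_rec, 2, 2)
  expect_equal(sort(out2$sigma_fs_norm), c(1, 2))
})

test_that("refractive index and size invert exactly from noise-free cross-sections", {
  cfg <- optical_config()
  grid <- cached_grid()
  ref <- grid$reference_sigma

  fm <- forward_model(1.43, 203, cfg)
  inv <- invert_ri_size(fm$sigma_fs / ref[["fs"]], fm$sigma_bs / ref[["bs"]],
                        grid)
  expect_equal(inv$n, 1.43, tolerance = 1e-3)
  expect_equal(inv$d, 203, tolerance = 1e-2)
  expect_false(inv$boundary)

  # the reference particle itself is a fixed point of the normalization
  inv_ref <- invert_ri_size(1, 1, grid)
  expect_equal(inv_ref$n, grid$reference[["n"]], tolerance = 1e-3)
  expect_equal(inv_ref$d, grid$reference[["d"]], tolerance = 1e-2)

  # grid-point round trips recover exactly (no refinement needed)
  set.seed(12)
  for (i in 1:10) {
    n0 <- sample(grid$n_grid[10:150], 1)
    d0 <- sample(grid$d_grid[10:200], 1)
    f <- forward_model(n0, d0, cfg)
    iv <- invert_ri_size(f$sigma_fs / ref[["fs"]], f$sigma_bs / ref[["bs"]],
                         grid, refine = FALSE)
    expect_equal(iv$n, n0, tolerance = 1e-9)
    expect_equal(iv$d, d0, tolerance = 1e-9)
  }
})

test_that("bounds clip the inversion and flag boundary estimates", {
  cfg <- optical_config()
  grid <- cached_grid()
  ref <- grid$reference_sigma
  fm <- forward_model(1.43, 203, cfg)
  inv <- invert_ri_size(fm$sigma_fs / ref[["fs"]], fm$sigma_bs / ref[["bs"]],
                        grid, bounds = list(n = c(1.46, 1.54)))
  expect_true(inv$boundary)
  expect_gte(inv$n, 1.46)
})

test_that("uncertainties propagate through the local Jacobian", {
  cfg <- optical_config()
  grid <- cached_grid()
  ref <- grid$reference_sigma
  fm <- forward_model(1.45, 250, cfg)
  inv <- invert_ri_size(fm$sigma_fs / ref[["fs"]], fm$sigma_bs / ref[["bs"]],
                        grid, sigma_rel_unc = c(0.08, 0.08))
  expect_true(is.finite(inv$sigma_n) && inv$sigma_n > 0)
  expect_true(is.finite(inv$sigma_d) && inv$sigma_d > 0)
  # Rayleigh-ish scaling: d ~ sigma^(1/6) puts the size uncertainty near
  # d * rel_unc / 6 within an order of magnitude
  expect_lt(inv$sigma_d, 250 * 0.08)
  expect_gt(inv$sigma_d, 250 * 0.08 / 60)
})

test_that("simulated bead populations separate in BS and recover their parameters", {
  cfg <- optical_config()
  grid <- cached_grid()
  pop <- simulate_bead_population(cfg, seed = 7)
  ps <- pop[pop$population == "polystyrene", ]
  si <- pop[pop$population == "silica", ]

  # forward cross-sections overlap; backward ones separate
  smd <- function(a, b) abs(mean(a) - mean(b)) / sqrt((var(a) + var(b)) / 2)
  smd_fs <- smd(ps$sigma_fs_norm, si$sigma_fs_norm)
  smd_bs <- smd(ps$sigma_bs_norm, si$sigma_bs_norm)
  expect_gt(smd_bs, 3 * smd_fs)
  overlap <- mean(si$sigma_fs_norm > min(ps$sigma_fs_norm) &
                  si$sigma_fs_norm < max(ps$sigma_fs_norm))
  expect_gt(overlap, 0.2)

  # population-mean recovery
  inv_si <- vapply(seq_len(nrow(si)), function(i) {
    unlist(invert_ri_size(si$sigma_fs_norm[i], si$sigma_bs_norm[i], grid,
                          refine = FALSE)[c("n", "d")])
  }, numeric(2))
  expect_lt(abs(mean(inv_si[1, ]) - 1.43), 0.01)
  expect_lt(abs(mean(inv_si[2, ]) - 203), 10)
})
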