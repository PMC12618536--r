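# Shared fixtures: a compact instrument configuration whose geometry is
# clean for reconstruction tests (pupil support strictly inside the
# spatial-frequency aperture, carriers separated from the DC
# autocorrelation support), plus cached expensive objects.

test_config <- function(shape = c(128L, 128L)) {
  optical_config(sensor_shape = shape,
                 aperture_radius_px = max(3, round(10 * shape[1] / 128)),
                 collection_na = 0.9)
}

# correlation modulus between two complex matrices
field_correlation <- function(a, b) {
  Mod(sum(a * Conj(b))) / sqrt(sum(Mod(a)^2) * sum(Mod(b)^2))
}

# noise-free sample/background hologram pair for a set of beads
render_pair <- function(beads, cfg, seed = 3) {
  cam <- camera_model()
  fr <- render_hologram(sim_scene(beads, seed = seed), cfg, cam,
                        poisson = FALSE, quantize = FALSE)
  fr_bg <- render_hologram(sim_scene(list(), seed = seed), cfg, cam,
                           poisson = FALSE, quantize = FALSE)
  list(sample = fr, background = fr_bg)
}

# model grid reused across particle tests (built once per test run)
cached_grid <- local({
  grid <- NULL
  function() {
    if (is.null(grid)) {
      grid <<- scatter_model_grid(optical_config(),
                                  n_grid = seq(1.36, 1.72, by = 0.002),
                                  d_grid = seq(40, 600, by = 2))
    }
    grid
  }
})
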