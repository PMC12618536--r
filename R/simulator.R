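#' Bead specification for the hologram simulator
#'
#' A spherical scatterer with a diameter, a refractive index, and a
#' (possibly time-varying) position. Lateral positions are in sample-plane
#' pixels (row, col, origin at the image centre is *not* assumed — they are
#' plain array coordinates), axial positions in micrometres.
#'
#' @param diameter Bead diameter (nm).
#' @param index Bead refractive index. Equal to the medium index gives a
#'   null scatterer.
#' @param row,col Initial lateral position (sample-plane pixels).
#' @param z Axial offset from the focal plane (um).
#' @param trajectory Optional matrix/data.frame with columns
#'   `frame, row, col, z` overriding the static position per frame.
#' @return An object of class `bead_spec`.
#' @export
bead_spec <- function(diameter, index, row, col, z = 0, trajectory = NULL) {
  stopifnot(diameter > 0, index > 0)
  if (!is.null(trajectory)) {
    trajectory <- as.data.frame(trajectory)
    stopifnot(all(c("frame", "row", "col", "z") %in% names(trajectory)))
  }
  structure(list(diameter = diameter, index = index,
                 row = row, col = col, z = z, trajectory = trajectory),
            class = "bead_spec")
}

bead_position <- function(bead, frame_index) {
  tr <- bead$trajectory
  if (is.null(tr)) {
    return(c(row = bead$row, col = bead$col, z = bead$z))
  }
  i <- match(frame_index, tr$frame)
  if (is.na(i)) {
    return(c(row = NA_real_, col = NA_real_, z = NA_real_))
  }
  c(row = tr$row[i], col = tr$col[i], z = tr$z[i])
}

#' Simulated scene: beads, background, drift and photon budget
#'
#' Collects everything the renderer needs besides the instrument itself.
#' The defaults describe the reference acquisition conditions: fringe
#' visibility 0.25 per channel; a forward-channel budget of 20,000
#' photoelectrons per pixel per unit incident intensity with the epi
#' illumination 204 times stronger (`1/alpha_bs^2`), which equalizes the
#' per-pixel electron budget of the two channels on the sensor; a static
#' substrate-roughness speckle; and no interferometer drift.
#'
#' @param beads List of [bead_spec()] objects (possibly empty).
#' @param background_roughness_rms Static substrate roughness amplitude in
#'   SA-equivalent units (rms of `alpha * |roughness field|`).
#' @param drift List with `offset` (radians/frame) and `gradient`
#'   (radians/pixel/frame, length 2): a global phase offset and a linear
#'   phase ramp, both accumulating linearly with the frame index.
#' @param visibility Named numeric `c(fs = , bs = )`, fringe modulation
#'   depth of each carrier relative to the frame's total DC intensity.
#' @param illumination_scale Named numeric `c(fs = , bs = )`: expected
#'   photoelectrons per pixel contributed by a unit-intensity incident
#'   field of that channel; the channel's background DC is
#'   `illumination_scale * alpha^2`.
#' @param seed Integer seed; together with the frame index it fully
#'   determines the rendered output.
#' @return An object of class `sim_scene`.
#' @export
sim_scene <- function(beads = list(),
                      background_roughness_rms = 0,
                      drift = list(offset = 0, gradient = c(0, 0)),
                      visibility = c(fs = 0.25, bs = 0.25),
                      illumination_scale = c(fs = 2e4, bs = 2e4 / 0.07^2),
                      seed = 1L) {
  if (inherits(beads, "bead_spec")) beads <- list(beads)
  stopifnot(all(vapply(beads, inherits, TRUE, "bead_spec")))
  stopifnot(all(visibility >= 0), all(visibility <= 1))
  stopifnot(all(illumination_scale > 0), background_roughness_rms >= 0)
  structure(list(beads = beads,
                 background_roughness_rms = background_roughness_rms,
                 drift = drift,
                 visibility = visibility,
                 illumination_scale = illumination_scale,
                 seed = as.integer(seed)),
            class = "sim_scene")
}

# fold a (seed, salt) pair into a valid 32-bit seed without overflow
derive_seed <- function(seed, salt) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(salt)) %% 2147483629)
}

# run code with a deterministic RNG stream, restoring the caller's state
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

# static band-limited complex speckle with spatial rms modulus `rms`
# (per channel, fixed by the scene seed)
roughness_field <- function(scene, config, channel) {
  if (scene$background_roughness_rms <= 0) {
    return(matrix(0 + 0i, config$sensor_shape[1], config$sensor_shape[2]))
  }
  shape <- config$sensor_shape
  alpha <- channel_alpha(config, channel)
  sd_target <- scene$background_roughness_rms / alpha
  chan_off <- if (channel == "fs") 11L else 22L
  with_seed(derive_seed(scene$seed, 1e6 + chan_off), {
    spec <- matrix(complex(real = stats::rnorm(prod(shape)),
                           imaginary = stats::rnorm(prod(shape))),
                   shape[1], shape[2])
    mask <- disc_mask(shape, c(0, 0), config$aperture_radius_px)
    spec[!mask] <- 0
    f <- ifft2(ifftshift2(spec))
    f * sd_target / sqrt(mean(Mod(f)^2))
  })
}

#' Coherent scattered field of a single bead
#'
#' Amplitude point-spread function of a circular pupil of the configured
#' collection NA, centred on the bead with sub-pixel accuracy, defocused
#' by angular-spectrum phase, and scaled so that the integrated squared
#' scattering-field amplitude equals the Mie forward-model cross-section
#' of the bead in that channel (see [forward_model()]). Fields of multiple
#' beads superpose linearly.
#'
#' The returned values are in SA units (scattered field over incident
#' field); the scattered field is given a 90-degree phase relative to the
#' background, the weak-scatterer convention.
#'
#' @param bead A [bead_spec()].
#' @param config An [optical_config()].
#' @param channel `"fs"` or `"bs"`.
#' @param defocus Axial offset from focus (um). Bounded by
#'   `max_defocus`.
#' @param frame_index Frame used to look up a moving bead's position.
#' @param max_defocus Validity guard for the angular-spectrum defocus (um).
#' @return A [complex_field()] in SA units.
#' @export
scattered_field <- function(bead, config, channel, defocus = NULL,
                            frame_index = 1L, max_defocus = 100) {
  channel <- match.arg(channel, c("fs", "bs"))
  shape <- config$sensor_shape
  pos <- bead_position(bead, frame_index)
  empty <- function() {
    field_from_config(matrix(0 + 0i, shape[1], shape[2]), channel, config)
  }
  if (any(is.na(pos))) return(empty())
  z <- if (is.null(defocus)) pos[["z"]] else defocus
  if (abs(z) > max_defocus) {
    stop("defocus beyond the configured validity bound (", max_defocus, " um)")
  }
  sigma <- forward_model(bead$index, bead$diameter, config)[[paste0("sigma_", channel)]]
  if (sigma <= 0) return(empty())

  p <- sample_pixel(config)                       # um per sample-plane px
  g <- freq_grid(shape)
  fr <- g$fr / p                                  # cycles/um
  fc <- g$fc / p
  f2 <- fr^2 + fc^2
  f_na <- config$collection_na / config$wavelength
  pupil <- f2 <= f_na^2
  kz <- 2 * pi * sqrt(pmax((config$medium_index / config$wavelength)^2 - f2, 0))
  kz0 <- 2 * pi * config$medium_index / config$wavelength
  spec <- matrix(0 + 0i, shape[1], shape[2])
  # sub-pixel shift to the bead position + defocus, relative on-axis phase
  # removed so a focused bead has a real-positive peak
  phase <- -2 * pi * (g$fr * pos[["row"]] + g$fc * pos[["col"]]) +
    z * (kz - kz0)
  spec[pupil] <- exp(1i * phase[pupil])
  psf <- ifft2(ifftshift2(spec))
  norm <- sum(Mod(psf)^2) * p^2                  # um^2
  field_from_config(1i * psf * sqrt(sigma / norm), channel, config)
}

#' Render one multiplexed hologram frame
#'
#' Forms the two channel fields (background of unit normalized amplitude
#' plus static roughness speckle plus bead scattering over `alpha`),
#' applies the accumulated phase drift, and composes the sensor intensity
#'
#' `I = D + mean(D) * sum_c nu_c * Re(Etilde_c * conj(R_c))`
#'
#' where `D` is the summed per-channel DC intensity (in expected
#' photoelectrons) and `R_c` are unit plane waves at the two carriers, so
#' that `nu_c` is each fringe's modulation depth against the frame's total
#' DC. The expected electrons are Poisson-sampled and quantized by the
#' camera model; the output is bit-identical for a given scene seed and
#' frame index.
#'
#' @param scene A [sim_scene()].
#' @param config An [optical_config()].
#' @param camera A [camera_model()].
#' @param frame_index Frame index (drives drift, motion and the RNG
#'   stream).
#' @param poisson Apply Poisson shot noise (default `TRUE`).
#' @param quantize Quantize to digital numbers (default `TRUE`); when
#'   `FALSE` the frame holds continuous, noise-free-capable values in DN
#'   units (for ideal-reconstruction tests).
#' @return A [hologram_frame()].
#' @export
render_hologram <- function(scene, config, camera = camera_model(),
                            frame_index = 1L, poisson = TRUE,
                            quantize = TRUE) {
  shape <- config$sensor_shape
  t <- frame_index - 1L
  ramp <- {
    r <- matrix(seq_len(shape[1]) - 1, shape[1], shape[2])
    cc <- matrix(seq_len(shape[2]) - 1, shape[1], shape[2], byrow = TRUE)
    scene$drift$offset * t +
      t * (scene$drift$gradient[1] * r + scene$drift$gradient[2] * cc)
  }
  drift_phasor <- if (all(ramp == 0)) 1 else exp(1i * ramp)

  total_dc <- matrix(0, shape[1], shape[2])
  fringe <- matrix(0, shape[1], shape[2])
  etil <- list()
  for (channel in c("fs", "bs")) {
    alpha <- channel_alpha(config, channel)
    es <- matrix(0 + 0i, shape[1], shape[2])
    for (bead in scene$beads) {
      es <- es + scattered_field(bead, config, channel,
                                 frame_index = frame_index)$values
    }
    etilde <- (1 + roughness_field(scene, config, channel) + es / alpha) *
      drift_phasor
    etil[[channel]] <- etilde
    budget <- scene$illumination_scale[[channel]] * alpha^2
    total_dc <- total_dc + budget * Mod(etilde)^2
  }
  dbar <- mean(total_dc)
  for (channel in c("fs", "bs")) {
    rw <- plane_wave(shape, channel_carrier(config, channel))
    fringe <- fringe + scene$visibility[[channel]] *
      Re(etil[[channel]] * Conj(rw))
  }
  expected <- total_dc + dbar * fringe

  ideal <- !poisson && !quantize   # linear mode: no clipping, no sampling
  if (!ideal && any(expected > camera$full_well)) {
    warning(sprintf("saturation: %.2f%% of pixels exceed the full well; clipped",
                    100 * mean(expected > camera$full_well)))
  }
  electrons <- if (poisson) {
    with_seed(derive_seed(scene$seed, frame_index), {
      matrix(stats::rpois(length(expected), pmax(expected, 0)),
             shape[1], shape[2])
    })
  } else {
    expected
  }
  if (!ideal) electrons <- pmin(electrons, camera$full_well)
  dn <- if (quantize) {
    electrons_to_dn(electrons, camera)
  } else {
    electrons / camera_gain(camera)   # continuous, unclipped in DN units
  }
  hologram_frame(dn, timestamp_index = frame_index, camera = camera,
                 validate_range = !ideal)
}

#' Motion models for simulated time series
#'
#' `motion_none()` keeps beads at their static position; `motion_flow()`
#' translates them at a constant lateral velocity (sample-plane
#' pixels/frame) so a bead crosses the field of view around `t0`;
#' `motion_brownian()` applies independent Gaussian lateral increments of
#' variance `2 * D` per axis per frame (`D` in px^2/frame), with optional
#' axial diffusion `D_z` (um^2/frame).
#'
#' @param velocity Length-2 lateral velocity, px/frame.
#' @param t0 Frame at which a flowing bead passes its nominal position.
#' @param D Lateral diffusion coefficient, px^2/frame.
#' @param D_z Axial diffusion coefficient, um^2/frame.
#' @return A motion descriptor consumed by [simulate_timeseries()].
#' @name motion
#' @export
motion_none <- function() structure(list(kind = "none"), class = "motion_model")

#' @rdname motion
#' @export
motion_flow <- function(velocity, t0) {
  structure(list(kind = "flow", velocity = velocity, t0 = t0),
            class = "motion_model")
}

#' @rdname motion
#' @export
motion_brownian <- function(D, D_z = 0) {
  structure(list(kind = "brownian", D = D, D_z = D_z), class = "motion_model")
}

# trajectory table for one bead under a motion model
build_trajectory <- function(bead, motion, n_frames, shape, seed) {
  frames <- seq_len(n_frames)
  switch(motion$kind,
    none = data.frame(frame = frames, row = bead$row, col = bead$col,
                      z = bead$z),
    flow = data.frame(frame = frames,
                      row = bead$row + (frames - motion$t0) * motion$velocity[1],
                      col = bead$col + (frames - motion$t0) * motion$velocity[2],
                      z = bead$z),
    brownian = with_seed(seed, {
      sd_lat <- sqrt(2 * motion$D)
      sd_ax <- sqrt(2 * motion$D_z)
      data.frame(
        frame = frames,
        row = bead$row + cumsum(c(0, stats::rnorm(n_frames - 1, 0, sd_lat))),
        col = bead$col + cumsum(c(0, stats::rnorm(n_frames - 1, 0, sd_lat))),
        z = bead$z + cumsum(c(0, stats::rnorm(n_frames - 1, 0,
                                              if (sd_ax > 0) sd_ax else 0))))
    }),
    stop("unknown motion model")
  )
}

#' Simulate a hologram time series with ground truth
#'
#' Renders `n_frames` holograms of the scene with per-frame bead positions
#' following the motion model and the phase drift accumulating linearly.
#' Beads that move outside the field of view are logged (message) and
#' simply contribute nothing to those frames.
#'
#' @inheritParams render_hologram
#' @param n_frames Number of frames (>= 1).
#' @param motion A [motion_none()], [motion_flow()] or [motion_brownian()]
#'   descriptor applied to every bead without an explicit trajectory.
#' @return List with `frames` (list of [hologram_frame()]), `truth`
#'   (data.frame: frame, bead, row, col, z, time_s, diameter, index),
#'   and the `scene`, `config`, `camera` used.
#' @export
simulate_timeseries <- function(scene, config, camera = camera_model(),
                                n_frames, motion = motion_none(),
                                poisson = TRUE, quantize = TRUE) {
  stopifnot(n_frames >= 1)
  shape <- config$sensor_shape
  beads <- scene$beads
  truth <- list()
  for (b in seq_along(beads)) {
    if (is.null(beads[[b]]$trajectory)) {
      beads[[b]]$trajectory <- build_trajectory(
        beads[[b]], motion, n_frames, shape,
        seed = derive_seed(scene$seed, 2e6 + b))
    }
    tr <- beads[[b]]$trajectory
    out_fov <- tr$row < 1 | tr$row > shape[1] | tr$col < 1 | tr$col > shape[2]
    if (any(out_fov)) {
      message(sprintf("bead %d outside the FOV in %d/%d frames",
                      b, sum(out_fov), n_frames))
      tr$row[out_fov] <- NA; tr$col[out_fov] <- NA
      beads[[b]]$trajectory <- tr
    }
    truth[[b]] <- data.frame(frame = tr$frame, bead = b, row = tr$row,
                             col = tr$col, z = tr$z,
                             time_s = (tr$frame - 1) / config$frame_rate,
                             diameter = beads[[b]]$diameter,
                             index = beads[[b]]$index)
  }
  scene$beads <- beads
  frames <- lapply(seq_len(n_frames), function(i) {
    render_hologram(scene, config, camera, frame_index = i,
                    poisson = poisson, quantize = quantize)
  })
  list(frames = frames,
       truth = if (length(truth)) do.call(rbind, truth) else
         data.frame(frame = integer(), bead = integer(), row = numeric(),
                    col = numeric(), z = numeric(), time_s = numeric(),
                    diameter = numeric(), index = numeric()),
       scene = scene, config = config, camera = camera)
}
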