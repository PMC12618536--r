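#' Optical configuration for a dual-channel multiplexed holographic microscope
#'
#' Collects the instrument constants shared by the simulator and the
#' reconstruction pipeline: illumination wavelength, imaging geometry,
#' the background transmittance/reflectivity `alpha` of each scattering
#' channel, and the two off-axis fringe carriers that multiplex the
#' forward-scattering (FS, transmission) and backward-scattering (BS, epi)
#' channels onto one sensor frame.
#'
#' Lengths are in micrometres throughout. Spatial frequencies (the
#' carriers) are in cycles per sensor pixel on the centred (fftshifted)
#' grid. The default values describe a water-immersion instrument:
#' 515 nm illumination, collection NA 1.33 in aqueous medium,
#' magnification 208, a 1024 x 1024 sensor read at 500 fps, and a
#' spatial-frequency aperture of radius 115 pixels (diameter 230) that
#' matches the NA-limited support of the transfer function.
#'
#' `alpha_fs = 1` expresses that the full transmitted background reaches
#' the sensor in the forward channel; `alpha_bs = 0.07` is the field
#' reflectivity of the glass--water interface that supplies the epi
#' background. The sensor pixel pitch is not an independent instrument
#' datum here; its default (9 um) is inferred from the 44 um field of
#' view at magnification 208.
#'
#' @param wavelength Illumination vacuum wavelength (um).
#' @param medium_index Refractive index of the immersion/sample medium.
#' @param collection_na Numerical aperture of the collection optics.
#' @param magnification Sensor-to-sample magnification.
#' @param alpha_fs,alpha_bs Background field transmittance (FS) and
#'   reflectivity (BS), in (0, 1].
#' @param sensor_shape Integer vector `c(rows, cols)` of sensor pixels.
#' @param sensor_pixel_pitch Sensor pixel pitch (um).
#' @param aperture_radius_px Radius, in spatial-frequency pixels, of the
#'   circular window used to extract each carrier lobe.
#' @param carrier_fs,carrier_bs Carrier spatial frequency of each channel,
#'   `c(f_row, f_col)` in cycles/pixel.
#' @param frame_rate Acquisition frame rate (Hz).
#' @return An object of class `optical_config`.
#' @seealso [camera_model()], [demultiplex()], [render_hologram()]
#' @export
#' @examples
#' cfg <- optical_config()
#' cfg$alpha_bs
#' sample_pixel(cfg)   # sample-plane pixel, um
optical_config <- function(wavelength = 0.515,
                           medium_index = 1.33,
                           collection_na = 1.33,
                           magnification = 208,
                           alpha_fs = 1.0,
                           alpha_bs = 0.07,
                           sensor_shape = c(1024L, 1024L),
                           sensor_pixel_pitch = 9,
                           aperture_radius_px = 115,
                           carrier_fs = c(0.25, 0),
                           carrier_bs = c(0, 0.25),
                           frame_rate = 500) {
  cfg <- list(
    wavelength = wavelength,
    medium_index = medium_index,
    collection_na = collection_na,
    magnification = magnification,
    alpha_fs = alpha_fs,
    alpha_bs = alpha_bs,
    sensor_shape = as.integer(sensor_shape),
    sensor_pixel_pitch = sensor_pixel_pitch,
    aperture_radius_px = aperture_radius_px,
    carrier_fs = as.numeric(carrier_fs),
    carrier_bs = as.numeric(carrier_bs),
    frame_rate = frame_rate
  )
  class(cfg) <- "optical_config"
  validate_optical_config(cfg)
  cfg
}

validate_optical_config <- function(cfg) {
  stopifnot(
    cfg$wavelength > 0, cfg$medium_index >= 1,
    cfg$magnification > 0, cfg$sensor_pixel_pitch > 0,
    length(cfg$sensor_shape) == 2, all(cfg$sensor_shape >= 8),
    cfg$aperture_radius_px > 0, cfg$frame_rate > 0
  )
  if (cfg$alpha_fs <= 0 || cfg$alpha_fs > 1 ||
      cfg$alpha_bs <= 0 || cfg$alpha_bs > 1) {
    stop("alpha values must lie in (0, 1]")
  }
  if (cfg$collection_na > cfg$medium_index) {
    stop("collection_na cannot exceed medium_index")
  }
  # carrier lobes, dilated by the aperture radius, must not overlap each
  # other, the DC lobe, or the Nyquist boundary
  n <- cfg$sensor_shape
  r <- cfg$aperture_radius_px
  p_fs <- cfg$carrier_fs * n
  p_bs <- cfg$carrier_bs * n
  d <- function(a, b) sqrt(sum((a - b)^2))
  if (d(p_fs, c(0, 0)) < 2 * r || d(p_bs, c(0, 0)) < 2 * r) {
    stop("carrier lobe overlaps the DC lobe (separation < 2 * aperture radius)")
  }
  if (d(p_fs, p_bs) < 2 * r) {
    stop("FS and BS carrier lobes overlap")
  }
  if (max(abs(p_fs)) + r > min(n) / 2 || max(abs(p_bs)) + r > min(n) / 2) {
    stop("carrier lobe does not fit inside the Nyquist square")
  }
  invisible(cfg)
}

#' @export
print.optical_config <- function(x, ...) {
  cat("<optical_config>\n")
  cat(sprintf("  wavelength %g um, medium n %g, NA %g, magnification %g\n",
              x$wavelength, x$medium_index, x$collection_na, x$magnification))
  cat(sprintf("  sensor %d x %d px (pitch %g um), sample pixel %.4f um\n",
              x$sensor_shape[1], x$sensor_shape[2], x$sensor_pixel_pitch,
              sample_pixel(x)))
  cat(sprintf("  alpha FS %g / BS %g, aperture radius %g px, %g fps\n",
              x$alpha_fs, x$alpha_bs, x$aperture_radius_px, x$frame_rate))
  cat(sprintf("  carriers FS (%g, %g), BS (%g, %g) cycles/px\n",
              x$carrier_fs[1], x$carrier_fs[2],
              x$carrier_bs[1], x$carrier_bs[2]))
  invisible(x)
}

#' Sample-plane pixel size
#'
#' @param config An [optical_config()].
#' @return Sample-plane pixel pitch (um), `sensor_pixel_pitch / magnification`.
#' @export
sample_pixel <- function(config) {
  config$sensor_pixel_pitch / config$magnification
}

#' Channel alpha lookup
#'
#' @param config An [optical_config()].
#' @param channel `"fs"` or `"bs"`.
#' @return The background transmittance (FS) or reflectivity (BS).
#' @export
channel_alpha <- function(config, channel) {
  channel <- match.arg(channel, c("fs", "bs"))
  if (channel == "fs") config$alpha_fs else config$alpha_bs
}

channel_carrier <- function(config, channel) {
  channel <- match.arg(channel, c("fs", "bs"))
  if (channel == "fs") config$carrier_fs else config$carrier_bs
}

#' Camera electron/digital-number model
#'
#' Linear photoelectron model of a scientific CMOS camera: the conversion
#' gain is `full_well / 2^bit_depth` electrons per digital number (DN),
#' and DN values are clipped to `[0, 2^bit_depth - 1]`. The default is a
#' 100 ke- full well at 12 bit; read noise defaults to 0 (shot-noise
#' limited operation).
#'
#' @param full_well Full-well capacity (electrons).
#' @param bit_depth ADC bit depth.
#' @param read_noise Read noise, electrons rms.
#' @return An object of class `camera_model`.
#' @export
#' @examples
#' cam <- camera_model()
#' camera_gain(cam)  # 24.414 e-/DN
camera_model <- function(full_well = 1e5, bit_depth = 12, read_noise = 0) {
  stopifnot(full_well > 0, bit_depth >= 1, bit_depth == round(bit_depth),
            read_noise >= 0)
  structure(list(full_well = full_well, bit_depth = as.integer(bit_depth),
                 read_noise = read_noise),
            class = "camera_model")
}

#' @export
print.camera_model <- function(x, ...) {
  cat(sprintf("<camera_model> full well %g e-, %d bit, gain %.4g e-/DN, read noise %g e-\n",
              x$full_well, x$bit_depth, camera_gain(x), x$read_noise))
  invisible(x)
}

#' @rdname camera_model
#' @param camera A `camera_model`.
#' @return `camera_gain()`: electrons per digital number.
#' @export
camera_gain <- function(camera) {
  camera$full_well / 2^camera$bit_depth
}

dn_max <- function(camera) 2^camera$bit_depth - 1

#' Single hologram frame
#'
#' A frame of camera digital numbers carrying both fringe systems.
#'
#' @param dn Matrix of digital numbers (integers within the camera's
#'   bit-depth range; non-integer values are accepted only for ideal,
#'   noise-free synthetic frames).
#' @param timestamp_index Frame index in its acquisition series.
#' @param camera The [camera_model()] that produced the frame.
#' @param validate_range Enforce the bit-depth range (default `TRUE`;
#'   ideal noise-free synthetic frames may exceed it).
#' @return An object of class `hologram_frame`.
#' @export
hologram_frame <- function(dn, timestamp_index = 1L, camera = camera_model(),
                           validate_range = TRUE) {
  stopifnot(is.matrix(dn), is.numeric(dn))
  if (any(!is.finite(dn))) stop("hologram contains non-finite values")
  if (validate_range && (any(dn < 0) || any(dn > dn_max(camera)))) {
    stop("digital numbers outside the camera bit-depth range")
  }
  structure(list(dn = dn, timestamp_index = as.integer(timestamp_index),
                 camera = camera),
            class = "hologram_frame")
}

#' @export
print.hologram_frame <- function(x, ...) {
  cat(sprintf("<hologram_frame> %d x %d px, frame %d, mean %.1f DN\n",
              nrow(x$dn), ncol(x$dn), x$timestamp_index, mean(x$dn)))
  invisible(x)
}

#' Convert digital numbers to photoelectrons
#'
#' @param frame A [hologram_frame()], or a numeric matrix of digital
#'   numbers (then `camera` must be given).
#' @param camera A [camera_model()]; taken from the frame if omitted.
#' @return Matrix of electron counts, `dn * gain`.
#' @export
#' @examples
#' f <- hologram_frame(matrix(2048, 4, 4))
#' dn_to_electrons(f)[1, 1]  # 50000
dn_to_electrons <- function(frame, camera = NULL) {
  if (inherits(frame, "hologram_frame")) {
    camera <- frame$camera
    dn <- frame$dn
  } else {
    if (is.null(camera)) stop("camera must be supplied for a bare matrix")
    dn <- frame
  }
  if (any(dn < 0) || any(dn > dn_max(camera))) {
    stop("digital numbers outside the camera bit-depth range")
  }
  dn * camera_gain(camera)
}

#' Convert photoelectrons to digital numbers
#'
#' Inverse of [dn_to_electrons()]: divides by the gain, rounds, and clips
#' to the bit-depth range.
#'
#' @param electrons Numeric matrix of electron counts.
#' @param camera A [camera_model()].
#' @return Integer-valued matrix of digital numbers.
#' @export
electrons_to_dn <- function(electrons, camera) {
  pmin(pmax(round(electrons / camera_gain(camera)), 0), dn_max(camera))
}

#' Analytic pixel count of the spatial-frequency aperture
#'
#' Area of the circular spatial-frequency window of the given radius,
#' `round(pi/4 * (2 * radius)^2)` pixels. This analytic disc area (not a
#' lattice-point count) is the `A_aperture` entering the shot-noise floor.
#'
#' @param radius_px Aperture radius in spatial-frequency pixels.
#' @return Integer pixel count.
#' @export
#' @examples
#' aperture_pixel_count(115)  # 41548
aperture_pixel_count <- function(radius_px) {
  stopifnot(radius_px > 0)
  round(pi / 4 * (2 * radius_px)^2)
}

#' Reconstructed complex amplitude of one scattering channel
#'
#' @param values Complex matrix (sample-plane grid).
#' @param channel `"fs"` or `"bs"`.
#' @param sample_plane_pixel Sample-plane pixel pitch (um).
#' @param wavelength Vacuum wavelength (um).
#' @param medium_index Medium refractive index.
#' @param z_offset Current refocus offset (um).
#' @return An object of class `complex_field`.
#' @export
complex_field <- function(values, channel, sample_plane_pixel,
                          wavelength, medium_index, z_offset = 0) {
  stopifnot(is.matrix(values))
  if (any(!is.finite(Re(values))) || any(!is.finite(Im(values)))) {
    stop("complex field contains non-finite values")
  }
  channel <- match.arg(channel, c("fs", "bs"))
  structure(list(values = as.matrix(values) + 0i, channel = channel,
                 sample_plane_pixel = sample_plane_pixel,
                 wavelength = wavelength, medium_index = medium_index,
                 z_offset = z_offset),
            class = "complex_field")
}

#' @export
print.complex_field <- function(x, ...) {
  cat(sprintf(
    "<complex_field> %s, %d x %d px (%.4f um/px), z = %g um, mean |E| = %.4g\n",
    toupper(x$channel), nrow(x$values), ncol(x$values),
    x$sample_plane_pixel, x$z_offset, mean(Mod(x$values))))
  invisible(x)
}

field_from_config <- function(values, channel, config, z_offset = 0) {
  complex_field(values, channel, sample_pixel(config),
                config$wavelength, config$medium_index, z_offset)
}

stopifnot_same_grid <- function(a, b) {
  stopifnot(inherits(a, "complex_field"), inherits(b, "complex_field"))
  if (a$channel != b$channel) stop("fields are from different channels")
  if (!identical(dim(a$values), dim(b$values))) {
    stop("fields have different shapes")
  }
  invisible(TRUE)
}

#' Read or write an optical/camera configuration file
#'
#' YAML files with one key per [optical_config()] / [camera_model()]
#' field; missing keys fall back to the package defaults, so an empty
#' file reproduces the reference instrument constants.
#'
#' @param path File path.
#' @return `read_config()`: a list with elements `optical` and `camera`.
#' @export
read_config <- function(path) {
  raw <- if (file.exists(path)) yaml::read_yaml(path) else stop("no such file: ", path)
  if (is.null(raw)) raw <- list()
  opt_names <- names(formals(optical_config))
  cam_names <- names(formals(camera_model))
  opt_args <- raw[names(raw) %in% opt_names]
  cam_args <- raw[names(raw) %in% cam_names]
  list(optical = do.call(optical_config, opt_args),
       camera = do.call(camera_model, cam_args))
}

#' @rdname read_config
#' @param optical An [optical_config()].
#' @param camera A [camera_model()].
#' @export
write_config <- function(path, optical = optical_config(),
                         camera = camera_model()) {
  x <- c(unclass(optical), unclass(camera))
  yaml::write_yaml(x, path)
  invisible(path)
}

#' Half-pitch lateral resolution of the instrument
#'
#' @param config An [optical_config()].
#' @return `wavelength / (2 * collection_na)` in um.
#' @export
half_pitch_resolution <- function(config) {
  config$wavelength / (2 * config$collection_na)
}

#' Normal-incidence Fresnel amplitude reflectivity
#'
#' Field (not intensity) reflectivity of a planar interface,
#' `|n1 - n2| / (n1 + n2)`; with glass and water it supplies the epi
#' channel's background `alpha`.
#'
#' @param n1,n2 Refractive indices on either side of the interface.
#' @return Amplitude reflectivity in `[0, 1)`.
#' @export
#' @examples
#' fresnel_reflectivity(1.52, 1.33)  # ~0.067, the BS alpha
fresnel_reflectivity <- function(n1, n2) {
  abs(n1 - n2) / (n1 + n2)
}
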