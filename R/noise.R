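# Temporal noise maps and the analytic shot-noise floor of SA imaging.

# coerce a stack argument (list of complex_field / list of matrices /
# 3-D array) to a list of complex matrices
as_field_list <- function(stack) {
  if (is.array(stack) && length(dim(stack)) == 3) {
    lapply(seq_len(dim(stack)[3]), function(i) stack[, , i])
  } else if (is.list(stack)) {
    lapply(stack, function(f) if (inherits(f, "complex_field")) f$values else f)
  } else {
    stop("unsupported stack type")
  }
}

#' Analytic shot-noise floor of frame-differential SA
#'
#' Evaluates the theoretical single-frame minimum detectable SA under
#' optical shot noise,
#'
#' `delta_SA = 2 * sqrt((4 - pi) * A_aperture / (2 * nu^2 * N_electron * A_sensor))`
#'
#' where `A_aperture` and `A_sensor` are the cropped and total pixel
#' areas in spatial-frequency space, `nu` is the fringe visibility and
#' `N_electron` the mean photoelectrons per pixel in the hologram. The
#' per-channel floor is this value times the channel's `alpha` (the SA
#' definition multiplies the normalized differential field by `alpha`),
#' which is the origin of the forward/backward sensitivity ratio
#' `1/alpha_bs` (about 14).
#'
#' @param n_electron Mean photoelectrons per pixel.
#' @param nu Fringe visibility in (0, 1].
#' @param a_aperture Aperture pixel count ([aperture_pixel_count()]).
#' @param a_sensor Total sensor pixel count.
#' @param alpha Channel background transmittance/reflectivity
#'   (default 1: the bare analytic floor).
#' @return The shot-noise SA floor (dimensionless SA units).
#' @export
#' @examples
#' shot_noise_floor(5e4, 0.25, aperture_pixel_count(115), 1024^2)
shot_noise_floor <- function(n_electron, nu, a_aperture, a_sensor,
                             alpha = 1) {
  stopifnot(n_electron > 0, a_aperture > 0, a_sensor > 0)
  if (nu <= 0 || nu > 1) stop("visibility must lie in (0, 1]")
  alpha * 2 * sqrt((4 - pi) * a_aperture / (2 * nu^2 * n_electron * a_sensor))
}

#' Fringe visibility from the hologram spectrum
#'
#' Crops the carrier (AC) lobe and the DC lobe of the hologram spectrum
#' with the configured aperture, inverse transforms each, and returns
#' `2 * mean|AC| / mean|DC|` — the modulation depth of that channel's
#' fringe relative to the frame's total DC intensity (the factor 2
#' restores the half of the modulation carried by the single AC lobe).
#'
#' @param frame A [hologram_frame()] or intensity matrix.
#' @param config An [optical_config()].
#' @param channel `"fs"`, `"bs"` or `"both"`.
#' @return Visibility estimate (named vector for `"both"`).
#' @export
estimate_visibility <- function(frame, config, channel = "both") {
  channel <- match.arg(channel, c("both", "fs", "bs"))
  intensity <- if (inherits(frame, "hologram_frame")) frame$dn else frame
  shape <- dim(intensity)
  validate_optical_config(config)   # rejects overlapping lobes
  spec <- fftshift2(fft2(intensity))
  mask0 <- disc_mask(shape, c(0, 0), config$aperture_radius_px)
  dc <- spec; dc[!mask0] <- 0
  dc_img <- ifft2(ifftshift2(dc))
  mean_dc <- mean(Mod(dc_img))
  one <- function(ch) {
    centre <- channel_carrier(config, ch) * shape
    m <- disc_mask(shape, centre, config$aperture_radius_px)
    ac <- spec; ac[!m] <- 0
    ac_img <- ifft2(ifftshift2(ac))
    2 * mean(Mod(ac_img)) / mean_dc
  }
  if (channel == "both") {
    c(fs = one("fs"), bs = one("bs"))
  } else {
    one(channel)
  }
}

#' Mean photoelectron count of a hologram
#'
#' @param frame A [hologram_frame()] (or DN matrix with `camera` given).
#' @param camera A [camera_model()]; taken from the frame if omitted.
#' @return Spatial mean of `dn * gain` (electrons). Warns when more than
#'   1% of pixels sit at the top of the DN range (saturation).
#' @export
estimate_n_electron <- function(frame, camera = NULL) {
  if (inherits(frame, "hologram_frame")) {
    camera <- frame$camera
    dn <- frame$dn
  } else {
    if (is.null(camera)) stop("camera must be supplied for a bare matrix")
    dn <- frame
  }
  sat <- mean(dn >= dn_max(camera))
  if (sat > 0.01) {
    warning(sprintf("%.1f%% of pixels are saturated; N_electron is biased",
                    100 * sat))
  }
  mean(dn) * camera_gain(camera)
}

#' Temporal SA noise of a no-sample stack
#'
#' Computes frame-to-frame differential SA images
#' (`alpha * |E_{t+1} - E_t| / |E_bg|`), takes their per-pixel temporal
#' standard deviation, and averages the STD map over a central evaluation
#' window. The scalar result is the single-frame minimum detectable SA.
#'
#' When the stack consists of hologram frames the fields are
#' demultiplexed first and the visibility, electron budget, and the
#' analytic floor (`alpha` times [shot_noise_floor()]) are estimated
#' from the data; with a bare complex-field stack those entries are `NA`
#' unless supplied.
#'
#' @param stack List of [hologram_frame()]s, list of [complex_field()]s,
#'   or a 3-D complex array (row, col, time). At least 2 frames.
#' @param config An [optical_config()] (required for hologram input).
#' @param channel `"fs"` or `"bs"` (hologram input).
#' @param alpha Channel `alpha`; from `config` if available, else 1.
#' @param e_bg Background field (complex matrix); the temporal mean of
#'   the stack when omitted.
#' @param window Evaluation window `c(rows, cols)` (default 200 x 200,
#'   clipped to the image), centred.
#' @return A `noise_report` list: `std_map`, `scalar_noise`, `nu`,
#'   `n_electron`, `theory_floor`, `window`, `n_differentials`.
#' @export
temporal_noise <- function(stack, config = NULL, channel = NULL,
                           alpha = NULL, e_bg = NULL,
                           window = c(200, 200)) {
  is_holo <- is.list(stack) && length(stack) > 0 &&
    inherits(stack[[1]], "hologram_frame")
  nu <- NA_real_; n_el <- NA_real_; theory <- NA_real_
  if (is_holo) {
    if (is.null(config) || is.null(channel)) {
      stop("hologram input needs config and channel")
    }
    channel <- match.arg(channel, c("fs", "bs"))
    if (is.null(alpha)) alpha <- channel_alpha(config, channel)
    nu <- estimate_visibility(stack[[1]], config, channel)
    n_el <- mean(vapply(stack, estimate_n_electron, numeric(1)))
    fields <- lapply(stack, function(f) demultiplex(f, config, channel)$values)
    a_ap <- aperture_pixel_count(config$aperture_radius_px)
    theory <- shot_noise_floor(n_el, nu, a_ap, prod(dim(stack[[1]]$dn)),
                               alpha = alpha)
  } else {
    fields <- as_field_list(stack)
    if (is.null(alpha)) {
      alpha <- if (!is.null(config) && !is.null(channel)) {
        channel_alpha(config, channel)
      } else 1
    }
  }
  n <- length(fields)
  if (n < 2) stop("need at least 2 frames")
  if (is.null(e_bg)) {
    e_bg <- Reduce(`+`, fields) / n
  } else if (inherits(e_bg, "complex_field")) {
    e_bg <- e_bg$values
  }
  bg_mod <- Mod(e_bg)

  # per-pixel temporal STD of the n-1 differential SA images (streaming
  # moments to avoid holding all differentials)
  s1 <- 0; s2 <- 0
  for (t in seq_len(n - 1)) {
    d <- alpha * Mod(fields[[t + 1]] - fields[[t]]) / bg_mod
    s1 <- s1 + d
    s2 <- s2 + d^2
  }
  m <- n - 1
  std_map <- sqrt(pmax(s2 / m - (s1 / m)^2, 0) * m / max(m - 1, 1))

  shape <- dim(std_map)
  w <- pmin(window, shape)
  r0 <- floor((shape[1] - w[1]) / 2)
  c0 <- floor((shape[2] - w[2]) / 2)
  win <- std_map[(r0 + 1):(r0 + w[1]), (c0 + 1):(c0 + w[2])]
  if (any(w < 1)) stop("evaluation window lies outside the image")

  structure(list(std_map = std_map,
                 scalar_noise = mean(win),
                 nu = unname(nu),
                 n_electron = n_el,
                 theory_floor = theory,
                 window = w,
                 n_differentials = m),
            class = "noise_report")
}

#' @export
print.noise_report <- function(x, ...) {
  cat(sprintf("<noise_report> scalar noise %.4g SA (%d differentials, window %d x %d)\n",
              x$scalar_noise, x$n_differentials, x$window[1], x$window[2]))
  if (is.finite(x$theory_floor)) {
    cat(sprintf("  nu %.3f, N_electron %.0f, analytic floor %.4g SA\n",
                x$nu, x$n_electron, x$theory_floor))
  }
  invisible(x)
}
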