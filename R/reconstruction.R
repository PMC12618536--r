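#' Scattering-field-amplitude image
#'
#' Nonnegative, dimensionless map of `alpha * |E_sample - E_bg| / |E_bg|`,
#' bounded by construction to `[0, 2]`. Pixels where the background
#' modulus is below the validity floor are `NA`.
#'
#' @param values Nonnegative numeric matrix (NA allowed for invalid
#'   pixels).
#' @param channel `"fs"` or `"bs"`.
#' @param provenance Named list recording how the image was formed
#'   (sample/background ids, alpha, refocus z, ...).
#' @return An object of class `sa_image`.
#' @export
sa_image <- function(values, channel, provenance = list()) {
  stopifnot(is.matrix(values))
  if (any(values < 0, na.rm = TRUE)) stop("SA values must be nonnegative")
  channel <- match.arg(channel, c("fs", "bs"))
  structure(list(values = values, channel = channel, provenance = provenance),
            class = "sa_image")
}

#' @export
print.sa_image <- function(x, ...) {
  cat(sprintf("<sa_image> %s, %d x %d px, max %.4g, mean %.4g\n",
              toupper(x$channel), nrow(x$values), ncol(x$values),
              max(x$values, na.rm = TRUE), mean(x$values, na.rm = TRUE)))
  invisible(x)
}

#' Demultiplex a hologram into its FS and BS complex amplitudes
#'
#' Fourier transforms the frame, translates the spectrum so the requested
#' carrier sits at the origin, zeroes everything outside the circular
#' spatial-frequency aperture, and inverse transforms. The carrier
#' translation is done by demodulating with the conjugate carrier plane
#' wave, so non-integer carrier frequencies are handled exactly. Both
#' channels come back on the same sample-plane grid.
#'
#' @param frame A [hologram_frame()] or a numeric intensity matrix.
#' @param config An [optical_config()].
#' @param channel `"fs"`, `"bs"`, or `"both"` (default).
#' @param use_electrons Convert digital numbers to electrons first
#'   (default `TRUE`; reconstruction is scale-invariant, this only fixes
#'   the units of the lobe amplitudes).
#' @return A [complex_field()], or a list `list(fs = , bs = )` when
#'   `channel = "both"`.
#' @export
demultiplex <- function(frame, config, channel = "both",
                        use_electrons = TRUE) {
  channel <- match.arg(channel, c("both", "fs", "bs"))
  intensity <- if (inherits(frame, "hologram_frame")) {
    if (use_electrons) frame$dn * camera_gain(frame$camera) else frame$dn
  } else {
    frame
  }
  stopifnot(identical(dim(intensity), as.integer(config$sensor_shape)) ||
            identical(dim(intensity), config$sensor_shape))
  shape <- dim(intensity)
  mask <- disc_mask(shape, c(0, 0), config$aperture_radius_px)

  one <- function(ch) {
    # the fringe term nu * Re(E * conj(R)) splits into E conj(R) at -f and
    # conj(E) R at +f; demodulating with R brings the E-bearing lobe to DC
    carrier <- channel_carrier(config, ch)
    demod <- intensity * plane_wave(shape, carrier)
    spec <- fftshift2(fft2(demod))
    in_lobe <- mean(Mod(spec[mask])^2)
    out_lobe <- stats::median(Mod(spec[!mask])^2)
    if ((is.finite(out_lobe) && in_lobe <= 4 * out_lobe) ||
        in_lobe <= 1e-12 * mean(Mod(spec)^2)) {
      warning(sprintf(
        "%s carrier lobe energy is close to the surrounding floor; check the carrier configuration",
        toupper(ch)))
    }
    spec[!mask] <- 0
    field_from_config(ifft2(ifftshift2(spec)), ch, config)
  }
  if (channel == "both") {
    list(fs = one("fs"), bs = one("bs"))
  } else {
    one(channel)
  }
}

#' Angular-spectrum propagation
#'
#' Propagates a complex field by `z` by multiplying its spectrum with
#' `exp(2i * pi * z * sqrt((n/lambda)^2 - fx^2 - fy^2))`. Evanescent
#' components (negative radicand) are zeroed; the energy of propagating
#' components is conserved exactly.
#'
#' @param field A [complex_field()].
#' @param z Propagation distance (um; positive towards the detector).
#' @param max_z Validity bound on `|z|` (um).
#' @return The propagated [complex_field()] with `z_offset` updated.
#' @export
propagate <- function(field, z, max_z = 1000) {
  stopifnot(inherits(field, "complex_field"))
  if (!is.finite(z) || abs(z) > max_z) {
    stop("propagation distance is non-finite or beyond the validity bound")
  }
  if (z == 0) return(field)
  shape <- dim(field$values)
  g <- freq_grid(shape)
  p <- field$sample_plane_pixel
  f2 <- (g$fr / p)^2 + (g$fc / p)^2
  rad <- (field$medium_index / field$wavelength)^2 - f2
  kernel <- matrix(0 + 0i, shape[1], shape[2])
  prop <- rad > 0
  kernel[prop] <- exp(2i * pi * z * sqrt(rad[prop]))
  spec <- fftshift2(fft2(field$values)) * kernel
  out <- field
  out$values <- ifft2(ifftshift2(spec))
  out$z_offset <- field$z_offset + z
  out
}

focus_metric <- function(values, metric) {
  a <- Mod(values)
  switch(metric,
    kurtosis = mean((a - mean(a))^4) / stats::var(as.numeric(a))^2,
    peak = max(a^2) / sum(a^2),
    gradient = {
      gx <- diff(a); gy <- t(diff(t(a)))
      (sum(gx^2) + sum(gy^2)) / sum(a^2)
    },
    tamura = sqrt(stats::sd(a) / mean(a)),
    stop("unknown focus metric")
  )
}

#' Autofocus by scanning angular-spectrum refocus distances
#'
#' Scans `z` over a grid and returns the distance maximizing a sharpness
#' metric of the differential field `|E_sample - E_bg|` (or of the field
#' itself if no background is given). The default metric is the amplitude
#' kurtosis of the differential field; `"peak"` (peak squared amplitude
#' fraction), `"gradient"` (gradient energy) and `"tamura"` are also
#' available.
#'
#' @param field A [complex_field()] (sample, or already-differential).
#' @param background Optional [complex_field()] subtracted before the
#'   metric is evaluated (subtraction is done after each propagation).
#' @param z_range Length-2 numeric, scan interval (um).
#' @param z_step Scan step (um); the range must contain at least 3 steps.
#' @param metric Focus metric name.
#' @return Best `z` (um), with attributes `metric_values`, `z_grid`,
#'   `metric`.
#' @export
autofocus <- function(field, background = NULL, z_range = c(-10, 10),
                      z_step = 0.5, metric = "kurtosis") {
  zs <- seq(z_range[1], z_range[2], by = z_step)
  if (length(zs) < 3) stop("z_range must contain at least 3 steps")
  vals <- vapply(zs, function(z) {
    f <- propagate(field, z)
    v <- if (is.null(background)) f$values else
      f$values - propagate(background, z)$values
    focus_metric(v, metric)
  }, numeric(1))
  if (any(!is.finite(vals)) ||
      max(vals) - min(vals) < 1e-9 * max(abs(vals), 1e-300)) {
    warning("focus metric is flat (no scatterer?); returning z = 0")
    z_best <- 0
  } else {
    z_best <- zs[which.max(vals)]
  }
  structure(z_best, metric_values = vals, z_grid = zs, metric = metric)
}

#' Automatic sample-free mask
#'
#' Pixels whose `|ratio - 1|` is below the given quantile — the flattest
#' fraction of the normalized field, assumed free of sample structure.
#'
#' @param ratio A [complex_field()] holding `E_sample / E_bg`.
#' @param quantile Fraction of pixels to keep (default 0.2).
#' @return Logical matrix.
#' @export
sample_free_mask <- function(ratio, quantile = 0.2) {
  dev <- Mod(ratio$values - 1)
  dev <= stats::quantile(dev, quantile)
}

#' Remove interferometric phase drift
#'
#' Fits `a + b*row + c*col` to the wrapped phase of the normalized field
#' over the sample-free mask by least squares and divides the fitted
#' phasor out. Assumes the drift is small enough that the phase over the
#' mask does not wrap (the small-drift regime between consecutive
#' acquisitions); no unwrapping is attempted.
#'
#' @param ratio A [complex_field()] holding `E_sample / E_bg`.
#' @param sample_free_mask Logical matrix marking sample-free pixels;
#'   must cover at least `min_coverage` of the image and not be collinear.
#' @param min_coverage Minimum mask fraction (default 0.01).
#' @return The corrected [complex_field()], with attribute `drift_coef`
#'   `c(a, b, c)` (radians, radians/px, radians/px).
#' @export
correct_phase_drift <- function(ratio, sample_free_mask,
                                min_coverage = 0.01) {
  stopifnot(inherits(ratio, "complex_field"),
            identical(dim(sample_free_mask), dim(ratio$values)))
  n_mask <- sum(sample_free_mask)
  if (n_mask < min_coverage * length(sample_free_mask)) {
    stop("sample-free mask covers less than ", 100 * min_coverage,
         "% of the image")
  }
  shape <- dim(ratio$values)
  rows <- matrix(seq_len(shape[1]) - 1, shape[1], shape[2])
  cols <- matrix(seq_len(shape[2]) - 1, shape[1], shape[2], byrow = TRUE)
  X <- cbind(1, rows[sample_free_mask], cols[sample_free_mask])
  if (qr(X)$rank < 3) stop("sample-free mask is collinear; cannot fit a plane")
  phi <- Arg(ratio$values)[sample_free_mask]
  coef <- stats::.lm.fit(X, phi)$coefficients
  plane <- coef[1] + coef[2] * rows + coef[3] * cols
  out <- ratio
  out$values <- ratio$values * exp(-1i * plane)
  attr(out, "drift_coef") <- stats::setNames(coef, c("a", "b", "c"))
  out
}

#' Scattering-field amplitude from sample and background fields
#'
#' Evaluates `SA = alpha * |E_sample - E_bg| / |E_bg|` pointwise. Pixels
#' where `|E_bg|` falls below `floor_frac` times its median are flagged
#' invalid (`NA`). Values above 2 indicate an `alpha` misconfiguration
#' and raise a warning (they are reported, not clipped).
#'
#' @param e_sample,e_bg [complex_field()] objects on the same grid and
#'   channel.
#' @param alpha Background transmittance/reflectivity of the channel; if
#'   `NULL`, taken as 1 for FS and 0.07 for BS.
#' @param floor_frac Validity floor for `|E_bg|`, as a fraction of its
#'   median (default 1e-6).
#' @return An [sa_image()].
#' @export
compute_sa <- function(e_sample, e_bg, alpha = NULL, floor_frac = 1e-6) {
  stopifnot_same_grid(e_sample, e_bg)
  if (is.null(alpha)) alpha <- if (e_sample$channel == "fs") 1 else 0.07
  bg_mod <- Mod(e_bg$values)
  floor <- floor_frac * stats::median(bg_mod)
  sa <- alpha * Mod(e_sample$values - e_bg$values) / bg_mod
  invalid <- bg_mod < floor
  sa[invalid] <- NA_real_
  if (any(sa > 2 + 1e-9, na.rm = TRUE)) {
    warning(sprintf(
      "SA exceeds 2 at %d pixels (max %.3g); check the alpha configuration",
      sum(sa > 2 + 1e-9, na.rm = TRUE), max(sa, na.rm = TRUE)))
  }
  sa_image(sa, e_sample$channel,
           provenance = list(alpha = alpha, refocus_z = e_sample$z_offset,
                             n_invalid = sum(invalid)))
}

#' Full single-frame SA reconstruction
#'
#' The pipeline route from a pair of holograms (sample and background) to
#' an SA image for one channel: demultiplex both, refocus, normalize the
#' sample field by the spatial mean of its complex ratio to the
#' background (removing laser-power and global path-length fluctuation),
#' fit and remove the residual phase drift over a sample-free mask, and
#' form the SA map.
#'
#' @param frame_sample,frame_bg [hologram_frame()] objects.
#' @param config An [optical_config()].
#' @param channel `"fs"` or `"bs"`.
#' @param refocus `"none"`, `"auto"`, or a numeric z (um).
#' @param drift_correct Fit/remove the residual phase plane (default
#'   `TRUE`).
#' @param mask Optional logical sample-free mask; automatic
#'   ([sample_free_mask()]) if `NULL`.
#' @return An [sa_image()].
#' @export
reconstruct_sa <- function(frame_sample, frame_bg, config, channel,
                           refocus = "none", drift_correct = TRUE,
                           mask = NULL) {
  channel <- match.arg(channel, c("fs", "bs"))
  es <- demultiplex(frame_sample, config, channel)
  eb <- demultiplex(frame_bg, config, channel)
  if (identical(refocus, "auto")) {
    z <- as.numeric(autofocus(es, background = eb))
  } else if (is.numeric(refocus)) {
    z <- refocus
  } else {
    z <- 0
  }
  if (z != 0) {
    es <- propagate(es, z)
    eb <- propagate(eb, z)
  }
  ratio <- es
  ratio$values <- es$values / eb$values
  ratio$values <- ratio$values / mean(ratio$values)   # per-frame normalization
  if (drift_correct) {
    if (is.null(mask)) mask <- sample_free_mask(ratio)
    ratio <- correct_phase_drift(ratio, mask)
  }
  alpha <- channel_alpha(config, channel)
  sa <- alpha * Mod(ratio$values - 1)
  if (any(sa > 2 + 1e-9, na.rm = TRUE)) {
    warning("SA exceeds 2; check the alpha configuration")
  }
  sa_image(sa, channel,
           provenance = list(sample_id = frame_sample$timestamp_index,
                             background_id = frame_bg$timestamp_index,
                             alpha = alpha, refocus_z = z))
}
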