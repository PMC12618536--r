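# Temporal-frequency-band fluctuation maps from SA time series.

#' Per-pixel temporal band-limited fluctuation map
#'
#' Container for the per-pixel temporal standard deviation of the
#' band-pass-filtered normalized field, in SA-like units.
#'
#' @param values Nonnegative numeric matrix.
#' @param band `c(f_lo, f_hi)` in Hz.
#' @param channel `"fs"` or `"bs"`.
#' @param fps Frame rate of the source series.
#' @param n_frames Number of frames the map was computed from.
#' @return An object of class `dynamic_map`.
#' @export
dynamic_map <- function(values, band, channel, fps, n_frames) {
  stopifnot(is.matrix(values), band[1] > 0, band[1] < band[2],
            band[2] <= fps / 2)
  if (any(values < 0, na.rm = TRUE)) stop("dynamic map values must be >= 0")
  channel <- match.arg(channel, c("fs", "bs"))
  structure(list(values = values, band = band, channel = channel,
                 fps = fps, n_frames = n_frames),
            class = "dynamic_map")
}

#' @export
print.dynamic_map <- function(x, ...) {
  cat(sprintf("<dynamic_map> %s %g-%g Hz, %d frames @ %g fps, mean %.4g\n",
              toupper(x$channel), x$band[1], x$band[2], x$n_frames, x$fps,
              mean(x$values, na.rm = TRUE)))
  invisible(x)
}

#' Per-frame normalization of a complex field stack
#'
#' Removes spatially uniform frame-to-frame variation (laser intensity
#' noise, global path-length difference): each frame's amplitude is
#' divided by its spatial mean amplitude, and its phase is reduced by its
#' spatial mean phase.
#'
#' @param field_stack List of fields / matrices or a 3-D complex array.
#' @return List of normalized complex matrices.
#' @export
normalize_frames <- function(field_stack) {
  fields <- as_field_list(field_stack)
  if (length(fields) == 0) stop("empty stack")
  lapply(fields, function(f) {
    a <- Mod(f)
    ma <- mean(a)
    if (ma == 0) stop("zero-mean amplitude frame cannot be normalized")
    (a / ma) * exp(1i * (Arg(f) - mean(Arg(f))))
  })
}

# mirror-padded boxcar mean with an odd kernel
box_mean <- function(x, kernel) {
  k2 <- (kernel - 1) / 2
  nr <- nrow(x); nc <- ncol(x)
  ridx <- c(rev(seq_len(k2) + 1), seq_len(nr), nr - seq_len(k2))
  cidx <- c(rev(seq_len(k2) + 1), seq_len(nc), nc - seq_len(k2))
  xp <- x[ridx, cidx]
  # separable two-pass mean: filter along rows, then along columns
  rowpass <- stats::filter(xp, rep(1 / kernel, kernel), sides = 2)
  rowpass <- matrix(rowpass, nrow(xp))[(k2 + 1):(k2 + nr), , drop = FALSE]
  colpass <- stats::filter(t(rowpass), rep(1 / kernel, kernel), sides = 2)
  t(matrix(colpass, ncol(rowpass)))[, (k2 + 1):(k2 + nc), drop = FALSE]
}

#' Subtract the local spatial mean from every frame
#'
#' Removes spatially smooth, globally drifting background structure by
#' subtracting, at each pixel, the mean over its centred `kernel x
#' kernel` neighbourhood (mirror padding at the borders). Applied to both
#' quadratures of a complex stack.
#'
#' @param field_stack List of complex/numeric matrices or a 3-D array.
#' @param kernel Odd kernel size >= 3 (default 11).
#' @return List of matrices with the local mean removed.
#' @export
subtract_local_mean <- function(field_stack, kernel = 11) {
  stopifnot(kernel >= 3, kernel %% 2 == 1)
  fields <- as_field_list(field_stack)
  if (any(dim(fields[[1]]) < kernel)) {
    stop("kernel larger than the image")
  }
  lapply(fields, function(f) {
    if (is.complex(f)) {
      (Re(f) - box_mean(Re(f), kernel)) +
        1i * (Im(f) - box_mean(Im(f), kernel))
    } else {
      f - box_mean(f, kernel)
    }
  })
}

#' Band-limited temporal fluctuation map
#'
#' Per pixel: remove the temporal mean, apply a zero-phase brick-wall
#' discrete-Fourier band selection (`f_lo <= |f| <= f_hi`) to each
#' quadrature of the complex time series, and report
#' `alpha * sqrt(STD_re^2 + STD_im^2)` — the square root of the
#' band-limited power, in SA-like units when the input is the normalized
#' field ratio `E_t / E_bg`. Population standard deviations are used, so
#' disjoint bands are exactly additive in power (Parseval).
#'
#' @param field_stack List of complex/numeric matrices or 3-D array; at
#'   least `2 * fps / f_lo` frames (two periods of the slowest
#'   component).
#' @param f_lo,f_hi Band edges (Hz), `0 < f_lo < f_hi <= fps/2`.
#' @param fps Frame rate (Hz).
#' @param alpha Channel `alpha` scale (default 1).
#' @param channel Channel tag for the output map.
#' @param component `"complex"` (both quadratures, default),
#'   `"amplitude"`, or `"phase"`.
#' @return A [dynamic_map()].
#' @export
bandpass_std_map <- function(field_stack, f_lo, f_hi, fps, alpha = 1,
                             channel = "fs",
                             component = c("complex", "amplitude", "phase")) {
  component <- match.arg(component)
  if (f_lo <= 0 || f_hi > fps / 2 || f_lo >= f_hi) {
    stop("band must satisfy 0 < f_lo < f_hi <= fps/2")
  }
  fields <- as_field_list(field_stack)
  T <- length(fields)
  if (T < 2 * fps / f_lo) {
    stop("need at least 2 * fps / f_lo frames for the slowest component")
  }
  shape <- dim(fields[[1]])
  npix <- prod(shape)
  series <- switch(component,
    complex = NULL,
    amplitude = lapply(fields, Mod),
    phase = lapply(fields, Arg))

  band_var <- function(mat) {   # mat: T x npix real
    mat <- sweep(mat, 2, colMeans(mat))
    X <- stats::mvfft(mat)
    f <- pmin(seq_len(T) - 1, T - (seq_len(T) - 1)) * fps / T
    keep <- f >= f_lo & f <= f_hi
    X[!keep, ] <- 0
    xf <- Re(stats::mvfft(X, inverse = TRUE)) / T
    colMeans(xf^2)          # population variance of the band component
  }
  to_mat <- function(lst) t(vapply(lst, as.numeric, numeric(npix)))

  if (component == "complex") {
    v <- band_var(to_mat(lapply(fields, Re))) +
      band_var(to_mat(lapply(fields, Im)))
  } else {
    v <- band_var(to_mat(series))
  }
  dynamic_map(matrix(alpha * sqrt(v), shape[1], shape[2]),
              band = c(f_lo, f_hi), channel = channel, fps = fps,
              n_frames = T)
}

#' Mean dynamic signal of a region over a time-lapse
#'
#' @param maps List of [dynamic_map()]s (one per time point, consistent
#'   shapes).
#' @param roi Logical matrix (region mask) or 2-column index matrix.
#' @param times Optional numeric time stamps (e.g. minutes); defaults to
#'   `seq_along(maps) - 1`.
#' @return data.frame with columns `time`, `value` (spatial mean over the
#'   ROI per time point).
#' @export
region_timecourse <- function(maps, roi, times = NULL) {
  stopifnot(length(maps) >= 1)
  shape <- dim(maps[[1]]$values)
  if (is.matrix(roi) && ncol(roi) == 2 && !is.logical(roi)) {
    m <- matrix(FALSE, shape[1], shape[2])
    m[roi] <- TRUE
    roi <- m
  }
  stopifnot(is.logical(roi), identical(dim(roi), shape))
  if (!any(roi)) stop("empty ROI")
  vals <- vapply(maps, function(mp) {
    stopifnot(identical(dim(mp$values), shape))
    mean(mp$values[roi], na.rm = TRUE)
  }, numeric(1))
  data.frame(time = if (is.null(times)) seq_along(maps) - 1 else times,
             value = vals)
}
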