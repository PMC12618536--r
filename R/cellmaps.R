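# Phase-derived dry-mass maps and a minimal fringe-count height estimator.

#' Dry-mass surface density from a quantitative phase image
#'
#' Converts an unwrapped optical phase map to depth-integrated dry-mass
#' surface density via the refraction increment:
#' `density = wavelength * phase / (2 * pi * gamma)` (pg/um^2 with the
#' wavelength in um and `gamma` in mL/g = um^3/pg).
#'
#' @param phase Phase map (radians, unwrapped; non-finite pixels are
#'   masked out).
#' @param wavelength Vacuum wavelength (um).
#' @param gamma Refraction increment (mL/g; default 0.18, the standard
#'   protein value).
#' @param pixel_area Sample-plane pixel area (um^2).
#' @param mask Optional logical cell mask; densities outside it are kept
#'   but excluded from the total.
#' @return An object of class `dry_mass_map`: `surface_density`
#'   (pg/um^2), `total` (pg over the mask), `mask`, `pixel_area`,
#'   `refraction_increment`.
#' @export
#' @examples
#' m <- dry_mass_map(matrix(1, 10, 10), 0.515, 0.18, pixel_area = 1)
#' m$total  # 100 * 0.515 / (2 * pi * 0.18)
dry_mass_map <- function(phase, wavelength, gamma = 0.18, pixel_area,
                         mask = NULL) {
  stopifnot(is.matrix(phase), wavelength > 0, gamma > 0, pixel_area > 0)
  density <- wavelength * phase / (2 * pi * gamma)
  bad <- !is.finite(density)
  density[bad] <- NA_real_
  if (is.null(mask)) mask <- !bad else mask <- mask & !bad
  structure(list(surface_density = density,
                 total = sum(density[mask]) * pixel_area,
                 mask = mask, pixel_area = pixel_area,
                 refraction_increment = gamma,
                 wavelength = wavelength),
            class = "dry_mass_map")
}

#' @export
print.dry_mass_map <- function(x, ...) {
  cat(sprintf("<dry_mass_map> %d x %d px, total %.3f pg over %d masked px\n",
              nrow(x$surface_density), ncol(x$surface_density), x$total,
              sum(x$mask)))
  invisible(x)
}

#' Total dry mass over a time-lapse of phase images
#'
#' @param phase_stack List of phase matrices (radians) or a 3-D array.
#' @param mask Logical cell mask (single mask, or list per time point).
#' @param wavelength Vacuum wavelength (um).
#' @param gamma Refraction increment (mL/g).
#' @param pixel_area Pixel area (um^2).
#' @param times Optional time stamps.
#' @return data.frame with columns `time`, `mass_pg`.
#' @export
total_dry_mass_series <- function(phase_stack, mask, wavelength,
                                  gamma = 0.18, pixel_area, times = NULL) {
  stack <- if (is.array(phase_stack) && length(dim(phase_stack)) == 3) {
    lapply(seq_len(dim(phase_stack)[3]), function(i) phase_stack[, , i])
  } else {
    phase_stack
  }
  if (length(stack) == 0) {
    return(data.frame(time = numeric(), mass_pg = numeric()))
  }
  masks <- if (is.list(mask)) mask else rep(list(mask), length(stack))
  stopifnot(length(masks) == length(stack))
  if (!any(masks[[1]])) stop("empty mask")
  mass <- mapply(function(ph, mk) {
    dry_mass_map(ph, wavelength, gamma, pixel_area, mask = mk)$total
  }, stack, masks)
  data.frame(time = if (is.null(times)) seq_along(stack) - 1 else times,
             mass_pg = mass)
}

#' Cell height from interference fringe counting
#'
#' Minimal estimator of the height change along a backscattering SA
#' profile showing thin-film (Newton-ring-like) fringes: counts fringe
#' periods via zero crossings of the mean-centred profile and converts
#' each full fringe to a height increment of
#' `wavelength / (2 * n_medium)`.
#'
#' @param profile Numeric vector (SA along a line crossing the fringes).
#' @param wavelength Illumination wavelength; the height comes back in
#'   the same unit.
#' @param n_medium Refractive index of the gap medium.
#' @param smooth Width of the moving-average pre-smoothing (odd; 1 = no
#'   smoothing).
#' @return Estimated cumulative height (same unit as `wavelength`), with
#'   attributes `n_fringes` and `fringe_positions` (crossing indices).
#'   Returns 0 with a warning when no oscillation is detectable.
#' @export
#' @examples
#' s <- seq(0, 2 * pi, length.out = 200)
#' height_from_fringes(cos(s), 0.515, 1.33)  # one fringe: ~0.1936 um
height_from_fringes <- function(profile, wavelength, n_medium, smooth = 5) {
  stopifnot(length(profile) >= 5, n_medium > 0)
  x <- as.numeric(profile)
  if (smooth > 1) {
    sm <- stats::filter(x, rep(1 / smooth, smooth), sides = 2)
    x <- as.numeric(sm)
    x <- x[!is.na(x)]
  }
  x <- x - mean(x)
  if (max(abs(x)) == 0) {
    warning("flat profile: no fringes detected")
    return(structure(0, n_fringes = 0, fringe_positions = integer()))
  }
  sgn <- sign(x)
  sgn[sgn == 0] <- 1
  crossings <- which(diff(sgn) != 0)
  n_fringes <- floor(length(crossings) / 2)
  if (n_fringes == 0) {
    warning("no complete fringe found in the profile")
    return(structure(0, n_fringes = 0, fringe_positions = crossings))
  }
  structure(n_fringes * wavelength / (2 * n_medium),
            n_fringes = n_fringes, fringe_positions = crossings)
}
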