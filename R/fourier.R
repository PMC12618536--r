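# Shared Fourier helpers. Images are (row, col) from the top-left; spatial
# frequencies live on the centred (fftshifted) grid in cycles/pixel.

fft2 <- function(x) stats::fft(x)
ifft2 <- function(x) stats::fft(x, inverse = TRUE) / length(x)

fftshift2 <- function(x) {
  n <- dim(x)
  x[c(seq(floor(n[1] / 2) + 1, n[1]), seq_len(floor(n[1] / 2))),
    c(seq(floor(n[2] / 2) + 1, n[2]), seq_len(floor(n[2] / 2)))]
}

ifftshift2 <- function(x) {
  n <- dim(x)
  x[c(seq(ceiling(n[1] / 2) + 1, n[1]), seq_len(ceiling(n[1] / 2))),
    c(seq(ceiling(n[2] / 2) + 1, n[2]), seq_len(ceiling(n[2] / 2)))]
}

# centred frequency axis in cycles/sample for n samples
freq_axis <- function(n) {
  (seq_len(n) - 1 - floor(n / 2)) / n
}

# list(fr, fc): matrices of row/col frequency (cycles/pixel), centred grid
freq_grid <- function(shape) {
  fr <- freq_axis(shape[1])
  fc <- freq_axis(shape[2])
  list(fr = matrix(fr, shape[1], shape[2]),
       fc = matrix(fc, shape[1], shape[2], byrow = TRUE))
}

# boolean disc |f - centre| <= radius on the centred frequency-pixel grid;
# centre in frequency pixels relative to DC
disc_mask <- function(shape, centre_px = c(0, 0), radius_px) {
  g <- freq_grid(shape)
  pr <- g$fr * shape[1]
  pc <- g$fc * shape[2]
  (pr - centre_px[1])^2 + (pc - centre_px[2])^2 <= radius_px^2
}

# complex plane wave exp(2i*pi*(f_r*r + f_c*c)) with f in cycles/pixel,
# pixel indices starting at 0
plane_wave <- function(shape, f) {
  r <- matrix(seq_len(shape[1]) - 1, shape[1], shape[2])
  cc <- matrix(seq_len(shape[2]) - 1, shape[1], shape[2], byrow = TRUE)
  exp(2i * pi * (f[1] * r + f[2] * cc))
}
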