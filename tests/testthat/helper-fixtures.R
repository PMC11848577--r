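# Shared fixtures: analytic fields, movies and small phantoms built in code.

# complex plane shear wave: displacement along `component`, propagating
# along the other axis, wavelength lambda_px pixels, amplitude amp_px
# pixels (stored in micrometres)
plane_wave_field <- function(nr, nc, h = 30, lambda_px = 40,
                             amp_px = 0.08, frequency = 1000,
                             component = "y", alpha_px = 0) {
  ax <- if (component == "y") {
    matrix(rep(seq_len(nc), each = nr), nr, nc)   # propagate along x
  } else {
    matrix(rep(seq_len(nr), times = nc), nr, nc)  # propagate along y
  }
  u <- amp_px * h * exp(-1i * 2 * pi / lambda_px * ax - alpha_px * ax)
  zero <- matrix(0 + 0i, nr, nc)
  if (component == "y") {
    complex_wave_field(x = zero, y = u, frequency = frequency, pixel_size = h)
  } else {
    complex_wave_field(x = u, y = zero, frequency = frequency, pixel_size = h)
  }
}

# dense-texture test image
test_speckle <- function(nr = 120, nc = nr, seed = 7, density = 0.2,
                         fwhm = 2) {
  make_speckle_image(c(nr, nc), round(density * nr * nc), fwhm, seed = seed)
}

# encode a field into a movie under the standard strobe (one frequency)
test_movie <- function(field, image = NULL, amplitude_scale = 0.1,
                       noise_fraction = 0, seed = 17, frame_rate = 4500,
                       quantize = TRUE) {
  d <- dim(field$components[[1]])
  if (is.null(image)) image <- test_speckle(d[1], d[2])
  sch <- build_schedule(field$frequency, frame_rate = frame_rate)
  encode_motion(image, field, sch, amplitude_scale = amplitude_scale,
                noise_fraction = noise_fraction, seed = seed,
                quantize = quantize)
}

# complex correlation and RMS-amplitude ratio between decoded and truth
# over an interior margin
field_fidelity <- function(decoded, truth, margin = 15) {
  d <- dim(truth$components[[1]])
  ri <- (margin + 1):(d[1] - margin); ci <- (margin + 1):(d[2] - margin)
  num <- 0 + 0i; pt <- 0; pd <- 0
  for (comp in names(truth$components)) {
    tu <- truth$components[[comp]][ri, ci]
    du <- decoded$components[[comp]][ri, ci]
    num <- num + sum(Conj(tu) * du)
    pt <- pt + sum(Mod(tu)^2); pd <- pd + sum(Mod(du)^2)
  }
  list(corr = Mod(num) / sqrt(pt * pd), amp_ratio = sqrt(pd / pt))
}

# exact translation operator (periodic): the ideal fixture for
# registration accuracy tests
fourier_shift <- function(m, dy, dx) {
  nr <- nrow(m); nc <- ncol(m)
  fr <- c(0:(nr %/% 2), -((nr - nr %/% 2 - 1):1)) / nr
  fc <- c(0:(nc %/% 2), -((nc - nc %/% 2 - 1):1)) / nc
  Re(stats::fft(stats::fft(m) * exp(-2i * pi * outer(fr * dy, fc * dx, "+")),
                inverse = TRUE)) / (nr * nc)
}
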