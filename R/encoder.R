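#' Synthetic speckle / feature image
#'
#' Generates the texture that motion is encoded into: a unit-intensity
#' background plus `n_features` Gaussian bumps of a given full width at
#' half maximum placed at uniformly random sub-pixel positions.
#' Reproducible for a fixed seed.
#'
#' @param shape `c(rows, cols)` in pixels.
#' @param n_features number of Gaussian features (>= 0).
#' @param feature_fwhm full width at half maximum of each feature (pixels).
#' @param seed integer seed, or `NULL`.
#' @param feature_amplitude peak amplitude of each feature on top of the
#'   unit background.
#'
#' @return A numeric matrix of intensities (>= 0).
#' @export
make_speckle_image <- function(shape, n_features, feature_fwhm = 2,
                               seed = NULL, feature_amplitude = 1) {
  stopifnot(length(shape) == 2L, n_features >= 0, feature_fwhm > 0)
  nr <- as.integer(shape[1]); nc <- as.integer(shape[2])
  img <- matrix(1, nr, nc)
  if (n_features == 0) return(img)
  pos <- with_seed(seed, cbind(stats::runif(n_features, 1, nr),
                               stats::runif(n_features, 1, nc)))
  sig <- feature_fwhm / (2 * sqrt(2 * log(2)))
  half <- max(1L, ceiling(4 * sig))
  for (k in seq_len(n_features)) {
    r0 <- pos[k, 1]; c0 <- pos[k, 2]
    ri <- max(1L, floor(r0 - half)):min(nr, ceiling(r0 + half))
    ci <- max(1L, floor(c0 - half)):min(nc, ceiling(c0 + half))
    bump <- feature_amplitude *
      exp(-(outer((ri - r0)^2, (ci - c0)^2, "+")) / (2 * sig^2))
    img[ri, ci] <- img[ri, ci] + bump
  }
  img
}

#' Stroboscopic acquisition schedule
#'
#' Builds the per-frequency frame capture times and vibration phases for a
#' camera running at a fixed frame rate while the sample vibrates at each
#' drive frequency in turn. Frames are consecutive camera frames starting
#' after `skip_cycles` vibration cycles (transient settling); the recorded
#' exact phases `phi_j = 2 pi f t_j mod 2 pi` are stored so that the
#' decoder never needs to assume uniform phase spacing. When
#' `frame_rate < 2 f` the sampling is stroboscopic (sub-Nyquist): the wave
#' appears aliased but at precisely known phases.
#'
#' @param frequencies drive frequencies (Hz).
#' @param frame_rate camera frame rate (frames/s).
#' @param frames_per_cycle nominal frames per vibration cycle (sets the
#'   number of frames together with `n_cycles`).
#' @param n_cycles number of sampled vibration cycles.
#' @param skip_cycles vibration cycles skipped before the first frame.
#'
#' @return An object of class `acquisition_schedule`: a list with
#'   `frequencies`, `frame_rate`, `frames_per_cycle`, `n_cycles`,
#'   `skip_cycles` and `per_frequency` (a list of `list(frequency, times,
#'   phases)`).
#' @export
build_schedule <- function(frequencies, frame_rate = 4500,
                           frames_per_cycle = 8L, n_cycles = 3L,
                           skip_cycles = 4L) {
  stopifnot(all(frequencies > 0), frame_rate > 0, frames_per_cycle >= 3L,
            n_cycles >= 1L, skip_cycles >= 0L)
  nf <- as.integer(frames_per_cycle) * as.integer(n_cycles)
  per <- lapply(frequencies, function(f) {
    t0 <- ceiling(skip_cycles / f * frame_rate - 1e-9) / frame_rate
    times <- t0 + (seq_len(nf) - 1L) / frame_rate
    phases <- (2 * pi * f * times) %% (2 * pi)
    ndistinct <- length(unique(round(phases / (2 * pi) * 1e9)))
    if (ndistinct < 3L)
      stop(sprintf(
        "degenerate stroboscopic schedule at %g Hz: only %d distinct phase(s) at %g fps",
        f, ndistinct, frame_rate))
    list(frequency = f, times = times, phases = phases)
  })
  structure(
    list(frequencies = as.numeric(frequencies), frame_rate = frame_rate,
         frames_per_cycle = as.integer(frames_per_cycle),
         n_cycles = as.integer(n_cycles),
         skip_cycles = as.integer(skip_cycles), per_frequency = per),
    class = "acquisition_schedule"
  )
}

#' @export
print.acquisition_schedule <- function(x, ...) {
  cat(sprintf(
    "<acquisition_schedule> %d frequencies (%g-%g Hz), %g fps, %d frames/cycle x %d cycles, skip %d\n",
    length(x$frequencies), min(x$frequencies), max(x$frequencies),
    x$frame_rate, x$frames_per_cycle, x$n_cycles, x$skip_cycles))
  invisible(x)
}

schedule_entry <- function(schedule, frequency) {
  stopifnot(inherits(schedule, "acquisition_schedule"))
  i <- which(abs(schedule$frequencies - frequency) < 1e-9)
  if (length(i) != 1L)
    stop(sprintf("frequency %g Hz is not part of the schedule", frequency))
  schedule$per_frequency[[i]]
}

#' Condition numbers of the per-frequency harmonic design
#'
#' For each frequency, the 2x2 normal matrix of the harmonic regressors
#' `(cos phi_j, -sin phi_j)` determines whether the complex harmonic
#' coefficient is identifiable from the recorded (possibly aliased)
#' phases. Values near 1 indicate uniformly spread phases.
#'
#' @param schedule an `acquisition_schedule`.
#' @return Named numeric vector of condition numbers.
#' @export
schedule_condition <- function(schedule) {
  stopifnot(inherits(schedule, "acquisition_schedule"))
  out <- vapply(schedule$per_frequency, function(e) {
    C <- cbind(cos(e$phases), -sin(e$phases))
    kappa(crossprod(C), exact = TRUE)
  }, 0)
  names(out) <- schedule$frequencies
  out
}

#' Image series container
#'
#' Ordered grayscale frames tied to one frequency of an acquisition
#' schedule.
#'
#' @param frames 3-D array `[rows, cols, frame]`, finite and >= 0.
#' @param frequency drive frequency (Hz).
#' @param phases recorded vibration phases per frame (radians).
#' @param times capture times (s), optional.
#' @param pixel_size pixel edge length (micrometres).
#' @param exposure exposure tag (arbitrary units), default 1.
#'
#' @return An object of class `image_series`.
#' @export
image_series <- function(frames, frequency, phases, times = NULL,
                         pixel_size, exposure = 1) {
  stopifnot(length(dim(frames)) == 3L, dim(frames)[3] == length(phases),
            frequency > 0, pixel_size > 0)
  if (!all(is.finite(frames)) || any(frames < 0))
    stop("frames must be finite and non-negative")
  structure(
    list(frames = frames, frequency = as.numeric(frequency),
         phases = as.numeric(phases), times = times,
         pixel_size = as.numeric(pixel_size), exposure = exposure),
    class = "image_series"
  )
}

#' @export
print.image_series <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<image_series> %d frames of %d x %d px, f = %g Hz, h = %.4g um\n",
              d[3], d[1], d[2], x$frequency, x$pixel_size))
  invisible(x)
}

#' Encode a harmonic displacement field into a grayscale movie
#'
#' Rescales the field so that the largest instantaneous displacement
#' magnitude over all frames and pixels equals `amplitude_scale` times the
#' pixel size, then renders each scheduled frame by resampling the input
#' image at `r - u(r, t_j)` (pull-back warp) with bicubic sub-pixel
#' interpolation. Optionally adds white Gaussian noise to the displacement
#' time series before warping (noise on the motion, not on the image
#' intensities), and optionally quantizes frame intensities to 16-bit
#' levels so that TIFF round trips are exact.
#'
#' @param image 2-D intensity image (same shape as the field).
#' @param field a [complex_wave_field] with one or two components
#'   (micrometres).
#' @param schedule an `acquisition_schedule` containing the field's
#'   frequency, or a numeric vector of phases (radians).
#' @param amplitude_scale peak displacement as a fraction of the pixel
#'   size (default 0.1).
#' @param noise_fraction white-noise standard deviation as a fraction of
#'   the RMS of each component's clean displacement series (default 0).
#' @param seed seed for the displacement noise.
#' @param boundary `"mirror"` (default) or `"periodic"` interpolation
#'   boundary.
#' @param max_displacement_px sanity bound on the encoded displacement
#'   (pixels); exceeding it is an error.
#' @param quantize quantize intensities to `2^bit_depth` levels.
#' @param bit_depth bit depth used when `quantize = TRUE`.
#'
#' @return An [image_series]; attribute `"amplitude_um"` records the peak
#'   displacement in micrometres after rescaling.
#' @export
encode_motion <- function(image, field, schedule, amplitude_scale = 0.1,
                          noise_fraction = 0, seed = NULL,
                          boundary = "mirror", max_displacement_px = 2,
                          quantize = TRUE, bit_depth = 16L) {
  stopifnot(inherits(field, "complex_wave_field"), amplitude_scale > 0)
  image <- as.matrix(image)
  d <- dim(field$components[[1]])
  if (!all(dim(image) == d))
    stop("image and field shapes do not match")
  if (inherits(schedule, "acquisition_schedule")) {
    entry <- schedule_entry(schedule, field$frequency)
    phases <- entry$phases; times <- entry$times
  } else {
    phases <- as.numeric(schedule); times <- NULL
  }
  h <- field$pixel_size
  nf <- length(phases)

  # per-frame displacement stacks (um), from the harmonic ansatz
  comps <- field$components
  ux <- if (!is.null(comps$x)) comps$x else matrix(0, d[1], d[2])
  uy <- if (!is.null(comps$y)) comps$y else matrix(0, d[1], d[2])
  sx <- array(0, c(d, nf)); sy <- array(0, c(d, nf))
  for (j in seq_len(nf)) {
    cj <- cos(phases[j]); sj <- sin(phases[j])
    sx[, , j] <- Re(ux) * cj - Im(ux) * sj
    sy[, , j] <- Re(uy) * cj - Im(uy) * sj
  }

  # rescale so max over frames and pixels of |u| is amplitude_scale * h
  mag_max <- sqrt(max(sx^2 + sy^2))
  if (mag_max == 0) {
    scale <- 0
  } else {
    scale <- amplitude_scale * h / mag_max
    sx <- sx * scale; sy <- sy * scale
  }

  if (noise_fraction > 0) {
    seeds <- if (is.null(seed)) list(NULL, NULL)
             else list(seed, (seed + 104729L) %% .Machine$integer.max)
    sx <- add_white_noise(sx, noise_fraction, seeds[[1]])
    sy <- add_white_noise(sy, noise_fraction, seeds[[2]])
  }

  max_px <- sqrt(max(sx^2 + sy^2)) / h
  if (max_px > max_displacement_px)
    stop(sprintf("encoded displacement %.3g px exceeds the sanity bound %g px",
                 max_px, max_displacement_px))

  frames <- array(0, c(d, nf))
  for (j in seq_len(nf)) {
    frames[, , j] <- warp_image(image, sx[, , j] / h, sy[, , j] / h,
                                boundary = boundary)
  }
  if (quantize) {
    vmax <- max(frames)
    if (vmax > 0) {
      # full scale is the next power of two: scaling by it is exact in
      # binary floating point, so TIFF round trips reproduce the values
      # bit for bit
      lev <- 2^as.integer(bit_depth) - 1
      S <- 2^ceiling(log2(vmax))
      frames <- round(frames / S * lev) / lev * S
    }
  }
  frames[frames < 0] <- 0
  out <- image_series(frames, field$frequency, phases, times,
                      field$pixel_size)
  attr(out, "amplitude_um") <- amplitude_scale * h
  attr(out, "intensity_max") <- max(frames)
  out
}
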