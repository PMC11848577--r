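#' Convert an elastic modulus to shear wave speed
#'
#' `SWS = sqrt(G' / rho)` for a storage (shear) modulus and
#' `SWS = sqrt(E / (3 rho))` for a Young's modulus (incompressible limit,
#' `E = 3 G`).
#'
#' @param value modulus in Pa (vectorized, >= 0).
#' @param kind `"storage"` (shear storage modulus G') or `"young"`
#'   (Young's modulus E).
#' @param density mass density (kg/m^3), default 1000.
#' @return Shear wave speed in m/s.
#' @examples
#' modulus_to_sws(1970, "young")    # 0.81 m/s
#' modulus_to_sws(2250, "storage")  # 1.5 m/s
#' @export
modulus_to_sws <- function(value, kind = c("storage", "young"),
                           density = 1000) {
  kind <- match.arg(kind)
  stopifnot(density > 0)
  if (any(value < 0)) stop("modulus must be non-negative")
  switch(kind,
         storage = sqrt(value / density),
         young = sqrt(value / (3 * density)))
}

# single-level 2-D Haar detail coefficients (orthonormal HH band)
haar_hh <- function(m) {
  nr <- 2L * (nrow(m) %/% 2L); nc <- 2L * (ncol(m) %/% 2L)
  if (nr < 2L || nc < 2L) return(numeric(0))
  a <- m[seq(1L, nr, 2L), seq(1L, nc, 2L)]
  b <- m[seq(2L, nr, 2L), seq(1L, nc, 2L)]
  cc <- m[seq(1L, nr, 2L), seq(2L, nc, 2L)]
  dd <- m[seq(2L, nr, 2L), seq(2L, nc, 2L)]
  as.vector((a - b - cc + dd) / 2)
}

#' Wavelet-based signal-to-noise ratio of a wave field
#'
#' Estimates the noise level as the median absolute deviation of the
#' finest-scale diagonal wavelet detail coefficients divided by 0.6745
#' (pooled over the real and imaginary planes of all components), and
#' reports `SNR = 20 log10(RMS(field) / sigma)` in dB, where the RMS
#' pools the same planes. A smooth wave contributes almost nothing to
#' the diagonal detail band, so sigma tracks the additive noise floor.
#'
#' @param field a [complex_wave_field] (or a numeric/complex matrix).
#' @return SNR in dB; `-Inf` for an identically zero field.
#' @export
donoho_snr <- function(field) {
  planes <- if (inherits(field, "complex_wave_field")) {
    unlist(lapply(field$components, function(u) list(Re(u), Im(u))),
           recursive = FALSE)
  } else if (is.complex(field)) {
    list(Re(as.matrix(field)), Im(as.matrix(field)))
  } else {
    list(as.matrix(field))
  }
  vals <- unlist(lapply(planes, as.vector))
  rms <- sqrt(mean(vals^2))
  if (rms == 0) return(-Inf)
  det <- unlist(lapply(planes, haar_hh))
  sigma <- stats::median(abs(det)) / 0.6745
  if (sigma == 0) return(Inf)
  20 * log10(rms / sigma)
}

#' Fit a wavelength model to a complex wave profile and return SWS
#'
#' Least-squares fit of a damped harmonic model to a complex-valued
#' profile extracted from a wave field: either a damped plane wave
#' `A exp(-i k x) exp(-alpha x)` (`model = "plane"`; the sign of the
#' spatial phase is resolved automatically) or a damped zeroth-order
#' Bessel radial profile `A J0(k r) exp(-alpha r)` (`model = "bessel"`).
#' Real and imaginary parts are fitted jointly; the wave speed is
#' `SWS = 2 pi f / k`.
#'
#' @param values complex profile samples.
#' @param distance physical positions of the samples (micrometres),
#'   same length; for the Bessel model, radial distances from the center.
#' @param frequency drive frequency (Hz).
#' @param model `"plane"` or `"bessel"`.
#'
#' @return List with `sws` (m/s), `k` (rad/m), `alpha` (1/m) and the
#'   `fit` object from [minpack.lm::nls.lm].
#' @export
profile_fit_sws <- function(values, distance, frequency,
                            model = c("plane", "bessel")) {
  model <- match.arg(model)
  stopifnot(length(values) == length(distance), frequency > 0)
  x <- as.numeric(distance) * 1e-6      # m
  v <- as.complex(values)

  # initial wavenumber from the dominant spatial harmonic
  dx <- stats::median(diff(x))
  if (!(dx > 0)) stop("distances must be increasing")
  lam_px <- dominant_wavelength(v)
  k0 <- 2 * pi / (lam_px * dx)
  env <- log(pmax(Mod(v), 1e-12 * max(Mod(v))))
  a0 <- max(0, -stats::coef(stats::lm(env ~ x))[2])

  predfun <- if (model == "plane") {
    function(p, sgn) (p[3] + 1i * p[4]) * exp(sgn * 1i * p[1] * x - p[2] * x)
  } else {
    function(p, sgn) (p[3] + 1i * p[4]) * besselJ(abs(p[1] * x), 0) *
      exp(-p[2] * x)
  }
  fit_one <- function(sgn) {
    resid <- function(p) {
      pr <- predfun(p, sgn)
      c(Re(pr - v), Im(pr - v))
    }
    amp0 <- v[which.max(Mod(v))]
    minpack.lm::nls.lm(
      par = c(k0, a0, Re(amp0), Im(amp0)), fn = resid,
      control = minpack.lm::nls.lm.control(maxiter = 200))
  }
  fits <- if (model == "plane") list(fit_one(-1), fit_one(1))
          else list(fit_one(1))
  dev <- vapply(fits, function(f) f$deviance, 0)
  best <- fits[[which.min(dev)]]
  if (!best$info %in% 1:4)
    stop("profile fit did not converge: ", best$message)
  k <- abs(best$par[1])
  if (!is.finite(k) || k <= 0) stop("profile fit returned invalid wavenumber")
  list(sws = 2 * pi * frequency / k, k = k, alpha = best$par[2], fit = best)
}

#' Per-region statistics of an SWS map
#'
#' Mean, standard deviation and pixel count of the valid (non-`NA`)
#' pixels per region label.
#'
#' @param map an [sws_field_map] (or numeric matrix).
#' @param labels integer label matrix; defaults to the map's own labels.
#' @return `data.frame` with columns `label`, `mean`, `sd`, `n` (empty
#'   regions keep their row with `n = 0` and `NA` statistics).
#' @export
region_stats <- function(map, labels = NULL) {
  grid <- if (inherits(map, "sws_field_map")) map$grid else as.matrix(map)
  if (is.null(labels) && inherits(map, "sws_field_map")) labels <- map$labels
  if (is.null(labels)) stop("labels are required")
  labels <- as.matrix(labels)
  if (!all(dim(labels) == dim(grid)))
    stop("labels and map must be aligned")
  lv <- sort(unique(as.vector(labels)))
  rows <- lapply(lv, function(l) {
    v <- grid[labels == l]
    v <- v[!is.na(v)]
    data.frame(label = l,
               mean = if (length(v)) mean(v) else NA_real_,
               sd = if (length(v) > 1) stats::sd(v) else
                 if (length(v) == 1) 0 else NA_real_,
               n = length(v))
  })
  do.call(rbind, rows)
}

#' Shear waves per image width
#'
#' Bookkeeping helper for simulation geometry: the number of wavelengths
#' spanning an image of `n_pixels` edge length at a given frequency and
#' wave speed, `n_pixels * h * f / SWS`.
#'
#' @param n_pixels image edge length in pixels.
#' @param pixel_size pixel edge (micrometres).
#' @param frequency vibration frequency (Hz).
#' @param sws shear wave speed (m/s).
#' @return Number of waves per image (dimensionless).
#' @examples
#' waves_per_image(500, 29.609, 3900, 1)  # about 57.7
#' @export
waves_per_image <- function(n_pixels, pixel_size, frequency, sws) {
  stopifnot(n_pixels > 0, pixel_size > 0, frequency > 0, sws > 0)
  n_pixels * pixel_size * 1e-6 * frequency / sws
}
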