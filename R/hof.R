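#' Harmonic optical flow configuration
#'
#' Settings for the iterative harmonic optical flow solver.
#'
#' @param lambda Horn-Schunck regularization weight, in the units of the
#'   structure-tensor trace. `NULL` (default) chooses
#'   `0.03 * mean(trace(m[grad I grad I^T]))` at solve time, which makes the
#'   regularization invariant to intensity rescaling while keeping the
#'   amplitude attenuation of waves a few kernel widths long below ~10%.
#' @param max_iter maximum number of iterations (default 100).
#' @param tol relative L2-change stopping threshold (default 1e-4).
#' @param kernel_N neighborhood half-width in pixels; `NULL` derives it
#'   from the pixel size via [hof_kernel_size].
#' @param median_cap maximum edge length of the per-iteration median
#'   filter window (pixels, default 11); the window edge is
#'   `min(kernel_N, median_cap)`.
#'
#' @return An object of class `hof_config`.
#' @export
hof_config <- function(lambda = NULL, max_iter = 100L, tol = 1e-4,
                       kernel_N = NULL, median_cap = 11L) {
  stopifnot(is.null(lambda) || lambda > 0, max_iter >= 1L, tol > 0,
            is.null(kernel_N) || kernel_N >= 3L)
  structure(list(lambda = lambda, max_iter = as.integer(max_iter),
                 tol = tol, kernel_N = if (is.null(kernel_N)) NULL
                 else as.integer(kernel_N),
                 median_cap = as.integer(median_cap)),
            class = "hof_config")
}

#' Resolution-scaled smoothing kernel size
#'
#' The neighborhood (and median filter) kernel is scaled with the pixel
#' size as `N = round(64 um / h)`, clamped to at least 3, so that the
#' physical smoothing capacity stays constant across image resolutions.
#'
#' @param pixel_size pixel edge length h (micrometres).
#' @return Integer kernel size N (pixels).
#' @examples
#' hof_kernel_size(2)   # 32
#' hof_kernel_size(4)   # 16
#' hof_kernel_size(10)  # 6
#' @export
hof_kernel_size <- function(pixel_size) {
  stopifnot(pixel_size > 0)
  max(3L, as.integer(round(64 / pixel_size)))
}

#' Center-excluded neighborhood average
#'
#' Uniform mean over the `(2N+1) x (2N+1)` window around each pixel,
#' excluding the center pixel, with weights summing to 1 and mirror
#' boundary handling. This is the discrete smoothing operator whose
#' difference from the identity approximates the Laplacian in the
#' Horn-Schunck update.
#'
#' @param field real or complex 2-D matrix.
#' @param N window half-width (pixels, >= 1).
#' @return Matrix of the same shape and mode.
#' @export
neighborhood_average <- function(field, N) {
  stopifnot(N >= 1L)
  box_mean(as.matrix(field), as.integer(N), exclude_center = TRUE)
}

#' Period-averaged structure terms of an image series
#'
#' Computes the two ingredients of the harmonic optical flow normal
#' equations from a registered, normalized series: the per-pixel 2x2
#' structure tensor `m[grad I grad I^T]` (temporal mean over the frames,
#' spatial gradients by central differences in pixel units) and the
#' complex right-hand side vector: the harmonic coefficient of
#' `(dI/dt) grad I` at the drive frequency, computed with the recorded
#' (possibly aliased) phases and expressed in displacement (pixel) units.
#' The temporal derivative is obtained analytically from the per-pixel
#' harmonic fit of `I`, which is exact for time-harmonic motion and
#' robust under stroboscopic sampling; dividing its harmonic projection
#' by `i` then removes the frequency scaling, so the fixed point of the
#' solver is a displacement.
#'
#' @param series an [image_series] (or 3-D array via `phases`).
#' @param phases recorded phases (radians); defaults to `series$phases`.
#'
#' @return An object of class `structure_terms`: list with `tensor`
#'   (list of matrices `t11`, `t12`, `t22`), `rhs` (list of complex
#'   matrices `x`, `y`) and `phases`.
#' @export
harmonic_structure_terms <- function(series, phases = NULL) {
  if (inherits(series, "image_series")) {
    frames <- series$frames
    if (is.null(phases)) phases <- series$phases
  } else {
    frames <- series
    if (is.null(phases)) stop("phases are required for a bare array")
  }
  d <- dim(frames)
  stopifnot(length(d) == 3L, d[3] == length(phases))
  if (length(unique(round(phases / (2 * pi) * 1e9))) < 3L)
    stop("phase design is rank-deficient; need >= 3 distinct phases")

  nr <- d[1]; nc <- d[2]; nf <- d[3]
  t11 <- matrix(0, nr, nc); t12 <- matrix(0, nr, nc); t22 <- matrix(0, nr, nc)
  gx <- array(0, d); gy <- array(0, d)
  for (j in seq_len(nf)) {
    I <- frames[, , j]
    # central differences, mirror boundary, per-pixel units
    Ix <- (I[, reflect_index(2:(nc + 1), nc)] -
             I[, reflect_index(0:(nc - 1), nc)]) / 2
    Iy <- (I[reflect_index(2:(nr + 1), nr), ] -
             I[reflect_index(0:(nr - 1), nr), ]) / 2
    gx[, , j] <- Ix; gy[, , j] <- Iy
    t11 <- t11 + Ix * Ix; t12 <- t12 + Ix * Iy; t22 <- t22 + Iy * Iy
  }
  t11 <- t11 / nf; t12 <- t12 / nf; t22 <- t22 / nf

  # analytic temporal derivative of the harmonic fit, in phase units:
  # I ~ I0 + Re(c e^{i phi}) => dI/dphi = Re(i c e^{i phi})
  fit <- harmonic_fit(frames, phases)
  dIdphi <- array(0, d)
  for (j in seq_len(nf))
    dIdphi[, , j] <- Re(1i * fit$coef * exp(1i * phases[j]))

  # project (dI/dphi) grad I onto the harmonic regressors and divide by i
  # so that the result is in displacement units
  px <- harmonic_fit(dIdphi * gx, phases)$coef / 1i
  py <- harmonic_fit(dIdphi * gy, phases)$coef / 1i

  structure(list(tensor = list(t11 = t11, t12 = t12, t22 = t22),
                 rhs = list(x = px, y = py), phases = phases),
            class = "structure_terms")
}

#' Decode the complex harmonic displacement field from an image series
#'
#' Iteratively solves the time-harmonic Horn-Schunck normal equations:
#' at every pixel the 2x2 system
#' `(m[grad I grad I^T] + lambda I) u_hat^{n+1} = lambda u_bar^n - F`
#' is solved in closed form, where `u_bar` is the center-excluded
#' neighborhood average of the current iterate and `F` is the harmonic
#' right-hand side from [harmonic_structure_terms]. After every iteration
#' the real and imaginary parts of each component are median filtered
#' (window edge `min(N, median_cap)`). Iteration starts from zero and
#' stops at `max_iter` or when the relative L2 change drops below `tol`.
#'
#' @param series an [image_series] (registered and normalized).
#' @param phases recorded phases; defaults to the series' phases.
#' @param config an [hof_config].
#'
#' @return A two-component [complex_wave_field] in micrometres.
#' @export
solve_hof <- function(series, phases = NULL, config = hof_config()) {
  stopifnot(inherits(series, "image_series"), inherits(config, "hof_config"))
  if (is.null(phases)) phases <- series$phases
  terms <- harmonic_structure_terms(series$frames, phases)
  h <- series$pixel_size
  N <- if (is.null(config$kernel_N)) hof_kernel_size(h) else config$kernel_N
  medw <- min(N, config$median_cap)
  if (medw %% 2L == 0L) medw <- medw + 1L
  lambda <- config$lambda
  if (is.null(lambda))
    lambda <- 0.03 * mean(terms$tensor$t11 + terms$tensor$t22)
  if (lambda <= 0) lambda <- 1e-12

  t11 <- terms$tensor$t11 + lambda
  t22 <- terms$tensor$t22 + lambda
  t12 <- terms$tensor$t12
  det <- t11 * t22 - t12 * t12
  Fx <- terms$rhs$x; Fy <- terms$rhs$y

  d <- dim(t11)
  ux <- matrix(complex(real = 0), d[1], d[2])
  uy <- ux
  for (it in seq_len(config$max_iter)) {
    bx <- lambda * neighborhood_average(ux, N) - Fx
    by <- lambda * neighborhood_average(uy, N) - Fy
    nx <- (t22 * bx - t12 * by) / det
    ny <- (t11 * by - t12 * bx) / det
    nx <- matrix(complex(real = median_filter2(Re(nx), medw),
                         imaginary = median_filter2(Im(nx), medw)),
                 d[1], d[2])
    ny <- matrix(complex(real = median_filter2(Re(ny), medw),
                         imaginary = median_filter2(Im(ny), medw)),
                 d[1], d[2])
    if (!all(is.finite(Re(nx)) & is.finite(Im(nx)) &
             is.finite(Re(ny)) & is.finite(Im(ny))))
      stop(sprintf("non-finite values in HOF iteration %d", it))
    delta <- sqrt(sum(Mod(nx - ux)^2 + Mod(ny - uy)^2))
    norm <- sqrt(sum(Mod(nx)^2 + Mod(ny)^2))
    ux <- nx; uy <- ny
    if (norm > 0 && delta / norm < config$tol) break
  }
  complex_wave_field(x = ux * h, y = uy * h,
                     frequency = series$frequency, pixel_size = h)
}
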