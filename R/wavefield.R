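#' Complex harmonic wave field
#'
#' Per-frequency complex displacement field u = u' + i*u'' with the time
#' convention u(r, t) = Re(u_hat(r) e^{i w t}) = u' cos(wt) - u'' sin(wt).
#' Holds one or both in-plane components (`x` along columns, `y` along
#' rows), the drive frequency and the pixel size. Displacements are stored
#' in micrometres.
#'
#' @param x,y complex matrices (micrometres); at least one must be given,
#'   and both must share one shape when present.
#' @param frequency drive frequency f (Hz); the angular frequency is
#'   `2 * pi * frequency`.
#' @param pixel_size pixel edge length h (micrometres).
#' @param check if `TRUE` (default) require all values to be finite.
#'
#' @return An object of class `complex_wave_field` with elements
#'   `components` (named list of complex matrices), `frequency`,
#'   `omega` and `pixel_size`.
#' @export
complex_wave_field <- function(x = NULL, y = NULL, frequency, pixel_size,
                               check = TRUE) {
  comps <- list()
  if (!is.null(x)) comps$x <- as.matrix(x)
  if (!is.null(y)) comps$y <- as.matrix(y)
  if (length(comps) == 0L) stop("at least one component (x or y) is required")
  comps <- lapply(comps, function(m) {
    if (!is.complex(m)) storage.mode(m) <- "complex"
    m
  })
  d <- dim(comps[[1]])
  if (!all(vapply(comps, function(m) all(dim(m) == d), TRUE)))
    stop("components must share one shape")
  stopifnot(length(frequency) == 1L, frequency > 0,
            length(pixel_size) == 1L, pixel_size > 0)
  if (check && !all(vapply(comps, function(m) all(is.finite(Re(m)) & is.finite(Im(m))), TRUE)))
    stop("wave field contains non-finite values")
  structure(
    list(components = comps, frequency = as.numeric(frequency),
         omega = 2 * pi * as.numeric(frequency),
         pixel_size = as.numeric(pixel_size)),
    class = "complex_wave_field"
  )
}

#' @export
print.complex_wave_field <- function(x, ...) {
  d <- dim(x$components[[1]])
  amp <- max(vapply(x$components, function(m) max(Mod(m)), 0))
  cat(sprintf(
    "<complex_wave_field> %d x %d px, f = %g Hz, h = %.4g um, components: %s, max |u| = %.3g um\n",
    d[1], d[2], x$frequency, x$pixel_size,
    paste(names(x$components), collapse = ","), amp))
  invisible(x)
}

# Merge single-component fields at one frequency into one two-component
# field (used by the pipeline to pair the x- and y-simulations).
merge_wave_fields <- function(fx, fy) {
  stopifnot(inherits(fx, "complex_wave_field"),
            inherits(fy, "complex_wave_field"),
            isTRUE(all.equal(fx$frequency, fy$frequency)),
            isTRUE(all.equal(fx$pixel_size, fy$pixel_size)))
  complex_wave_field(x = fx$components$x, y = fy$components$y,
                     frequency = fx$frequency, pixel_size = fx$pixel_size)
}
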