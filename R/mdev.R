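#' Long-lag finite gradient scheme
#'
#' Parameters of the noise-suppressing finite gradient: central
#' differences with lags `s1` (rows) and `s2` (columns), averaged over a
#' `(2*r1+1) x (2*r2+1)` neighborhood. The default `s1 = s2 = 10`,
#' `r1 = r2 = 0` realizes a quadratic derivative kernel spanning 20
#' pixels.
#'
#' @param s1,s2 central-difference lags in pixels (>= 1); `s1` acts along
#'   rows (y), `s2` along columns (x).
#' @param r1,r2 averaging half-widths in pixels (>= 0); `r1` extends
#'   along columns, `r2` along rows.
#' @param pixel_size pixel edge length h (micrometres).
#'
#' @return An object of class `gradient_scheme`.
#' @export
gradient_scheme <- function(s1 = 10L, s2 = 10L, r1 = 0L, r2 = 0L,
                            pixel_size) {
  stopifnot(s1 >= 1L, s2 >= 1L, r1 >= 0L, r2 >= 0L, pixel_size > 0)
  structure(list(s1 = as.integer(s1), s2 = as.integer(s2),
                 r1 = as.integer(r1), r2 = as.integer(r2),
                 pixel_size = as.numeric(pixel_size)),
            class = "gradient_scheme")
}

# shift a matrix by (dr, dc) filling the exposed border with NA
shift_na <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(m[1][NA], nr, nc)
  sr <- max(1L, 1L - dr):min(nr, nr - dr)
  sc <- max(1L, 1L - dc):min(nc, nc - dc)
  if (length(sr) > 0L && length(sc) > 0L)
    out[sr, sc] <- m[sr + dr, sc + dc, drop = FALSE]
  out
}

# neighborhood box sum with NA propagation at the borders
avg_sum_na <- function(m, rrow, rcol) {
  if (rrow == 0L && rcol == 0L) return(m)
  out <- matrix(if (is.complex(m)) 0 + 0i else 0, nrow(m), ncol(m))
  for (dn in -rrow:rrow) for (dm in -rcol:rcol)
    out <- out + shift_na(m, dn, dm)
  out
}

#' Long-lag finite gradient of a complex field
#'
#' Central differences with lags `s1` (rows) and `s2` (columns) are
#' averaged over the scheme's neighborhood and scaled by
#' `1 / (2 (2 r1 + 1) (2 r2 + 1) s h)`, yielding the per-pixel gradient
#' in SI units (per metre; `h` is converted from micrometres). Long lags
#' suppress short-wavelength noise in place of spatial bandpass
#' filtering. Pixels whose stencil reaches outside the field are flagged
#' invalid.
#'
#' @param field 2-D real or complex matrix.
#' @param scheme a [gradient_scheme].
#'
#' @return List with `gx`, `gy` (same mode as `field`, per metre; invalid
#'   pixels are `NA`) and logical `mask` (`TRUE` where valid).
#' @export
finite_gradient <- function(field, scheme) {
  stopifnot(inherits(scheme, "gradient_scheme"))
  field <- as.matrix(field)
  nr <- nrow(field); nc <- ncol(field)
  s1 <- scheme$s1; s2 <- scheme$s2; r1 <- scheme$r1; r2 <- scheme$r2
  if (nr <= 2L * (s1 + r2) || nc <= 2L * (s2 + r1))
    stop("gradient stencil exceeds the field")
  h <- scheme$pixel_size * 1e-6
  a <- shift_na(field, s1, 0L) - shift_na(field, -s1, 0L)   # row lag
  b <- shift_na(field, 0L, s2) - shift_na(field, 0L, -s2)   # column lag
  norm <- 2 * (2 * r1 + 1) * (2 * r2 + 1)
  gy <- avg_sum_na(a, r2, r1) / (norm * s1 * h)
  gx <- avg_sum_na(b, r2, r1) / (norm * s2 * h)
  mask <- !(is.na(gx) | is.na(gy))
  list(gx = gx, gy = gy, mask = mask)
}

#' Long-lag Laplacian
#'
#' Discrete Laplacian in the same long-lag family as [finite_gradient].
#' The default (`method = "second_difference"`) uses lagged second
#' central differences, `(y[k+s] - 2 y[k] + y[k-s]) / (s h)^2` per
#' direction, averaged over the scheme's `(2 r1 + 1) x (2 r2 + 1)`
#' neighborhood; its total stencil spans `2 s` pixels per direction (a
#' square 20-pixel derivative kernel at the default `s = 10`), and it is
#' exact on quadratics. `method = "gradient_twice"` instead applies the
#' Eq.-style long-lag gradient twice (divergence of the gradient), which
#' doubles the footprint and the low-pass bias of the spectral response.
#' The validity mask is eroded by the stencil footprint.
#'
#' @inheritParams finite_gradient
#' @param method `"second_difference"` (default) or `"gradient_twice"`.
#' @return List with `lap` (per square metre, `NA` where invalid) and
#'   logical `mask`.
#' @export
laplacian <- function(field, scheme,
                      method = c("second_difference", "gradient_twice")) {
  method <- match.arg(method)
  if (method == "gradient_twice") {
    g <- finite_gradient(field, scheme)
    gxx <- finite_gradient(g$gx, scheme)
    gyy <- finite_gradient(g$gy, scheme)
    lap <- gxx$gx + gyy$gy
    return(list(lap = lap, mask = !is.na(lap)))
  }
  stopifnot(inherits(scheme, "gradient_scheme"))
  field <- as.matrix(field)
  nr <- nrow(field); nc <- ncol(field)
  s1 <- scheme$s1; s2 <- scheme$s2; r1 <- scheme$r1; r2 <- scheme$r2
  if (nr <= 2L * (s1 + r2) || nc <= 2L * (s2 + r1))
    stop("Laplacian stencil exceeds the field")
  h <- scheme$pixel_size * 1e-6
  d2r <- shift_na(field, s1, 0L) - 2 * field + shift_na(field, -s1, 0L)
  d2c <- shift_na(field, 0L, s2) - 2 * field + shift_na(field, 0L, -s2)
  norm <- (2 * r1 + 1) * (2 * r2 + 1)
  lap <- avg_sum_na(d2r, r2, r1) / (norm * (s1 * h)^2) +
    avg_sum_na(d2c, r2, r1) / (norm * (s2 * h)^2)
  list(lap = lap, mask = !is.na(lap))
}

#' Magnitude shear modulus map
#'
#' Container for the inverted magnitude modulus `|G*|` with its validity
#' mask.
#'
#' @param magnitude matrix of `|G*|` (Pa), `NA` where invalid.
#' @param mask logical matrix, `TRUE` where valid.
#' @param density mass density (kg/m^3).
#' @param frequencies drive frequencies that entered the inversion (Hz).
#' @param pixel_size pixel edge length (micrometres).
#' @return An object of class `modulus_map`.
#' @export
modulus_map <- function(magnitude, mask, density, frequencies, pixel_size) {
  stopifnot(all(dim(magnitude) == dim(mask)), density > 0)
  if (any(magnitude[mask] < 0, na.rm = TRUE))
    stop("|G*| must be non-negative where valid")
  structure(list(magnitude = magnitude, mask = mask,
                 density = as.numeric(density),
                 frequencies = as.numeric(frequencies),
                 pixel_size = as.numeric(pixel_size)),
            class = "modulus_map")
}

#' @export
print.modulus_map <- function(x, ...) {
  cat(sprintf(
    "<modulus_map> %d x %d px, %d frequencies, median |G*| = %.4g Pa, %d%% valid\n",
    nrow(x$magnitude), ncol(x$magnitude), length(x$frequencies),
    stats::median(x$magnitude[x$mask]),
    round(100 * mean(x$mask))))
  invisible(x)
}

#' Multifrequency dual elasto-visco (MDEV) direct inversion
#'
#' Inverts complex wave fields to the magnitude shear modulus by the
#' pixelwise ratio of summed magnitudes,
#' `|G*| = rho * sum_{j,m} w_m^2 |u_j(w_m)| / sum_{j,m} |lap u_j(w_m)|`,
#' over all field components `j` and excitation frequencies `m`.
#' Numerator and denominator are accumulated separately (frequency
#' compounding of magnitude wave images and magnitude Laplacian images
#' prior to the division), which stabilizes the estimate at the nodes of
#' standing waves. No spatial bandpass filter is applied to the fields.
#' Pixels whose summed Laplacian magnitude falls below a floor
#' (`1e-9 x` its spatial median) are masked invalid, as is the stencil
#' border.
#'
#' @param fields a [complex_wave_field] or list of them; all on one grid
#'   and pixel size.
#' @param density mass density rho (kg/m^3), default 1000 (1 kg/L).
#' @param scheme a [gradient_scheme]; `NULL` uses the default scheme at
#'   the fields' pixel size.
#' @param laplacian_method passed to [laplacian].
#'
#' @return A [modulus_map] (Pa).
#' @export
mdev_modulus <- function(fields, density = 1000, scheme = NULL,
                         laplacian_method = "second_difference") {
  if (inherits(fields, "complex_wave_field")) fields <- list(fields)
  stopifnot(length(fields) >= 1L,
            all(vapply(fields, inherits, TRUE, "complex_wave_field")))
  d <- dim(fields[[1]]$components[[1]])
  h <- fields[[1]]$pixel_size
  for (f in fields) {
    if (!all(dim(f$components[[1]]) == d) ||
        !isTRUE(all.equal(f$pixel_size, h)))
      stop("all fields must share one grid and pixel size")
  }
  if (is.null(scheme)) scheme <- gradient_scheme(pixel_size = h)
  num <- matrix(0, d[1], d[2])
  den <- matrix(0, d[1], d[2])
  mask <- matrix(TRUE, d[1], d[2])
  for (f in fields) {
    omega <- f$omega
    for (u in f$components) {
      um <- u * 1e-6                       # um -> m
      L <- laplacian(um, scheme, method = laplacian_method)
      num <- num + omega^2 * Mod(um)
      lap <- L$lap
      lap[!L$mask] <- 0
      den <- den + Mod(lap)
      mask <- mask & L$mask
    }
  }
  floor_ <- 1e-9 * stats::median(den[mask])
  mask <- mask & den >= floor_
  mag <- matrix(NA_real_, d[1], d[2])
  mag[mask] <- density * num[mask] / den[mask]
  modulus_map(mag, mask, density, vapply(fields, function(f) f$frequency, 0),
              h)
}

#' Shear wave speed from a modulus map
#'
#' `SWS = sqrt(|G*| / rho)` per pixel; the validity mask is propagated as
#' `NA`.
#'
#' @param map a [modulus_map].
#' @param labels optional region labels to attach to the result.
#' @return An [sws_field_map] (m/s).
#' @export
sws_from_modulus <- function(map, labels = NULL) {
  stopifnot(inherits(map, "modulus_map"))
  grid <- sqrt(map$magnitude / map$density)
  grid[!map$mask] <- NA_real_
  sws_field_map(grid, map$pixel_size, labels = labels,
                density = map$density)
}
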