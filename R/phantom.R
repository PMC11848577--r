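#' Shear-wave-speed field map
#'
#' Container for a two-dimensional map of shear wave speed (SWS), the
#' stiffness surrogate used throughout the package (SWS = sqrt(G'/rho) in a
#' purely elastic, incompressible medium). A map carries the SWS grid in
#' m/s, the physical pixel size in micrometres, an optional integer region
#' label grid of the same shape (0 = background), and the assumed mass
#' density in kg/m^3.
#'
#' @param grid numeric matrix of SWS values (m/s); may contain `NA` for
#'   pixels masked as invalid by an inversion.
#' @param pixel_size edge length of one pixel (micrometres).
#' @param labels optional integer matrix of region labels, same shape as
#'   `grid`.
#' @param density mass density rho (kg/m^3); defaults to 1000 (1 kg/L), the
#'   value recommended for soft biological tissue.
#'
#' @return An object of class `sws_field_map`.
#' @export
sws_field_map <- function(grid, pixel_size, labels = NULL, density = 1000) {
  grid <- as.matrix(grid)
  stopifnot(is.numeric(grid), length(pixel_size) == 1L, pixel_size > 0,
            length(density) == 1L, density > 0)
  if (any(grid[!is.na(grid)] < 0))
    stop("SWS values must be non-negative")
  if (!is.null(labels)) {
    labels <- as.matrix(labels)
    if (!all(dim(labels) == dim(grid)))
      stop("labels and grid must have identical shape")
    storage.mode(labels) <- "integer"
  }
  structure(
    list(grid = grid, pixel_size = as.numeric(pixel_size),
         labels = labels, density = as.numeric(density)),
    class = "sws_field_map"
  )
}

#' @export
print.sws_field_map <- function(x, ...) {
  d <- dim(x$grid)
  rng <- range(x$grid, na.rm = TRUE)
  cat(sprintf("<sws_field_map> %d x %d px, h = %.4g um, rho = %g kg/m^3\n",
              d[1], d[2], x$pixel_size, x$density))
  cat(sprintf("  SWS range: %.3g .. %.3g m/s; %d masked px; %s\n",
              rng[1], rng[2], sum(is.na(x$grid)),
              if (is.null(x$labels)) "no labels"
              else sprintf("%d labelled regions", length(unique(as.vector(x$labels))))))
  invisible(x)
}

#' Build a piecewise-constant phantom with circular inclusions
#'
#' Constructs the ground-truth SWS map used by the simulation experiments:
#' a uniform background with zero or more non-overlapping circular
#' inclusions of different stiffness. Labels are 0 for background and
#' 1..K for the inclusions in the order given.
#'
#' @param shape integer vector `c(rows, cols)` of the pixel grid.
#' @param pixel_size pixel edge length (micrometres).
#' @param background_sws background shear wave speed (m/s).
#' @param inclusion_specs list of inclusions, each a list with elements
#'   `center` (`c(row, col)` in pixels), `radius` (pixels) and `sws` (m/s).
#' @param density mass density (kg/m^3).
#'
#' @return An [sws_field_map] with piecewise-constant `grid` and integer
#'   `labels`.
#' @examples
#' ph <- build_two_inclusion_phantom(
#'   shape = c(120, 120), pixel_size = 30, background_sws = 3.6,
#'   inclusion_specs = list(
#'     list(center = c(40, 40), radius = 15, sws = 2.7),
#'     list(center = c(85, 85), radius = 15, sws = 4.5)))
#' table(ph$labels)
#' @export
build_two_inclusion_phantom <- function(shape, pixel_size, background_sws,
                                        inclusion_specs = list(),
                                        density = 1000) {
  stopifnot(length(shape) == 2L, all(shape >= 1), background_sws > 0)
  nr <- as.integer(shape[1]); nc <- as.integer(shape[2])
  grid <- matrix(background_sws, nr, nc)
  labels <- matrix(0L, nr, nc)
  K <- length(inclusion_specs)
  if (K > 0) {
    ctr <- t(vapply(inclusion_specs, function(s) as.numeric(s$center),
                    numeric(2)))
    rad <- vapply(inclusion_specs, function(s) as.numeric(s$radius), 0)
    sws <- vapply(inclusion_specs, function(s) as.numeric(s$sws), 0)
    if (any(rad <= 0)) stop("inclusion radii must be > 0")
    if (any(sws <= 0)) stop("inclusion SWS values must be > 0")
    inside <- ctr[, 1] - rad >= 1 & ctr[, 1] + rad <= nr &
      ctr[, 2] - rad >= 1 & ctr[, 2] + rad <= nc
    if (!all(inside))
      stop(sprintf("inclusion %d extends outside the grid",
                   which(!inside)[1]))
    if (K > 1) {
      for (a in 1:(K - 1)) for (b in (a + 1):K) {
        if (sqrt(sum((ctr[a, ] - ctr[b, ])^2)) < rad[a] + rad[b])
          stop(sprintf("inclusions %d and %d overlap", a, b))
      }
    }
    rr <- rep(seq_len(nr), times = nc)
    cc <- rep(seq_len(nc), each = nr)
    for (k in seq_len(K)) {
      m <- (rr - ctr[k, 1])^2 + (cc - ctr[k, 2])^2 <= rad[k]^2
      grid[m] <- sws[k]
      labels[m] <- k
    }
  }
  sws_field_map(grid, pixel_size, labels, density)
}
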