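#' Merge a bracketed exposure series into a relative radiance image
#'
#' Combines images of the same scene taken at increasing exposure times
#' into one relative-radiance image: a per-pixel weighted average of
#' `intensity / exposure`, with tent weights that down-weight saturated
#' and near-zero pixels. Pixels saturated (or empty) at every exposure
#' fall back to the shortest exposure's radiance estimate; if that happens
#' at every pixel the merge is refused.
#'
#' @param images list of 2-D intensity matrices sharing one shape.
#' @param exposures strictly increasing exposure times (same length).
#' @param full_scale intensity value regarded as full scale; defaults to
#'   the maximum over all images.
#' @param saturation_threshold fraction of full scale above which a pixel
#'   counts as saturated (default 0.98).
#'
#' @return A 2-D relative radiance image (intensity per unit exposure).
#' @export
hdr_merge <- function(images, exposures, full_scale = NULL,
                      saturation_threshold = 0.98) {
  if (is.matrix(images)) images <- list(images)
  stopifnot(length(images) >= 1L, length(images) == length(exposures))
  if (length(exposures) > 1L && any(diff(exposures) <= 0))
    stop("exposures must be strictly increasing")
  d <- dim(images[[1]])
  if (!all(vapply(images, function(m) all(dim(m) == d), TRUE)))
    stop("images must share one shape")
  if (is.null(full_scale)) full_scale <- max(vapply(images, max, 0))
  if (full_scale <= 0) stop("images are empty")
  sat <- saturation_threshold
  wsum <- matrix(0, d[1], d[2]); acc <- matrix(0, d[1], d[2])
  for (k in seq_along(images)) {
    v <- images[[k]] / full_scale
    w <- pmax(0, pmin(v / (sat / 2), (sat - v) / (sat / 2)))
    acc <- acc + w * images[[k]] / exposures[k]
    wsum <- wsum + w
  }
  bad <- wsum <= 0
  if (all(bad))
    stop("all pixels saturated or empty at every exposure; cannot merge")
  out <- matrix(0, d[1], d[2])
  out[!bad] <- acc[!bad] / wsum[!bad]
  if (any(bad)) {
    shortest <- images[[1]] / exposures[1]
    out[bad] <- shortest[bad]
  }
  out
}

#' Contrast-limited adaptive histogram equalization
#'
#' Normalizes local image contrast with CLAHE: the image is divided into
#' a grid of tiles, each tile's histogram is clipped at a fraction of its
#' pixel count (the excess is redistributed uniformly), and every pixel
#' is remapped through the bilinear interpolation of the cumulative
#' histograms of the four nearest tiles. The result lies in `[0, 1]`;
#' a constant image stays constant. On an already-equalized image the
#' tile histograms are nearly flat, so a second pass is close to the
#' identity.
#'
#' @param image 2-D numeric matrix (finite).
#' @param clip_limit contrast clip limit as a fraction of the tile pixel
#'   count per histogram bin, relative to the uniform level (default
#'   0.01, i.e., bins * 0.01 = 2.56 times the uniform bin height at 256
#'   bins).
#' @param tile_grid `c(nx, ny)` number of tiles per dimension (default 8).
#' @param bins histogram bins (default 256).
#'
#' @return A 2-D image with values in `[0, 1]`.
#' @export
equalize <- function(image, clip_limit = 0.01, tile_grid = c(8L, 8L),
                     bins = 256L) {
  image <- as.matrix(image)
  if (!all(is.finite(image))) stop("image must be finite")
  rng <- range(image)
  if (rng[2] - rng[1] <= 0) {
    return(matrix(stats::median(pmax(0, pmin(1, image))), nrow(image),
                  ncol(image)))
  }
  x <- (image - rng[1]) / (rng[2] - rng[1])
  nr <- nrow(x); nc <- ncol(x)
  ntc <- as.integer(tile_grid[1]); ntr <- as.integer(tile_grid[2])
  bins <- as.integer(bins)
  b <- matrix(pmin(bins, floor(x * bins) + 1L), nr, nc)  # bin index 1..bins

  # tile boundaries (as equal as possible)
  redges <- round(seq(0, nr, length.out = ntr + 1L))
  cedges <- round(seq(0, nc, length.out = ntc + 1L))
  rcent <- (redges[-1] + redges[-(ntr + 1L)] + 1) / 2
  ccent <- (cedges[-1] + cedges[-(ntc + 1L)] + 1) / 2

  # per-tile clipped cumulative mapping M[tile, bin] in [0, 1]
  M <- array(0, c(ntr, ntc, bins))
  for (ti in seq_len(ntr)) for (tj in seq_len(ntc)) {
    bb <- b[(redges[ti] + 1L):redges[ti + 1L],
            (cedges[tj] + 1L):cedges[tj + 1L]]
    hh <- tabulate(bb, nbins = bins)
    npx <- length(bb)
    clip <- max(1, clip_limit * npx)
    excess <- sum(pmax(hh - clip, 0))
    hh <- pmin(hh, clip) + excess / bins
    M[ti, tj, ] <- cumsum(hh) / npx
  }

  # bilinear interpolation between the four nearest tile mappings
  ri <- findInterval(seq_len(nr), rcent)           # 0..ntr
  ci <- findInterval(seq_len(nc), ccent)
  r0 <- pmax(1L, ri); r1 <- pmin(ntr, ri + 1L)
  c0 <- pmax(1L, ci); c1 <- pmin(ntc, ci + 1L)
  wr <- ifelse(r1 == r0, 0,
               (seq_len(nr) - rcent[r0]) / (rcent[r1] - rcent[r0]))
  wc <- ifelse(c1 == c0, 0,
               (seq_len(nc) - ccent[c0]) / (ccent[c1] - ccent[c0]))
  wr <- pmax(0, pmin(1, wr)); wc <- pmax(0, pmin(1, wc))

  m00 <- matrix(M[cbind(r0[row(b)], c0[col(b)], as.vector(b))], nr, nc)
  m01 <- matrix(M[cbind(r0[row(b)], c1[col(b)], as.vector(b))], nr, nc)
  m10 <- matrix(M[cbind(r1[row(b)], c0[col(b)], as.vector(b))], nr, nc)
  m11 <- matrix(M[cbind(r1[row(b)], c1[col(b)], as.vector(b))], nr, nc)
  WR <- matrix(wr, nr, nc); WC <- matrix(wc, nr, nc, byrow = TRUE)
  out <- (1 - WR) * ((1 - WC) * m00 + WC * m01) +
    WR * ((1 - WC) * m10 + WC * m11)
  out[out < 0] <- 0; out[out > 1] <- 1
  out
}

#' Rigid transform record
#'
#' Translation (and optional rotation) estimated by [rigid_register];
#' `dx` is the shift along columns (x), `dy` along rows (y), in pixels.
#'
#' @param dx,dy translation in pixels.
#' @param rotation rotation in radians (default 0; the default registration
#'   is translation-only).
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(dx = 0, dy = 0, rotation = 0) {
  stopifnot(is.finite(dx), is.finite(dy), is.finite(rotation))
  structure(list(dx = dx, dy = dy, rotation = rotation),
            class = "rigid_transform")
}

# Exact (Fourier-domain) translation of an image by (dy, dx) pixels;
# content moves by +d, wrapping periodically at the borders.
fourier_translate <- function(m, dy, dx) {
  nr <- nrow(m); nc <- ncol(m)
  fr <- c(0:(nr %/% 2), -((nr - nr %/% 2 - 1):1)) / nr
  fc <- c(0:(nc %/% 2), -((nc - nc %/% 2 - 1):1)) / nc
  ph <- exp(-2i * pi * outer(fr * dy, fc * dx, "+"))
  # keep the Nyquist row/column real-symmetric
  out <- Re(stats::fft(stats::fft(m) * ph, inverse = TRUE)) / (nr * nc)
  out
}

# Sub-pixel translation between two images by phase correlation with
# local DFT upsampling. Returns c(dy, dx) such that
# img(r) ~ ref(r - shift), i.e., img is ref moved by +shift.
phase_correlation_shift <- function(ref, img, upsample = 50L,
                                    refine_radius = 1.5) {
  nr <- nrow(ref); nc <- ncol(ref)
  # Hann window reduces the spectral leakage of the non-periodic borders,
  # which otherwise biases the sub-pixel estimate
  wnd <- outer(0.5 - 0.5 * cos(2 * pi * (seq_len(nr) - 1) / (nr - 1)),
               0.5 - 0.5 * cos(2 * pi * (seq_len(nc) - 1) / (nc - 1)))
  ref <- (ref - mean(ref)) * wnd
  img <- (img - mean(img)) * wnd
  F1 <- stats::fft(ref); F2 <- stats::fft(img)
  R <- F1 * Conj(F2)
  R <- R / (Mod(R) + 1e-12)
  cc <- Re(stats::fft(R, inverse = TRUE)) / (nr * nc)
  pk <- which.max(cc)
  pr <- ((pk - 1L) %% nr); pc <- ((pk - 1L) %/% nr)
  if (pr > nr / 2) pr <- pr - nr
  if (pc > nc / 2) pc <- pc - nc
  # cc peaks at (-dy, -dx) for img = ref shifted by +d
  d0 <- c(-pr, -pc)
  # refine by evaluating the correlation on an upsampled grid around d0
  step <- 1 / upsample
  dr <- seq(d0[1] - refine_radius, d0[1] + refine_radius, by = step)
  dc <- seq(d0[2] - refine_radius, d0[2] + refine_radius, by = step)
  fr <- c(0:(nr %/% 2), -((nr - nr %/% 2 - 1):1)) / nr
  fc <- c(0:(nc %/% 2), -((nc - nc %/% 2 - 1):1)) / nc
  # correlation(d) = sum_k R(k) exp(+2 pi i k . (-d)); build with kernels
  Er <- exp(-2i * pi * outer(dr, fr))      # |dr| x nr
  Ec <- exp(-2i * pi * outer(fc, dc))      # nc x |dc|
  cc2 <- Re(Er %*% R %*% Ec)
  pk2 <- arrayInd(which.max(cc2), dim(cc2))
  c(dy = dr[pk2[1]], dx = dc[pk2[2]])
}

#' Rigid registration of an image series
#'
#' Aligns every frame of a series to a reference frame (default: the
#' first) by translation estimated with sub-pixel phase correlation, and
#' resamples the frames accordingly. This suppresses bulk motion and the
#' long-wavelength in-plane translation caused by compression waves,
#' which is why no spatial bandpass filtering is needed before inversion.
#'
#' @param series an [image_series].
#' @param reference_index frame used as the reference (default 1).
#' @param max_shift sanity bound (pixels); estimates beyond it trigger a
#'   warning and an identity transform.
#' @param upsample phase-correlation upsampling factor (sub-pixel
#'   resolution `1/upsample` px).
#'
#' @return A list with `series` (registered [image_series]) and
#'   `transforms` (list of [rigid_transform], one per frame).
#' @export
rigid_register <- function(series, reference_index = 1L, max_shift = 20,
                           upsample = 50L) {
  stopifnot(inherits(series, "image_series"))
  d <- dim(series$frames)
  if (d[3] < 2L) stop("need at least 2 frames to register")
  ref <- series$frames[, , reference_index]
  frames <- series$frames
  transforms <- vector("list", d[3])
  for (j in seq_len(d[3])) {
    if (j == reference_index) {
      transforms[[j]] <- rigid_transform(0, 0)
      next
    }
    sh <- phase_correlation_shift(ref, frames[, , j], upsample = upsample)
    if (!all(is.finite(sh)) || max(abs(sh)) > max_shift) {
      warning(sprintf(
        "registration of frame %d diverged (shift %.2f, %.2f px); using identity",
        j, sh["dx"], sh["dy"]))
      transforms[[j]] <- rigid_transform(0, 0)
      next
    }
    transforms[[j]] <- rigid_transform(dx = unname(sh["dx"]),
                                       dy = unname(sh["dy"]))
    if (any(abs(sh) > 0)) {
      # img(r) = ref(r - s): shifting img by -s undoes the translation.
      # A Fourier shift is the exact translation operator (no
      # interpolation phase error); wrap-around affects only the border.
      frames[, , j] <- fourier_translate(frames[, , j],
                                         dy = -sh["dy"], dx = -sh["dx"])
    }
  }
  frames[frames < 0] <- 0
  out <- image_series(frames, series$frequency, series$phases,
                      series$times, series$pixel_size, series$exposure)
  list(series = out, transforms = transforms)
}

#' Transforms as a data frame
#'
#' @param transforms list of [rigid_transform] (as returned by
#'   [rigid_register]).
#' @return `data.frame` with columns `frame`, `dx`, `dy`, `rotation`.
#' @export
transforms_to_df <- function(transforms) {
  data.frame(
    frame = seq_along(transforms),
    dx = vapply(transforms, function(t) t$dx, 0),
    dy = vapply(transforms, function(t) t$dy, 0),
    rotation = vapply(transforms, function(t) t$rotation, 0)
  )
}
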