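# Internal numerical helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG state afterwards. seed = NULL leaves the
# global stream untouched (and advances it).
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

# Mirror (reflect-without-repeat) index into 1..n: 0 -> 2, n+1 -> n-1.
reflect_index <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  i <- (i - 1L) %% (2L * (n - 1L))
  i <- ifelse(i >= n, 2L * (n - 1L) - i, i)
  as.integer(i + 1L)
}

periodic_index <- function(i, n) as.integer(((i - 1L) %% n) + 1L)

boundary_indexer <- function(boundary = c("mirror", "periodic")) {
  boundary <- match.arg(boundary)
  if (boundary == "mirror") reflect_index else periodic_index
}

# Catmull-Rom cubic interpolation weights for fractional offsets t in [0, 1).
# Returns a length-4 list of weight vectors for taps at offsets -1, 0, 1, 2.
# Weights sum to 1, so integer positions reproduce pixel values exactly.
catmull_rom_weights <- function(t) {
  list(
    ((-t + 2) * t - 1) * t / 2,
    ((3 * t - 5) * t * t + 2) / 2,
    ((-3 * t + 4) * t + 1) * t / 2,
    ((t - 1) * t * t) / 2
  )
}

# Sample matrix `img` at real-valued (row, col) positions with bicubic
# (Catmull-Rom) interpolation. `row`, `col` are equal-length vectors in
# the 1-based pixel-center coordinate system.
interp_bicubic <- function(img, row, col, boundary = "mirror") {
  fix <- boundary_indexer(boundary)
  nr <- nrow(img); nc <- ncol(img)
  r0 <- floor(row); c0 <- floor(col)
  wr <- catmull_rom_weights(row - r0)
  wc <- catmull_rom_weights(col - c0)
  out <- numeric(length(row))
  for (b in -1:2) {
    ci <- fix(c0 + b, nc)
    colw <- wc[[b + 2L]]
    acc <- numeric(length(row))
    for (a in -1:2) {
      ri <- fix(r0 + a, nr)
      acc <- acc + wr[[a + 2L]] * img[ri + (ci - 1L) * nr]
    }
    out <- out + colw * acc
  }
  out
}

# Warp an image by a displacement field given in pixels: the output frame
# at (r, c) samples the input at (r - uy, c - ux) (pull-back), so image
# content moves by +u.
warp_image <- function(img, ux, uy, boundary = "mirror") {
  nr <- nrow(img); nc <- ncol(img)
  rr <- rep(seq_len(nr), times = nc)
  cc <- rep(seq_len(nc), each = nr)
  matrix(interp_bicubic(img, rr - as.vector(uy), cc - as.vector(ux), boundary),
         nr, nc)
}

# Uniform window mean over a (2N+1)x(2N+1) neighborhood with mirror
# boundary handling, computed with an integral image. Works for real and
# complex matrices. exclude_center drops the central pixel from the mean
# (weights still sum to 1).
box_mean <- function(m, N, exclude_center = FALSE) {
  if (N < 1L) stop("window half-width N must be >= 1")
  nr <- nrow(m); nc <- ncol(m)
  ri <- reflect_index((1L - N):(nr + N), nr)
  ci <- reflect_index((1L - N):(nc + N), nc)
  pad <- m[ri, ci, drop = FALSE]
  # integral image with a leading zero row/column
  S <- rbind(0, apply(pad, 2, cumsum))
  S <- cbind(0, t(apply(S, 1, cumsum)))
  w <- 2L * N + 1L
  i1 <- seq_len(nr); j1 <- seq_len(nc)
  sums <- S[i1 + w, j1 + w, drop = FALSE] - S[i1, j1 + w, drop = FALSE] -
    S[i1 + w, j1, drop = FALSE] + S[i1, j1, drop = FALSE]
  if (exclude_center) (sums - m) / (w * w - 1L) else sums / (w * w)
}

# Median of 9 vectors via a sorting network (vectorized 3x3 median).
median9 <- function(p) {
  sw <- function(i, j) {
    lo <- pmin(p[[i]], p[[j]]); hi <- pmax(p[[i]], p[[j]])
    p[[i]] <<- lo; p[[j]] <<- hi
  }
  sw(1, 2); sw(4, 5); sw(7, 8)
  sw(2, 3); sw(5, 6); sw(8, 9)
  sw(1, 2); sw(4, 5); sw(7, 8)
  med3 <- function(a, b, c) pmax(pmin(a, b), pmin(pmax(a, b), c))
  med3(pmax(pmax(p[[1]], p[[4]]), p[[7]]),
       med3(p[[2]], p[[5]], p[[8]]),
       pmin(pmin(p[[3]], p[[6]]), p[[9]]))
}

# Square median filter with mirror boundary; width must be odd. The 3x3
# case uses a vectorized sorting network; larger windows use the exact
# compiled filter.
median_filter2 <- function(m, width) {
  if (width < 2L) return(m)
  if (width %% 2L == 0L) width <- width + 1L
  nr <- nrow(m); nc <- ncol(m)
  if (width == 3L) {
    half <- 1L
    shifts <- vector("list", 9L)
    k <- 0L
    for (dc in -half:half) {
      ci <- reflect_index(seq_len(nc) + dc, nc)
      for (dr in -half:half) {
        ri <- reflect_index(seq_len(nr) + dr, nr)
        k <- k + 1L
        shifts[[k]] <- m[ri, ci, drop = FALSE]
      }
    }
    return(matrix(median9(shifts), nr, nc))
  }
  .median_filter_cpp(m, as.integer(width))
}

# Least-squares harmonic fit of a frame stack against recorded phases.
# Each pixel's time course s_j is modelled as s0 + a*cos(phi_j) -
# b*sin(phi_j); returns the complex coefficient a + i*b (so that s ~
# s0 + Re((a+ib) e^{i phi})) and the temporal mean term.
harmonic_fit <- function(frames, phases) {
  d <- dim(frames)
  if (length(d) != 3L) stop("frames must be a 3-D array [rows, cols, frames]")
  if (d[3] != length(phases)) stop("number of frames and phases differ")
  X <- cbind(1, cos(phases), -sin(phases))
  XtXi <- tryCatch(solve(crossprod(X)), error = function(e)
    stop("phase design is rank-deficient; need >= 3 distinct phases"))
  if (kappa(crossprod(X)) > 1e8)
    stop("phase design is rank-deficient; need >= 3 distinct phases")
  S <- matrix(frames, d[1] * d[2], d[3])
  B <- S %*% (X %*% XtXi)
  list(
    mean = matrix(B[, 1], d[1], d[2]),
    coef = matrix(complex(real = B[, 2], imaginary = B[, 3]), d[1], d[2])
  )
}

# Wavelength of the dominant spatial harmonic in a complex line profile,
# in pixels, via a zero-padded FFT peak.
dominant_wavelength <- function(profile, pad_factor = 32L) {
  n <- length(profile)
  m <- as.integer(pad_factor) * n
  sp <- abs(stats::fft(c(profile - mean(profile), rep(0, m - n))))
  freqs <- c(0:(m %/% 2), -((m - m %/% 2 - 1):1)) / m
  pk <- which.max(sp)
  1 / abs(freqs[pk])
}
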