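#' Solve the heterogeneous 2-D Helmholtz problem for one shear-wave component
#'
#' Computes the steady-state complex displacement field of a time-harmonic
#' shear wave in a heterogeneous 2-D medium by second-order finite
#' differences. The scalar equation per in-plane component is
#' `div(G grad(u)) + rho w^2 u = 0` with a complex shear modulus
#' `G = rho * SWS^2 * (1 + i * loss_factor)`, a uniform-amplitude Dirichlet
#' source line on one boundary edge (top edge for the x-component,
#' left edge for the y-component, i.e., a planar source perpendicular to
#' the main propagation direction), and first-order Sommerfeld (radiation)
#' conditions `du/dn = -i k u` with local `k = w / SWS` on the remaining
#' edges. The solution is linear in `source_amplitude`.
#'
#' The complex sparse system is solved as an equivalent real system of
#' twice the size with a sparse LU factorization.
#'
#' @param map an [sws_field_map] with the SWS distribution.
#' @param frequency drive frequency (Hz).
#' @param component `"x"` or `"y"`; selects the source geometry and the
#'   component slot of the returned field.
#' @param loss_factor dimensionless loss tangent eta of the complex modulus
#'   `G (1 + i eta)`; small positive values damp the waves and keep the
#'   discrete system well conditioned. Default 0.05.
#' @param source_amplitude displacement amplitude on the source line
#'   (micrometres).
#'
#' @return A single-component [complex_wave_field] (micrometres).
#' @export
solve_helmholtz <- function(map, frequency, component = c("x", "y"),
                            loss_factor = 0.05, source_amplitude = 1) {
  stopifnot(inherits(map, "sws_field_map"), frequency > 0, loss_factor >= 0)
  component <- match.arg(component)
  nr <- nrow(map$grid); nc <- ncol(map$grid)
  if (nr < 3L || nc < 3L) stop("grid too small for the 5-point stencil")
  if (source_amplitude == 0) {
    z <- matrix(complex(real = 0, imaginary = 0), nr, nc)
    args <- list(frequency = frequency, pixel_size = map$pixel_size)
    args[[component]] <- z
    return(do.call(complex_wave_field, args))
  }

  h <- map$pixel_size * 1e-6              # m
  rho <- map$density
  omega <- 2 * pi * frequency
  cmap <- map$grid                        # m/s
  G <- rho * cmap^2 * complex(real = 1, imaginary = loss_factor)   # Pa
  kmap <- omega / cmap                    # rad/m (real part, for the BC)

  N <- nr * nc
  idx <- function(i, j) i + (j - 1L) * nr

  # node classification
  is_source <- matrix(FALSE, nr, nc)
  if (component == "x") is_source[1L, ] <- TRUE else is_source[, 1L] <- TRUE

  ii <- rep(seq_len(nr), times = nc)
  jj <- rep(seq_len(nc), each = nr)
  src <- as.vector(is_source)
  interior <- ii > 1L & ii < nr & jj > 1L & jj < nc & !src

  ti <- integer(0); tj <- integer(0); tz <- complex(0)
  push <- function(i, j, z) {
    ti <<- c(ti, i); tj <<- c(tj, j); tz <<- c(tz, z)
  }
  b <- complex(real = numeric(N), imaginary = numeric(N))

  # Dirichlet source line: u = source_amplitude (in metres internally)
  amp_m <- source_amplitude * 1e-6
  ps <- idx(ii[src], jj[src])
  push(ps, ps, rep(complex(real = 1), length(ps)))
  b[ps] <- amp_m

  # interior: flux form, scaled by h^2:
  #   Ge(uE - uC) - Gw(uC - uW) + Gs(uS - uC) - Gn(uC - uN) + rho w^2 h^2 uC = 0
  pi_ <- ii[interior]; pj <- jj[interior]
  pC <- idx(pi_, pj)
  gC <- G[pC]
  gE <- (gC + G[idx(pi_, pj + 1L)]) / 2
  gW <- (gC + G[idx(pi_, pj - 1L)]) / 2
  gS <- (gC + G[idx(pi_ + 1L, pj)]) / 2
  gN <- (gC + G[idx(pi_ - 1L, pj)]) / 2
  push(pC, idx(pi_, pj + 1L), gE)
  push(pC, idx(pi_, pj - 1L), gW)
  push(pC, idx(pi_ + 1L, pj), gS)
  push(pC, idx(pi_ - 1L, pj), gN)
  push(pC, pC, -(gE + gW + gS + gN) + rho * omega^2 * h^2)

  # remaining boundary nodes: first-order Sommerfeld du/dn = -i k u,
  # one-sided difference towards the interior neighbour:
  #   u_b (1 + i k h) - u_neighbour = 0
  bnd <- !src & !interior
  bi <- ii[bnd]; bj <- jj[bnd]
  # inward neighbour: normal of the edge the node sits on; corners use
  # the left/right edge normal
  ni <- bi; nj <- bj
  left <- bj == 1L; right <- bj == nc
  top <- bi == 1L & !left & !right; bottom <- bi == nr & !left & !right
  nj[left] <- 2L; nj[right] <- nc - 1L
  ni[top] <- 2L; ni[bottom] <- nr - 1L
  pB <- idx(bi, bj)
  push(pB, pB, 1 + complex(imaginary = kmap[pB] * h))
  push(pB, idx(ni, nj), rep(complex(real = -1), length(pB)))

  # complex system A u = b as augmented real system
  Ar <- Matrix::sparseMatrix(i = ti, j = tj, x = Re(tz), dims = c(N, N))
  Ai <- Matrix::sparseMatrix(i = ti, j = tj, x = Im(tz), dims = c(N, N))
  Aug <- rbind(cbind(Ar, -Ai), cbind(Ai, Ar))
  rhs <- c(Re(b), Im(b))
  sol <- tryCatch(
    Matrix::solve(Aug, rhs),
    error = function(e) {
      warning("Helmholtz system ill-conditioned (", conditionMessage(e),
              "); retrying with additional damping regularization")
      eps <- rho * omega^2 * h^2 * 1e-3
      AiR <- Ai + Matrix::Diagonal(N, x = eps * as.numeric(interior))
      AugR <- rbind(cbind(Ar, -AiR), cbind(AiR, Ar))
      Matrix::solve(AugR, rhs)
    }
  )
  sol <- as.numeric(sol)
  u <- matrix(complex(real = sol[seq_len(N)], imaginary = sol[N + seq_len(N)]),
              nr, nc)
  u <- u * 1e6                            # back to micrometres
  if (!all(is.finite(Re(u)) & is.finite(Im(u))))
    stop("Helmholtz solve produced non-finite values")
  args <- list(frequency = frequency, pixel_size = map$pixel_size)
  args[[component]] <- u
  do.call(complex_wave_field, args)
}

#' Convert a complex harmonic field to a real-valued time series
#'
#' Samples the harmonic motion `u(r, t) = u' cos(phi) - u'' sin(phi)` at
#' equidistant phases `phi_j = 2 pi j / frames_per_cycle` over `n_cycles`
#' vibration periods, producing `frames_per_cycle * n_cycles` real frames
#' per component.
#'
#' @param field a [complex_wave_field] (one or two components).
#' @param frames_per_cycle frames per vibration cycle (>= 3 so that a
#'   harmonic fit stays identifiable).
#' @param n_cycles number of cycles.
#'
#' @return A list with `frames` (a named list, per component, of 3-D arrays
#'   `[rows, cols, frame]`, in the field's displacement units) and `phases`
#'   (radians, length `frames_per_cycle * n_cycles`).
#' @export
complex_to_time_series <- function(field, frames_per_cycle = 8L,
                                   n_cycles = 3L) {
  stopifnot(inherits(field, "complex_wave_field"), frames_per_cycle >= 3L,
            n_cycles >= 1L)
  nf <- as.integer(frames_per_cycle) * as.integer(n_cycles)
  phases <- 2 * pi * (seq_len(nf) - 1L) / frames_per_cycle
  frames <- lapply(field$components, function(u) {
    d <- dim(u)
    out <- array(0, c(d[1], d[2], nf))
    for (j in seq_len(nf))
      out[, , j] <- Re(u) * cos(phases[j]) - Im(u) * sin(phases[j])
    out
  })
  list(frames = frames, phases = phases %% (2 * pi))
}

#' Add white Gaussian noise scaled to the RMS of a stack
#'
#' Adds zero-mean Gaussian noise with standard deviation
#' `fraction * RMS(frames)` to a frame stack, reproducibly for a fixed
#' seed. The caller's RNG state is left untouched.
#'
#' @param frames numeric array (any shape).
#' @param fraction noise standard deviation as a fraction of the clean
#'   stack's root-mean-square value.
#' @param seed integer seed, or `NULL` to draw from the global stream.
#'
#' @return The noisy array, same shape as the input.
#' @export
add_white_noise <- function(frames, fraction, seed = NULL) {
  stopifnot(fraction >= 0)
  if (fraction == 0) return(frames)
  sigma <- fraction * sqrt(mean(frames^2))
  noise <- with_seed(seed, stats::rnorm(length(frames), sd = sigma))
  frames + array(noise, dim = if (is.null(dim(frames))) length(frames)
                 else dim(frames))
}
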