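test_that("kernel size scales inversely with pixel size", {
  expect_identical(hof_kernel_size(2), 32L)
  expect_identical(hof_kernel_size(4), 16L)
  expect_identical(hof_kernel_size(10), 6L)   # round(6.4)
  expect_identical(hof_kernel_size(30), 3L)   # clamped
})

test_that("neighborhood average matches a brute-force windowed mean", {
  # trivial contracts
  expect_equal(neighborhood_average(matrix(3.5, 10, 12), 2),
               matrix(3.5, 10, 12))
  ramp <- outer(1:20, 1:20, function(i, j) 2 * i - 3 * j)
  av <- neighborhood_average(ramp, 3)
  expect_equal(av[4:17, 4:17], ramp[4:17, 4:17], tolerance = 1e-12)

  set.seed(12)
  m <- matrix(complex(real = rnorm(32 * 32), imaginary = rnorm(32 * 32)),
              32, 32)
  N <- 2L
  brute <- matrix(0 + 0i, 32, 32)
  for (i in 1:32) for (j in 1:32) {
    acc <- 0 + 0i
    for (a in -N:N) for (b in -N:N) {
      if (a == 0 && b == 0) next
      ia <- opelast:::reflect_index(i + a, 32L)
      jb <- opelast:::reflect_index(j + b, 32L)
      acc <- acc + m[ia, jb]
    }
    brute[i, j] <- acc / ((2 * N + 1)^2 - 1)
  }
  expect_equal(neighborhood_average(m, N), brute, tolerance = 1e-12)
})

test_that("structure terms match a direct projection oracle", {
  set.seed(14)
  nr <- 24; nc <- 24
  phases <- (2 * pi * 1000 / 4500 * (0:23)) %% (2 * pi)
  I0 <- test_speckle(nr, nc, seed = 9)
  g <- matrix(rnorm(nr * nc, sd = 0.05), nr, nc)
  frames <- array(0, c(nr, nc, 24))
  for (j in 1:24) frames[, , j] <- I0 + cos(phases[j]) * g
  terms <- harmonic_structure_terms(frames, phases)

  # temporally constant series: zero right-hand side
  const <- array(I0, c(nr, nc, 24))
  tc <- harmonic_structure_terms(const, phases)
  expect_lt(max(Mod(tc$rhs$x)), 1e-10)
  expect_lt(max(Mod(tc$rhs$y)), 1e-10)

  # oracle: per-pixel least squares of (dI/dphi * gradI) on the harmonic
  # regressors, with dI/dphi from the analytic derivative of the fit of I
  X <- cbind(1, cos(phases), -sin(phases))
  P <- X %*% solve(crossprod(X))
  gradI <- function(I) {
    nc_ <- ncol(I); nr_ <- nrow(I)
    Ix <- (I[, opelast:::reflect_index(2:(nc_ + 1), nc_)] -
             I[, opelast:::reflect_index(0:(nc_ - 1), nc_)]) / 2
    Iy <- (I[opelast:::reflect_index(2:(nr_ + 1), nr_), ] -
             I[opelast:::reflect_index(0:(nr_ - 1), nr_), ]) / 2
    list(x = Ix, y = Iy)
  }
  S <- matrix(frames, nr * nc, 24)
  B <- S %*% P
  chat <- complex(real = B[, 2], imaginary = B[, 3])
  for (comp in c("x", "y")) {
    W <- matrix(0, nr * nc, 24)
    for (j in 1:24) {
      gi <- gradI(frames[, , j])[[comp]]
      dphi <- Re(1i * chat * exp(1i * phases[j]))
      W[, j] <- dphi * as.vector(gi)
    }
    BW <- W %*% P
    oracle <- matrix(complex(real = BW[, 2], imaginary = BW[, 3]) / 1i,
                     nr, nc)
    got <- terms$rhs[[comp]]
    expect_lt(max(Mod(got - oracle)) / max(Mod(oracle)), 1e-10)
  }

  # tensor is positive semidefinite everywhere
  ev_min <- with(terms$tensor,
                 (t11 + t22 - sqrt((t11 - t22)^2 + 4 * t12^2)) / 2)
  expect_gte(min(ev_min), -1e-12)
})

test_that("zero-motion movies decode to a zero field", {
  img <- test_speckle(48, 48)
  series <- image_series(array(img, c(48, 48, 8)), 1000,
                         2 * pi * (0:7) / 8, NULL, pixel_size = 30)
  dec <- solve_hof(series)
  expect_lt(max(Mod(dec$components$x)), 1e-9)
  expect_lt(max(Mod(dec$components$y)), 1e-9)
})

test_that("encoded plane waves decode with high fidelity", {
  fld <- plane_wave_field(120, 120, h = 30, lambda_px = 40)
  mov <- test_movie(fld)
  dec <- solve_hof(mov)
  truth <- plane_wave_field(120, 120, h = 30, lambda_px = 40,
                            amp_px = 0.1)
  fid <- field_fidelity(dec, truth)
  expect_gt(fid$corr, 0.95)
  expect_lt(abs(fid$amp_ratio - 1), 0.1)
})

test_that("decoding is linear in the encoded amplitude", {
  fld <- plane_wave_field(100, 100, h = 30, lambda_px = 36)
  img <- test_speckle(100, 100)
  m1 <- test_movie(fld, img, amplitude_scale = 0.1)
  m2 <- test_movie(fld, img, amplitude_scale = 0.05)
  d1 <- solve_hof(m1); d2 <- solve_hof(m2)
  r <- sqrt(sum(Mod(d2$components$y[20:80, 20:80])^2) /
              sum(Mod(d1$components$y[20:80, 20:80])^2))
  expect_lt(abs(r - 0.5) / 0.5, 0.05)
})

test_that("stroboscopic (aliased) and unaliased sampling decode alike", {
  # 2400 Hz wave: 4500 fps is sub-Nyquist (aliased), 19200 fps samples
  # 8 frames per true cycle
  fld <- plane_wave_field(100, 100, h = 30, lambda_px = 36,
                          frequency = 2400)
  img <- test_speckle(100, 100)
  m_alias <- test_movie(fld, img, frame_rate = 4500)
  m_fast <- test_movie(fld, img, frame_rate = 19200)
  d1 <- solve_hof(m_alias); d2 <- solve_hof(m_fast)
  ri <- 16:85
  num <- sqrt(sum(Mod(d1$components$y[ri, ri] - d2$components$y[ri, ri])^2))
  den <- sqrt(sum(Mod(d2$components$y[ri, ri])^2))
  expect_lt(num / den, 0.02)
})
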