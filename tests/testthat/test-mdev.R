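grid_xy <- function(nr, nc) {
  list(r = matrix(rep(seq_len(nr), times = nc), nr, nc),
       c = matrix(rep(seq_len(nc), each = nr), nr, nc))
}

test_that("long-lag gradient is exact on linear fields and matches the sum oracle", {
  h <- 25
  sch <- gradient_scheme(s1 = 4, s2 = 4, r1 = 0, r2 = 0, pixel_size = h)
  g <- grid_xy(40, 40)
  hm <- h * 1e-6
  lin <- 3 * g$c * hm - 2 * g$r * hm
  fg <- finite_gradient(lin, sch)
  expect_equal(unique(round(as.vector(fg$gx[fg$mask]), 9)), 3)
  expect_equal(unique(round(as.vector(fg$gy[fg$mask]), 9)), -2)

  # brute-force double-sum evaluation with averaging neighborhoods
  set.seed(21)
  m <- matrix(complex(real = rnorm(1600), imaginary = rnorm(1600)), 40, 40)
  s1 <- 3L; s2 <- 2L; r1 <- 1L; r2 <- 2L
  schm <- gradient_scheme(s1, s2, r1, r2, pixel_size = h)
  got <- finite_gradient(m, schm)
  norm <- 2 * (2 * r1 + 1) * (2 * r2 + 1)
  for (k in c(8, 15, 33)) for (l in c(9, 20, 31)) {
    sa <- 0 + 0i; sb <- 0 + 0i
    for (mm in -r1:r1) for (nn in -r2:r2) {
      sa <- sa + (m[k + nn + s1, l + mm] - m[k + nn - s1, l + mm])
      sb <- sb + (m[k + nn, l + mm + s2] - m[k + nn, l + mm - s2])
    }
    expect_equal(got$gy[k, l], sa / (norm * s1 * hm), tolerance = 1e-12)
    expect_equal(got$gx[k, l], sb / (norm * s2 * hm), tolerance = 1e-12)
  }

  # plane wave: long-lag response sin(k s h)/(s h)
  lam_px <- 90; k <- 2 * pi / (lam_px * hm)
  pw <- exp(1i * k * g$c * hm)
  fp <- finite_gradient(pw, sch)
  keff <- sin(k * 4 * hm) / (4 * hm)
  ratio <- fp$gx[fp$mask] / (1i * k * pw[fp$mask])
  expect_equal(unique(round(ratio, 9)), complex(real = round(keff / k, 9)))
  expect_lt(abs(keff / k - 1), 0.02)   # k*s*h < 0.3 regime
})

test_that("gradient with unit lags reduces to the central difference", {
  set.seed(3)
  m <- matrix(rnorm(400), 20, 20)
  h <- 10; hm <- h * 1e-6
  sch <- gradient_scheme(1, 1, 0, 0, pixel_size = h)
  fg <- finite_gradient(m, sch)
  i <- 5:16; j <- 4:17
  expect_equal(fg$gx[i, j], (m[i, j + 1] - m[i, j - 1]) / (2 * hm),
               tolerance = 1e-12)
  expect_equal(fg$gy[i, j], (m[i + 1, j] - m[i - 1, j]) / (2 * hm),
               tolerance = 1e-12)
  expect_error(finite_gradient(m[1:5, 1:5],
                               gradient_scheme(10, 10, 0, 0, 10)),
               "stencil")
})

test_that("Laplacian is exact on quadratics and has the lagged second-difference response", {
  h <- 20; hm <- h * 1e-6
  g <- grid_xy(60, 60)
  quad <- (g$c * hm)^2 + (g$r * hm)^2
  sch <- gradient_scheme(5, 5, 0, 0, pixel_size = h)
  L <- laplacian(quad, sch)
  expect_lt(max(abs(L$lap[L$mask] - 4)) / 4, 0.01)
  expect_equal(max(abs(laplacian(matrix(1, 30, 30),
                                 gradient_scheme(3, 3, 0, 0, h))$lap),
                   na.rm = TRUE), 0)

  lam_px <- 40; k <- 2 * pi / (lam_px * hm)
  pw <- exp(1i * k * g$c * hm)
  L2 <- laplacian(pw, sch)
  keff <- 2 * sin(k * 5 * hm / 2) / (5 * hm)
  ratio <- L2$lap[L2$mask] / (-k^2 * pw[L2$mask])
  expect_equal(Mod(unique(round(ratio, 9))), round(keff^2 / k^2, 9))

  # small-lag regime: within 2% of the continuum -k^2
  sch1 <- gradient_scheme(1, 1, 0, 0, pixel_size = h)
  L3 <- laplacian(pw, sch1)
  expect_lt(max(Mod(L3$lap[L3$mask] + k^2 * pw[L3$mask])) / k^2, 0.02)

  # unit lag reduces to the 5-point Laplacian
  set.seed(6)
  m <- matrix(rnorm(400), 20, 20)
  L4 <- laplacian(m, gradient_scheme(1, 1, 0, 0, h))
  i <- 3:18
  five <- (m[i + 1, i] + m[i - 1, i] + m[i, i + 1] + m[i, i - 1] -
             4 * m[i, i]) / hm^2
  expect_equal(L4$lap[i, i], five, tolerance = 1e-9)
})

test_that("MDEV recovers the modulus of analytic plane waves", {
  h <- 25; hm <- h * 1e-6
  g <- grid_xy(120, 120)
  c0 <- 3; rho <- 1000
  mk_wave <- function(f, lam_px) {
    k <- 2 * pi / (lam_px * hm)
    complex_wave_field(x = 0.5 * exp(-1i * k * g$c * hm),
                       frequency = f, pixel_size = h)
  }
  # frequency chosen so that c = lambda * f = 3 m/s
  lam_px <- 48; lam_m <- lam_px * hm; f <- c0 / lam_m
  sch <- gradient_scheme(5, 5, 0, 0, pixel_size = h)
  w1 <- mk_wave(f, lam_px)
  mm <- mdev_modulus(w1, density = rho, scheme = sch)
  expected <- rho * c0^2
  vals <- mm$magnitude[mm$mask]
  expect_lt(max(abs(vals - expected)) / expected, 0.05)

  # two frequencies in the same medium: the compound estimator agrees
  # with each single-frequency inversion (short lags, where the
  # derivative response is essentially flat)
  sch1 <- gradient_scheme(1, 1, 0, 0, pixel_size = h)
  lam2 <- 30; f2 <- c0 / (lam2 * hm)
  w2 <- mk_wave(f2, lam2)
  m1s <- mdev_modulus(w1, density = rho, scheme = sch1)
  mcs <- mdev_modulus(list(w1, w2), density = rho, scheme = sch1)
  mid <- m1s$mask & mcs$mask
  expect_lt(max(abs(mcs$magnitude[mid] - m1s$magnitude[mid])) / expected,
            0.01)
})

test_that("frequency compounding stabilizes standing-wave nodes", {
  h <- 25; hm <- h * 1e-6
  nr <- 120; nc <- 120
  g <- grid_xy(nr, nc)
  c0 <- 3; rho <- 1000
  mk_standing <- function(lam_px, x0) {
    k <- 2 * pi / (lam_px * hm)
    f <- c0 * k / (2 * pi)
    u <- matrix(complex(real = cos(k * (g$c - x0) * hm)), nr, nc)
    complex_wave_field(x = u, frequency = f, pixel_size = h)
  }
  # displaced node lines; a whiff of decode-like noise makes the nodes of
  # the single-frequency inversion unstable
  set.seed(77)
  w1 <- mk_standing(44, 0); w2 <- mk_standing(31, 11)
  noisy <- function(w) {
    w$components$x <- w$components$x +
      matrix(complex(real = rnorm(nr * nc, sd = 5e-4),
                     imaginary = rnorm(nr * nc, sd = 5e-4)), nr, nc)
    w
  }
  w1 <- noisy(w1); w2 <- noisy(w2)
  sch <- gradient_scheme(3, 3, 0, 0, pixel_size = h)
  s1 <- mdev_modulus(w1, density = rho, scheme = sch)
  comp <- mdev_modulus(list(w1, w2), density = rho, scheme = sch)
  expected <- rho * c0^2
  # single frequency: large relative errors near its node lines
  err1 <- abs(s1$magnitude - expected) / expected
  expect_gt(max(err1[s1$mask]), 0.5)
  # compound: stable everywhere off the border
  errc <- abs(comp$magnitude - expected) / expected
  expect_lt(stats::quantile(errc[comp$mask], 0.99), 0.1)
})

test_that("SWS maps follow sqrt(|G*|/rho) with mask propagation", {
  mag <- matrix(c(2250, 0, 1000, NA), 2, 2)
  mask <- matrix(c(TRUE, TRUE, TRUE, FALSE), 2, 2)
  mm <- modulus_map(mag, mask, density = 1000, frequencies = 1000,
                    pixel_size = 10)
  sws <- sws_from_modulus(mm)
  expect_equal(sws$grid[1, 1], 1.5)
  expect_equal(sws$grid[2, 1], 0)
  expect_equal(sws$grid[1, 2], 1)
  expect_true(is.na(sws$grid[2, 2]))
})
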