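test_that("modulus conversions reproduce the published reference points", {
  # AFM Young's modulus 1.97 kPa -> 0.81 m/s
  expect_equal(round(modulus_to_sws(1970, "young"), 2), 0.81)
  # E. coli biofilm Young's modulus 500 kPa -> 12.9 m/s
  expect_equal(round(modulus_to_sws(5e5, "young"), 1), 12.9)
  # storage modulus 2250 Pa -> 1.5 m/s
  expect_equal(round(modulus_to_sws(2250, "storage"), 2), 1.5)
  # bulk rheology range 56-309 Pa -> 0.23-0.56 m/s (lower bound printed
  # truncated: sqrt(56/1000) = 0.2366)
  expect_equal(round(modulus_to_sws(309, "storage"), 2), 0.56)
  expect_lt(abs(modulus_to_sws(56, "storage") - 0.23), 0.01)
  expect_error(modulus_to_sws(-5, "storage"), "non-negative")
  # round trip with the inversion convention
  sws <- c(0.5, 1.5, 4.2)
  expect_equal(modulus_to_sws(1000 * sws^2, "storage"), sws,
               tolerance = 1e-12)
})

test_that("waves-per-image bookkeeping matches the simulation geometry", {
  # 500 px x 29.609 um at 3.9 kHz in a 1 m/s medium: 57.7 waves
  expect_lt(abs(waves_per_image(500, 29.609, 3900, 1) - 57.7), 0.1)
  # low end of the simulated range: 0.2 kHz -> 2.96 waves
  expect_lt(abs(waves_per_image(500, 29.609, 200, 1) - 2.96), 0.01)
})

test_that("wavelet SNR estimate tracks known noise levels", {
  set.seed(41)
  nr <- 128; nc <- 128
  cc <- matrix(rep(1:nc, each = nr), nr, nc)
  clean <- 3 * exp(-1i * 2 * pi / 40 * cc)
  sigma <- 0.05
  noise <- matrix(complex(real = rnorm(nr * nc, sd = sigma),
                          imaginary = rnorm(nr * nc, sd = sigma)), nr, nc)
  fld <- complex_wave_field(x = clean + noise, frequency = 1000,
                            pixel_size = 10)
  rms <- sqrt(mean(c(Re(clean + noise)^2, Im(clean + noise)^2)))
  expect_lt(abs(donoho_snr(fld) - 20 * log10(rms / sigma)), 3)

  # doubling the wave amplitude at fixed noise adds 6 dB
  fld2 <- complex_wave_field(x = 2 * clean + noise, frequency = 1000,
                             pixel_size = 10)
  expect_lt(abs((donoho_snr(fld2) - donoho_snr(fld)) - 6), 0.5)

  # pure noise: RMS equals sigma, SNR ~ 0 dB
  pn <- complex_wave_field(x = noise, frequency = 1000, pixel_size = 10)
  expect_lt(abs(donoho_snr(pn)), 3)

  z <- complex_wave_field(x = matrix(0i, 8, 8), frequency = 1,
                          pixel_size = 1)
  expect_identical(donoho_snr(z), -Inf)
})

test_that("profile fits recover SWS from damped plane and Bessel profiles", {
  # lambda = 2 mm at 1000 Hz -> SWS = 2 m/s
  x_um <- seq(0, 8000, by = 25)
  k <- 2 * pi / 2000e-6
  v <- (1.3 - 0.4i) * exp(-1i * k * x_um * 1e-6 - 60 * x_um * 1e-6)
  fit <- profile_fit_sws(v, x_um, 1000, model = "plane")
  expect_lt(abs(fit$sws - 2) / 2, 0.01)

  # Bessel radial profile with known wavenumber
  r_um <- seq(0, 6000, by = 20)
  kb <- 2 * pi / 1500e-6
  vb <- 0.8 * besselJ(kb * r_um * 1e-6, 0) * exp(-40 * r_um * 1e-6)
  fitb <- profile_fit_sws(vb, r_um, 1200, model = "bessel")
  expect_lt(abs(fitb$sws - 2 * pi * 1200 / kb) / (2 * pi * 1200 / kb),
            0.02)

  # robustness: 10% additive noise, Monte-Carlo over seeds
  for (sd_ in 1:4) {
    set.seed(sd_)
    rmsv <- sqrt(mean(Mod(v)^2))
    vn <- v + complex(real = rnorm(length(v), sd = 0.1 * rmsv),
                      imaginary = rnorm(length(v), sd = 0.1 * rmsv))
    fn <- profile_fit_sws(vn, x_um, 1000, model = "plane")
    expect_lt(abs(fn$sws - 2) / 2, 0.05)
  }
})

test_that("profile fits are unbiased across the wavelength range", {
  for (lam_px in c(10, 40, 120, 200)) {
    n <- max(4 * lam_px, 240)
    x_um <- (seq_len(n) - 1) * 20
    k <- 2 * pi / (lam_px * 20e-6)
    v <- exp(-1i * k * x_um * 1e-6 - 10 * x_um * 1e-6)
    f <- 1000
    fit <- profile_fit_sws(v, x_um, f, model = "plane")
    expect_lt(abs(fit$k - k) / k, 0.01)
  }
})

test_that("region statistics equal brute-force masked averages", {
  set.seed(55)
  g <- matrix(rnorm(400, 3), 20, 20)
  g[sample(400, 30)] <- NA
  lab <- matrix(sample(0:2, 400, replace = TRUE), 20, 20)
  st <- region_stats(g, lab)
  for (l in 0:2) {
    v <- g[lab == l]; v <- v[!is.na(v)]
    expect_equal(st$mean[st$label == l], mean(v))
    expect_equal(st$sd[st$label == l], sd(v))
    expect_equal(st$n[st$label == l], length(v))
  }
  expect_equal(sum(st$n), sum(!is.na(g)))
  # constant and empty regions
  cm <- matrix(2.5, 6, 6)
  lb <- matrix(0L, 6, 6); lb[1, 1] <- 1L
  cm[1, 1] <- NA
  stc <- region_stats(cm, lb)
  expect_equal(stc$mean[stc$label == 0], 2.5)
  expect_equal(stc$sd[stc$label == 0], 0)
  expect_equal(stc$n[stc$label == 1], 0)
  expect_true(is.na(stc$mean[stc$label == 1]))
})
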