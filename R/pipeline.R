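#' Configuration for the reference two-inclusion simulation experiment
#'
#' Assembles the full run configuration of the synthetic reference
#' experiment: a piecewise-constant two-inclusion phantom (soft inclusion
#' 2.7 m/s, background 3.6 m/s, stiff inclusion 4.5 m/s) simulated at the
#' twelve drive frequencies 0.8-2.4 kHz, encoded as 24-frame speckle
#' movies with peak displacement 10% of the pixel size and 10% white
#' noise on the displacement series, HOF-decoded and MDEV-inverted with
#' frequency compounding over the 800-2400 Hz band.
#'
#' `grid_scale` scales the grid down from the 500 x 500 px / 29.609 um
#' reference while keeping the physical field of view (and hence the
#' number of waves per image) constant; the long-lag derivative kernel is
#' scaled with it so the derivative transfer function is unchanged.
#'
#' @param grid_scale grid scaling factor (1 = 500 x 500 px; 0.5 = 250 x
#'   250 px at doubled pixel size).
#' @param frequencies drive frequencies (Hz).
#' @param seed base seed for speckle and noise generation.
#' @param noise_fraction white-noise fraction on the displacement series.
#' @param amplitude_scale peak displacement as a fraction of pixel size.
#' @param loss_factor loss tangent of the simulation medium.
#' @param equalize,register apply per-frame CLAHE / rigid registration
#'   before decoding. Registration defaults to on (it cancels bulk motion
#'   and compression-wave translations). Equalization defaults to off for
#'   synthetic runs: it exists to remove illumination changes in real
#'   acquisitions, and its nonlinear per-frame remapping perturbs
#'   brightness constancy on uniformly lit synthetic movies.
#' @param band frequency band (Hz) compounded into the final SWS map.
#' @param out_dir optional output directory for maps, tables and
#'   provenance.
#'
#' @return A `run_config` list.
#' @export
reference_config <- function(grid_scale = 1,
                        frequencies = c(800, 900, 1000, 1100, 1200, 1300,
                                        1400, 1500, 1700, 1900, 2100, 2400),
                        seed = 1L,
                        noise_fraction = 0.1,
                        amplitude_scale = 0.1,
                        loss_factor = 0.05,
                        equalize = FALSE,
                        register = TRUE,
                        band = c(800, 2400),
                        out_dir = NULL) {
  stopifnot(grid_scale > 0, grid_scale <= 1)
  n <- as.integer(round(500 * grid_scale))
  h <- 29.609 * 500 / n
  rad <- 0.12 * n
  cfg <- list(
    shape = c(n, n),
    pixel_size = h,
    background_sws = 3.6,
    inclusions = list(
      list(center = c(0.30 * n, 0.30 * n), radius = rad, sws = 2.7),
      list(center = c(0.70 * n, 0.70 * n), radius = rad, sws = 4.5)
    ),
    density = 1000,
    frequencies = frequencies,
    frame_rate = 4500,
    frames_per_cycle = 8L,
    n_cycles = 3L,
    skip_cycles = 4L,
    noise_fraction = noise_fraction,
    amplitude_scale = amplitude_scale,
    feature_density = 0.2,
    feature_fwhm = 2,
    loss_factor = loss_factor,
    hof = hof_config(),
    scheme_s = max(1L, as.integer(round(10 * grid_scale))),
    scheme_r = 1L,
    band = band,
    equalize = equalize,
    register = register,
    quantize = TRUE,
    seed = as.integer(seed),
    out_dir = out_dir
  )
  class(cfg) <- "run_config"
  cfg
}

config_phantom <- function(config) {
  build_two_inclusion_phantom(config$shape, config$pixel_size,
                              config$background_sws, config$inclusions,
                              density = config$density)
}

#' Simulate the multifrequency wave fields of a run configuration
#'
#' Solves the heterogeneous Helmholtz problem for both in-plane
#' components at every configured frequency. The result is deterministic
#' given the phantom, so it can be reused across encoding seeds.
#'
#' @param config a `run_config` (see [reference_config]).
#' @param phantom optional precomputed [sws_field_map].
#' @param verbose print progress.
#' @return List of two-component [complex_wave_field], one per frequency.
#' @export
simulate_run_fields <- function(config, phantom = NULL, verbose = FALSE) {
  if (is.null(phantom)) phantom <- config_phantom(config)
  lapply(config$frequencies, function(f) {
    if (verbose) message(sprintf("  simulating %g Hz", f))
    fx <- solve_helmholtz(phantom, f, "x", config$loss_factor)
    fy <- solve_helmholtz(phantom, f, "y", config$loss_factor)
    merge_wave_fields(fx, fy)
  })
}

# preprocessing + HOF decoding of one movie (normalize, register, decode)
decode_series <- function(series, config) {
  frames <- series$frames
  if (isTRUE(config$equalize)) {
    for (j in seq_len(dim(frames)[3]))
      frames[, , j] <- equalize(frames[, , j])
    series <- image_series(frames, series$frequency, series$phases,
                           series$times, series$pixel_size,
                           series$exposure)
  }
  if (isTRUE(config$register)) {
    series <- rigid_register(series)$series
  }
  solve_hof(series, config = config$hof)
}

#' Run the end-to-end two-inclusion reference experiment
#'
#' Simulate -> encode -> preprocess -> decode -> invert on the
#' configured phantom: simulates both wave components at all
#' frequencies, encodes them into noisy speckle movies under the
#' stroboscopic schedule, decodes the complex displacement fields with
#' harmonic optical flow, inverts per frequency and compounds over the
#' configured band, and reports region statistics and the
#' frequency-resolved region curves.
#'
#' @param config a `run_config` from [reference_config].
#' @param fields optional precomputed simulation fields (from
#'   [simulate_run_fields]) to reuse across seeds.
#' @param verbose print stage progress.
#'
#' @return List with `phantom`, `schedule`, `fields`, `decoded`,
#'   `modulus`, `sws_compound` ([sws_field_map] with phantom labels),
#'   `stats` (region means of the compound map), `freq_curves`
#'   (per-frequency, per-region SWS means), `sws_single` (per-frequency
#'   maps) and `config`.
#' @export
run_reference_experiment <- function(config = reference_config(), fields = NULL,
                                   verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
  }
  phantom <- stage("phantom", config_phantom(config))
  if (is.null(fields))
    fields <- stage("wavesim",
                    simulate_run_fields(config, phantom, verbose))
  schedule <- stage("schedule",
                    build_schedule(config$frequencies, config$frame_rate,
                                   config$frames_per_cycle, config$n_cycles,
                                   config$skip_cycles))
  speckle <- stage("encoder", make_speckle_image(
    config$shape,
    n_features = as.integer(round(config$feature_density *
                                    prod(config$shape))),
    feature_fwhm = config$feature_fwhm, seed = config$seed))

  decoded <- vector("list", length(fields))
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    if (verbose) message(sprintf("  encoding/decoding %g Hz", f$frequency))
    movie <- stage("encoder", encode_motion(
      speckle, f, schedule, amplitude_scale = config$amplitude_scale,
      noise_fraction = config$noise_fraction,
      seed = (config$seed + 7919L * i) %% .Machine$integer.max,
      quantize = isTRUE(config$quantize)))
    decoded[[i]] <- stage("hof", decode_series(movie, config))
  }

  invert_results <- stage("mdev",
                          invert_decoded(decoded, phantom$labels, config))
  out <- c(list(config = config, phantom = phantom, schedule = schedule,
                fields = fields, decoded = decoded),
           invert_results)
  if (!is.null(config$out_dir)) write_run_outputs(out, config$out_dir)
  out
}

# per-frequency + compound MDEV inversion and region summaries
invert_decoded <- function(decoded, labels, config) {
  h <- decoded[[1]]$pixel_size
  scheme <- gradient_scheme(s1 = config$scheme_s, s2 = config$scheme_s,
                            r1 = config$scheme_r, r2 = config$scheme_r,
                            pixel_size = h)
  sws_single <- lapply(decoded, function(f) {
    sws_from_modulus(mdev_modulus(f, density = config$density,
                                  scheme = scheme), labels = labels)
  })
  curves <- NULL
  if (!is.null(labels)) {
    curves <- do.call(rbind, lapply(seq_along(decoded), function(i) {
      st <- region_stats(sws_single[[i]], labels)
      st$frequency <- decoded[[i]]$frequency
      st
    }))
  }
  freqs <- vapply(decoded, function(f) f$frequency, 0)
  in_band <- freqs >= config$band[1] & freqs <= config$band[2]
  if (!any(in_band)) stop("no decoded frequency falls inside the band")
  modulus <- mdev_modulus(decoded[in_band], density = config$density,
                          scheme = scheme)
  sws_compound <- sws_from_modulus(modulus, labels = labels)
  stats <- if (!is.null(labels)) region_stats(sws_compound, labels) else NULL
  list(modulus = modulus, sws_compound = sws_compound,
       sws_single = sws_single, stats = stats, freq_curves = curves)
}

#' Decode and invert externally supplied movies
#'
#' Runs the preprocess -> HOF -> MDEV path on movies stored on disk
#' (written by [write_image_series]) against a stored acquisition
#' schedule. The movies must match the schedule: every movie frequency
#' must be listed in the schedule and carry the matching recorded
#' phases; mismatches are rejected before any computation.
#'
#' @param movie_paths character vector of path prefixes (as accepted by
#'   [read_image_series]).
#' @param schedule_path JSON schedule file (see [write_schedule]).
#' @param config a `run_config`; geometry fields are ignored, the
#'   preprocessing, HOF, scheme and band settings are used.
#' @param labels optional region label matrix for the statistics.
#'
#' @return As [run_reference_experiment], without `phantom` and `fields`.
#' @export
run_decode_invert <- function(movie_paths, schedule_path,
                              config = reference_config(), labels = NULL) {
  schedule <- read_schedule(schedule_path)
  series_list <- lapply(movie_paths, read_image_series)
  for (s in series_list) {
    entry <- tryCatch(schedule_entry(schedule, s$frequency),
                      error = function(e)
                        stop("movie/schedule mismatch: ",
                             conditionMessage(e), call. = FALSE))
    if (length(entry$phases) != length(s$phases) ||
        max(abs(entry$phases - s$phases)) > 1e-9)
      stop(sprintf(
        "movie/schedule mismatch: recorded phases at %g Hz disagree",
        s$frequency), call. = FALSE)
  }
  d <- dim(series_list[[1]]$frames)
  for (s in series_list) {
    if (!all(dim(s$frames)[1:2] == d[1:2]))
      stop("movies do not share one frame shape", call. = FALSE)
  }
  decoded <- lapply(series_list, decode_series, config = config)
  c(list(config = config, schedule = schedule, decoded = decoded),
    invert_decoded(decoded, labels, config))
}

# write maps, tables and a provenance record for a finished run
write_run_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sws <- result$sws_compound$grid
  vmax <- max(sws, na.rm = TRUE)
  img <- sws / vmax
  img[is.na(img)] <- 0
  tiff::writeTIFF(img, file.path(out_dir, "sws_compound.tif"),
                  bits.per.sample = 16L)
  if (!is.null(result$stats))
    utils::write.csv(result$stats, file.path(out_dir, "region_stats.csv"),
                     row.names = FALSE)
  if (!is.null(result$freq_curves))
    utils::write.csv(result$freq_curves,
                     file.path(out_dir, "freq_curves.csv"),
                     row.names = FALSE)
  prov <- list(
    package = "opelast",
    version = as.character(utils::packageVersion("opelast")),
    r_version = R.version.string,
    config = result$config[setdiff(names(result$config),
                                   c("hof", "inclusions"))],
    hof = unclass(result$config$hof),
    inclusions = result$config$inclusions,
    timestamp = format(Sys.time(), tz = "UTC")
  )
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  invisible(out_dir)
}
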