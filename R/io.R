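#' Write an image series as a multi-page TIFF with a JSON sidecar
#'
#' Frames are stored as 16-bit TIFF pages (normalized by the stack
#' maximum, which is recorded in the sidecar), so a series whose frames
#' were quantized to 16-bit levels (the encoder default) round-trips
#' bit-exactly. The sidecar carries the frequency, capture times, phases,
#' pixel size and exposure tag.
#'
#' @param series an [image_series].
#' @param path_prefix output path without extension; writes
#'   `<prefix>.tif` and `<prefix>.json`.
#' @return The prefix, invisibly.
#' @export
write_image_series <- function(series, path_prefix) {
  stopifnot(inherits(series, "image_series"))
  d <- dim(series$frames)
  vmax <- max(series$frames)
  # power-of-two full scale: exact to rescale, exact to store in JSON
  scale_exp <- if (vmax > 0) ceiling(log2(vmax)) else 0
  S <- 2^scale_exp
  lev <- 65535
  pages <- lapply(seq_len(d[3]), function(j) {
    k <- round(series$frames[, , j] / S * lev)
    # the TIFF writer truncates; a half-level offset makes it exact
    pmin((k + 0.5) / lev, 1)
  })
  tiff::writeTIFF(pages, paste0(path_prefix, ".tif"),
                  bits.per.sample = 16L)
  # doubles serialized with 17 significant digits survive the JSON round
  # trip bit-exactly
  meta <- list(
    frequency = series$frequency,
    phases = sprintf("%.17g", series$phases),
    times = if (is.null(series$times)) NULL
            else sprintf("%.17g", series$times),
    pixel_size = series$pixel_size,
    exposure = series$exposure,
    scale_exponent = scale_exp,
    shape = d
  )
  jsonlite::write_json(meta, paste0(path_prefix, ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path_prefix)
}

#' Read an image series written by [write_image_series]
#'
#' @param path_prefix path without extension.
#' @return An [image_series].
#' @export
read_image_series <- function(path_prefix) {
  meta <- jsonlite::read_json(paste0(path_prefix, ".json"),
                              simplifyVector = TRUE)
  pages <- tiff::readTIFF(paste0(path_prefix, ".tif"), all = TRUE)
  if (is.matrix(pages)) pages <- list(pages)
  d <- c(dim(pages[[1]]), length(pages))
  S <- 2^meta$scale_exponent
  frames <- array(0, d)
  for (j in seq_along(pages)) frames[, , j] <- pages[[j]] * S
  image_series(frames, meta$frequency, as.numeric(meta$phases),
               times = if (is.null(meta$times)) NULL
                       else as.numeric(meta$times),
               pixel_size = meta$pixel_size,
               exposure = meta$exposure)
}

#' Write a set of complex wave fields to an array container
#'
#' Stores per-frequency, per-component real and imaginary displacement
#' planes plus their attributes (frequency, pixel size, and any
#' simulation metadata) in one R serialization file. An optional ground
#' truth map can be stored alongside.
#'
#' @param fields list of [complex_wave_field].
#' @param path output file (conventionally `.rds`).
#' @param ground_truth optional [sws_field_map] saved with the fields.
#' @param attrs optional named list of run attributes (e.g., loss factor).
#' @return `path`, invisibly.
#' @export
write_wave_fields <- function(fields, path, ground_truth = NULL,
                              attrs = NULL) {
  if (inherits(fields, "complex_wave_field")) fields <- list(fields)
  stopifnot(all(vapply(fields, inherits, TRUE, "complex_wave_field")))
  saveRDS(list(fields = fields, ground_truth = ground_truth, attrs = attrs),
          path)
  invisible(path)
}

#' Read wave fields written by [write_wave_fields]
#'
#' @param path container file.
#' @return List with `fields`, `ground_truth`, `attrs`.
#' @export
read_wave_fields <- function(path) {
  obj <- readRDS(path)
  stopifnot(is.list(obj), all(vapply(obj$fields, inherits, TRUE,
                                     "complex_wave_field")))
  obj
}

#' Write an acquisition schedule to JSON
#'
#' @param schedule an `acquisition_schedule`.
#' @param path output JSON file.
#' @return `path`, invisibly.
#' @export
write_schedule <- function(schedule, path) {
  stopifnot(inherits(schedule, "acquisition_schedule"))
  obj <- unclass(schedule)
  obj$per_frequency <- lapply(obj$per_frequency, function(e)
    list(frequency = e$frequency,
         times = sprintf("%.17g", e$times),
         phases = sprintf("%.17g", e$phases)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read an acquisition schedule from JSON
#'
#' @param path JSON file written by [write_schedule].
#' @return An `acquisition_schedule`.
#' @export
read_schedule <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  sched <- build_schedule(obj$frequencies, obj$frame_rate,
                          obj$frames_per_cycle, obj$n_cycles,
                          obj$skip_cycles)
  # keep the stored times/phases verbatim (they are the contract)
  for (i in seq_along(sched$per_frequency)) {
    sched$per_frequency[[i]]$times <-
      as.numeric(obj$per_frequency[[i]]$times)
    sched$per_frequency[[i]]$phases <-
      as.numeric(obj$per_frequency[[i]]$phases)
  }
  sched
}
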