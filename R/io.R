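#' Read and write the package's CSV, TIFF and JSON interchange formats
#'
#' Titration tables use columns `residue`, `lipid_conc_uM`,
#' `intensity_ratio`; CEST tables `residue`, `offset_kHz`,
#' `intensity_ratio`, `bandwidth_Hz`; relaxation tables `residue`,
#' `delay_ms`, `intensity`; track tables `frame`, `track_id`, `x`, `y`,
#' `observed`. Image stacks are multi-page 16-bit grayscale TIFF with a
#' JSON sidecar (`<path>.json`) holding the frame period, pixel binning and
#' the count scale used for the 16-bit encoding.
#'
#' @param dataset,profiles,series,tracks,stack object to write
#' @param path file path
#' @param protein_conc protein concentration (uM) to attach on read
#' @name synaptodock-io
NULL

#' @rdname synaptodock-io
#' @export
write_titration_csv <- function(dataset, path) {
  stopifnot(inherits(dataset, "titration_dataset"))
  df <- data.frame(
    residue = rep(dataset$residues, times = length(dataset$lipid_concs)),
    lipid_conc_uM = rep(dataset$lipid_concs, each = length(dataset$residues)),
    intensity_ratio = as.vector(dataset$ratios))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname synaptodock-io
#' @export
read_titration_csv <- function(path, protein_conc) {
  df <- utils::read.csv(path)
  residues <- sort(unique(df$residue))
  concs <- sort(unique(df$lipid_conc_uM))
  ratios <- matrix(NA_real_, length(residues), length(concs))
  ratios[cbind(match(df$residue, residues), match(df$lipid_conc_uM, concs))] <-
    df$intensity_ratio
  titration_dataset(protein_conc, residues, concs, ratios)
}

#' @rdname synaptodock-io
#' @export
write_cest_csv <- function(profiles, path) {
  stopifnot(inherits(profiles, "cest_profile_set"))
  df <- data.frame(
    residue = rep(profiles$residues, times = length(profiles$offsets)),
    offset_kHz = rep(profiles$offsets, each = length(profiles$residues)),
    intensity_ratio = as.vector(profiles$ratios),
    bandwidth_Hz = profiles$bandwidth)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname synaptodock-io
#' @export
read_cest_csv <- function(path) {
  df <- utils::read.csv(path)
  residues <- sort(unique(df$residue))
  offsets <- sort(unique(df$offset_kHz))
  ratios <- matrix(NA_real_, length(residues), length(offsets))
  ratios[cbind(match(df$residue, residues), match(df$offset_kHz, offsets))] <-
    df$intensity_ratio
  cest_profile_set(residues, offsets, ratios, bandwidth = df$bandwidth_Hz[1])
}

#' @rdname synaptodock-io
#' @export
write_relaxation_csv <- function(series, path) {
  stopifnot(inherits(series, "relaxation_series"))
  df <- data.frame(
    residue = rep(series$residues, times = length(series$delays)),
    delay_ms = rep(series$delays, each = length(series$residues)),
    intensity = as.vector(series$intensities))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname synaptodock-io
#' @export
read_relaxation_csv <- function(path) {
  df <- utils::read.csv(path)
  residues <- sort(unique(df$residue))
  delays <- sort(unique(df$delay_ms))
  intens <- matrix(NA_real_, length(residues), length(delays))
  intens[cbind(match(df$residue, residues), match(df$delay_ms, delays))] <-
    df$intensity
  relaxation_series(delays, intens, residues)
}

#' @rdname synaptodock-io
#' @export
write_tracks_csv <- function(tracks, path) {
  stopifnot(inherits(tracks, "track_set"))
  df <- tracks$points[, c("frame", "track_id", "x", "y", "observed")]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @param frame_count,frame_period movie geometry to attach on read
#' @rdname synaptodock-io
#' @export
read_tracks_csv <- function(path, frame_count = NULL, frame_period = 40) {
  df <- utils::read.csv(path)
  if (is.null(frame_count)) frame_count <- max(df$frame) + 1L
  track_set(df[, c("track_id", "frame", "x", "y", "observed")],
            frame_count, frame_period)
}

#' @rdname synaptodock-io
#' @export
write_tirf_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  scale <- max(1, max(vapply(stack$frames, max, 0)))
  pages <- lapply(stack$frames, function(f) f / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  jsonlite::write_json(list(frame_period_ms = stack$frame_period,
                            pixel_binning = stack$pixel_binning,
                            count_scale = scale),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname synaptodock-io
#' @export
read_tirf_stack <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"))
  pages <- tiff::readTIFF(path, all = TRUE)
  frames <- lapply(pages, function(p) round(p * meta$count_scale))
  image_stack(frames, frame_period = meta$frame_period_ms,
              pixel_binning = meta$pixel_binning)
}

#' @param acf an `acf_curve`
#' @rdname synaptodock-io
#' @export
write_acf_csv <- function(acf, path) {
  stopifnot(inherits(acf, "acf_curve"))
  utils::write.csv(data.frame(tau_frames = acf$taus,
                              tau_ms = acf$taus * acf$frame_period,
                              p_tau = acf$values,
                              p_tau_normalized = acf$values_norm),
                   path, row.names = FALSE)
  invisible(path)
}
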