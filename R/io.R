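#' Write an angiography movie as multi-page TIFF with a JSON sidecar
#'
#' Frames are stored as 32-bit float TIFF pages rescaled to `[0, 1]`; the
#' sidecar records the affine rescaling together with frame rate,
#' injection frame and pixel size, so reading restores the original
#' intensities.
#'
#' @param movie an [angio_movie()].
#' @param tiff_path,json_path output paths.
#' @export
write_angio_movie <- function(movie, tiff_path, json_path) {
  d <- dim(movie$frames)
  lo <- min(movie$frames); hi <- max(movie$frames)
  scale <- if (hi > lo) hi - lo else 1
  pages <- lapply(seq_len(d[1]), function(t)
    (movie$frames[t, , ] - lo) / scale)
  tiff::writeTIFF(pages, tiff_path, bits.per.sample = 32L)
  meta <- list(frame_rate = movie$frame_rate,
               injection_frame = movie$injection_frame,
               pixel_size_um = movie$pixel_size_um,
               intensity_offset = lo, intensity_scale = scale)
  jsonlite::write_json(meta, json_path, auto_unbox = TRUE, digits = NA)
  invisible(tiff_path)
}

#' Read an angiography movie written by [write_angio_movie()]
#'
#' @param tiff_path,json_path input paths.
#' @return an [angio_movie()].
#' @export
read_angio_movie <- function(tiff_path, json_path) {
  pages <- tiff::readTIFF(tiff_path, all = TRUE)
  meta <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  frames <- array(0, dim = c(length(pages), dim(pages[[1]])))
  for (t in seq_along(pages))
    frames[t, , ] <- pages[[t]] * meta$intensity_scale +
      meta$intensity_offset
  angio_movie(frames, meta$frame_rate, meta$injection_frame,
              meta$pixel_size_um)
}

#' Write a volume (mask, atlas labels, slope map) as NIfTI-1
#'
#' @param vol 3D array.
#' @param path output `.nii`/`.nii.gz` path.
#' @export
write_volume_nifti <- function(vol, path) {
  RNifti::writeNifti(RNifti::asNifti(vol * 1), path)
  invisible(path)
}

#' Read a NIfTI-1 volume as a plain array
#'
#' @param path input path.
#' @export
read_volume_nifti <- function(path) {
  v <- RNifti::readNifti(path)
  array(as.numeric(v), dim = dim(v))
}

#' Write / read an LFP trace and stimulus log as CSV
#'
#' The trace CSV has columns `time_s`, `value_uV`; the stimulus log has a
#' single `stim_time_s` column.
#'
#' @param trace list with `samples`, `sampling_rate`, `start_time`.
#' @param path output path.
#' @export
write_lfp_csv <- function(trace, path) {
  start <- if (is.null(trace$start_time)) 0 else trace$start_time
  df <- data.frame(
    time_s = start + (seq_along(trace$samples) - 1) / trace$sampling_rate,
    value_uV = trace$samples)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_lfp_csv
#' @export
read_lfp_csv <- function(path) {
  df <- utils::read.csv(path)
  fs <- 1 / median(diff(df$time_s))
  list(samples = df$value_uV, sampling_rate = round(fs),
       start_time = df$time_s[1])
}

#' @rdname write_lfp_csv
#' @param stim_times numeric vector of stimulus times (s).
#' @export
write_stim_log_csv <- function(stim_times, path) {
  utils::write.csv(data.frame(stim_time_s = stim_times), path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_lfp_csv
#' @export
read_stim_log_csv <- function(path) {
  utils::read.csv(path)$stim_time_s
}

#' Write / read a count matrix as TSV with JSON sample metadata
#'
#' @param counts genes x samples matrix.
#' @param meta sample metadata data.frame.
#' @param tsv_path,json_path output paths.
#' @export
write_counts_tsv <- function(counts, meta, tsv_path, json_path) {
  utils::write.table(counts, tsv_path, sep = "\t", quote = FALSE,
                     col.names = NA)
  jsonlite::write_json(meta, json_path, dataframe = "rows", digits = NA)
  invisible(tsv_path)
}

#' @rdname write_counts_tsv
#' @export
read_counts_tsv <- function(tsv_path, json_path) {
  counts <- as.matrix(utils::read.table(tsv_path, sep = "\t", header = TRUE,
                                        row.names = 1, check.names = FALSE))
  meta <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  list(counts = counts, sample_meta = meta)
}
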