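# File I/O: multi-page TIFF movies with JSON sidecars, binary masks,
# event tables and summary JSON.

#' Write a movie as multi-page TIFF with a JSON sidecar
#'
#' Frames are scaled to the TIFF 32-bit float range as-is; calibration
#' (pixel size, frame rate) goes into `<path>.json`.
#'
#' @param movie a [wf_movie()].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_movie_tiff <- function(movie, path) {
  stopifnot(inherits(movie, "wf_movie"))
  T_n <- nrow(movie$frames)
  pages <- lapply(seq_len(T_n), function(t)
    matrix(movie$frames[t, ], movie$height, movie$width))
  mx <- max(unlist(lapply(pages, max)), 1)
  pages <- lapply(pages, function(p) { p[is.na(p)] <- 0; p / mx })
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  jsonlite::write_json(
    list(pixel_size_um = movie$pixel_size_um,
         frame_rate_hz = movie$frame_rate_hz,
         intensity_scale = mx, n_frames = T_n),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a movie from multi-page TIFF plus JSON sidecar
#'
#' @param path TIFF path written by [write_movie_tiff()], or any
#'   multi-page grayscale TIFF if `pixel_size_um` and `frame_rate_hz` are
#'   given explicitly.
#' @param pixel_size_um,frame_rate_hz calibration overrides.
#' @param roi_mask,vessel_mask optional masks (see [wf_movie()]).
#' @return a [wf_movie()].
#' @export
read_movie_tiff <- function(path, pixel_size_um = NULL,
                            frame_rate_hz = NULL, roi_mask = NULL,
                            vessel_mask = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  scale <- 1
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side)
    pixel_size_um <- pixel_size_um %||% meta$pixel_size_um
    frame_rate_hz <- frame_rate_hz %||% meta$frame_rate_hz
    scale <- meta$intensity_scale %||% 1
  }
  if (is.null(pixel_size_um) || is.null(frame_rate_hz))
    stop("pixel_size_um and frame_rate_hz required (no sidecar found)")
  h <- nrow(pages[[1]]); w <- ncol(pages[[1]])
  frames <- t(vapply(pages, function(p) {
    if (length(dim(p)) == 3) p <- p[, , 1]
    as.vector(p) * scale
  }, numeric(h * w)))
  wf_movie(frames, h, w, pixel_size_um, frame_rate_hz, roi_mask, vessel_mask)
}

#' Read a binary mask image (PNG or TIFF)
#'
#' Nonzero pixels are TRUE.
#' @param path image path ending in .png or .tif/.tiff.
#' @return logical matrix.
#' @export
read_mask <- function(path) {
  img <- if (grepl("\\.png$", path, ignore.case = TRUE))
    png::readPNG(path) else tiff::readTIFF(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  img > 0
}

#' Write an event table as CSV
#'
#' Columns: start, end, max_frame, amplitude.
#' @param es an `event_set`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_events_csv <- function(es, path) {
  stopifnot(inherits(es, "event_set"))
  write.csv(es$events, path, row.names = FALSE)
  invisible(path)
}
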