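#' Write / read a movie as multi-page 16-bit TIFF
#'
#' Intensities are scaled into the 16-bit range; the scale factor, frame
#' rate and channel tag go to a JSON sidecar (\code{<path>.json}) so the
#' round trip restores the original values up to 16-bit quantization.
#'
#' @param stack A [frame_stack()].
#' @param path Output TIFF path.
#' @return \code{path}, invisibly.
#' @export
write_movie_tiff <- function(stack, path) {
  stopifnot(inherits(stack, "frame_stack"))
  mx <- max(stack$data)
  scale <- if (mx > 0) mx else 1
  pages <- lapply(seq_len(dim(stack$data)[3]),
                  function(i) pmin(pmax(stack$data[, , i] / scale, 0), 1))
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  jsonlite::write_json(list(frame_rate = stack$frame_rate,
                            channel = stack$channel, scale = scale),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_movie_tiff
#' @export
read_movie_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  meta <- list(frame_rate = 25, channel = "green", scale = 1)
  side <- paste0(path, ".json")
  if (file.exists(side))
    meta <- utils::modifyList(meta, jsonlite::read_json(side,
                                                        simplifyVector = TRUE))
  arr <- array(0, dim = c(dim(pages[[1]]), length(pages)))
  for (i in seq_along(pages)) arr[, , i] <- pages[[i]] * meta$scale
  frame_stack(arr, meta$frame_rate, meta$channel)
}

#' Write per-bouton traces as CSV
#'
#' One file per bouton (\code{trace_bouton<id>.csv}) with columns
#' \code{time_s, f_raw, f_bg, f_t, dff}.
#'
#' @param traces List of \code{bouton_trace}.
#' @param dir Output directory (created if needed).
#' @return Written paths, invisibly.
#' @export
write_traces_csv <- function(traces, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(traces, function(tr) {
    p <- file.path(dir, sprintf("trace_bouton%s.csv", tr$bouton_id))
    utils::write.csv(data.frame(
      time_s = tr$time, f_raw = tr$f_raw, f_bg = tr$f_bg, f_t = tr$f_t,
      dff = if (is.null(tr$dff)) NA_real_ else tr$dff),
      p, row.names = FALSE)
    p
  }, character(1))
  invisible(paths)
}

#' Write / read an ROI set as JSON
#'
#' Stores bouton and background pixel-index lists (1-based linear matrix
#' indices), the frame shape and per-bouton tags.
#'
#' @param rois A [roi_set()].
#' @param path Output path.
#' @return \code{path} (write) or the [roi_set()] (read).
#' @export
write_roi_json <- function(rois, path) {
  stopifnot(inherits(rois, "roi_set"))
  jsonlite::write_json(list(frame_shape = rois$frame_shape,
                            boutons = rois$boutons,
                            backgrounds = rois$backgrounds,
                            type = rois$type, nmj_id = rois$nmj_id),
                       path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_roi_json
#' @export
read_roi_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE,
                           simplifyMatrix = FALSE)
  roi_set(lapply(x$boutons, as.integer),
          lapply(x$backgrounds, as.integer),
          as.integer(x$frame_shape), x$type, x$nmj_id)
}

#' Write a focal record as two-column CSV
#'
#' @param record Data frame from [generate_focal_record()].
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_focal_csv <- function(record, path) {
  utils::write.csv(record[, c("time_s", "amplitude")], path,
                   row.names = FALSE)
  invisible(path)
}
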