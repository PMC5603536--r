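# TIFF I/O. The tiff package stores data in [0, 1]; movies are written as
# 32-bit float pages divided by a scale factor kept in a plain-text sidecar
# (<path>.scale), masks as 8-bit 0/255, labeled masks as 16-bit.

#' Write a movie stack as a multi-page TIFF
#' @param movie H x W x T numeric array.
#' @param path output path; an intensity scale factor is written to
#'   `<path>.scale`.
#' @export
write_movie_tiff <- function(movie, path) {
  s <- max(movie, 1)
  pages <- lapply(seq_len(dim(movie)[3]),
                  function(t) pmin(pmax(movie[, , t] / s, 0), 1))
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  writeLines(format(s, digits = 17), paste0(path, ".scale"))
  invisible(path)
}

#' Read a movie stack written by [write_movie_tiff()]
#' @param path TIFF path.
#' @return H x W x T numeric array.
#' @export
read_movie_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  s_file <- paste0(path, ".scale")
  s <- if (file.exists(s_file)) as.numeric(readLines(s_file)[1]) else 1
  arr <- array(0, c(dim(pages[[1]])[1:2], length(pages)))
  for (t in seq_along(pages)) {
    p <- pages[[t]]
    if (length(dim(p)) == 3) p <- p[, , 1]
    arr[, , t] <- p * s
  }
  arr
}

#' Write a binary mask as an 8-bit TIFF (0/255)
#' @param mask logical H x W matrix.
#' @param path output path.
#' @export
write_mask_tiff <- function(mask, path) {
  tiff::writeTIFF(matrix(as.numeric(mask), nrow(mask)), path,
                  bits.per.sample = 8L)
  invisible(path)
}

#' Read a binary mask TIFF
#' @param path TIFF path.
#' @return logical H x W matrix (any non-zero pixel is TRUE).
#' @export
read_mask_tiff <- function(path) {
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  m > 0
}

#' Write a labeled mask as a 16-bit TIFF
#' @param labels integer H x W matrix (background 0, labels 1..K < 65536).
#' @param path output path.
#' @export
write_labels_tiff <- function(labels, path) {
  stopifnot(max(labels) < 65536L)
  tiff::writeTIFF(labels / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a labeled mask written by [write_labels_tiff()]
#' @param path TIFF path.
#' @return integer H x W matrix.
#' @export
read_labels_tiff <- function(path) {
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  matrix(as.integer(round(m * 65535)), nrow(m))
}

#' Read polygon vertices from a CSV
#'
#' One `(row, col)` vertex per line, 0-based pixel-index coordinates.
#' @param path CSV path.
#' @return matrix with `row`, `col` columns.
#' @export
read_polygon_csv <- function(path) {
  d <- utils::read.csv(path)
  as.matrix(d[, c("row", "col")])
}

#' Export fusion events to a data.frame / CSV row set
#'
#' @param events list of `fusion_event` objects.
#' @return data.frame with one row per event: id, location, fusion frame,
#'   acceptance, rejection reason, peak amplitude, FWHM slope.
#' @export
events_to_table <- function(events) {
  if (length(events) == 0)
    return(data.frame(event_id = integer(0), row_px = numeric(0),
                      col_px = numeric(0), t0_frame = integer(0),
                      accepted = logical(0), rejection_reason = character(0),
                      peak_amplitude = numeric(0),
                      fwhm_slope_um_per_frame = numeric(0)))
  do.call(rbind, lapply(seq_along(events), function(i) {
    e <- events[[i]]
    data.frame(event_id = i, row_px = e$row_px, col_px = e$col_px,
               t0_frame = e$t0_frame, accepted = e$accepted,
               rejection_reason = e$rejection_reason %||% NA_character_,
               peak_amplitude = suppressWarnings(
                 max(e$amplitude_trace, na.rm = TRUE)),
               fwhm_slope_um_per_frame = e$fwhm_slope_um_per_frame)
  }))
}
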