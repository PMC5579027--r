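#' Write / read a current trace
#'
#' Traces are stored as a two-column CSV (`time_s,current_A`) with a JSON
#' sidecar (`<path>.json`) holding the sample rate and baseline current.
#' The round trip is lossless to full double precision (15 significant
#' digits).
#'
#' @param trace An `rp_trace`.
#' @param path CSV path.
#' @return `write_trace` returns `path` invisibly; `read_trace` returns an
#'   `rp_trace`.
#' @export
write_trace <- function(trace, path) {
  df <- data.frame(time_s = format(trace$time_s, digits = 15, trim = TRUE,
                                   scientific = TRUE),
                   current_A = format(trace$current_A, digits = 15,
                                      trim = TRUE, scientific = TRUE))
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  sidecar <- list(sample_rate_hz = 1 / attr(trace, "sample_period_s"),
                  I0_A = attr(trace, "i0_A"))
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  sidecar_path <- paste0(path, ".json")
  if (!file.exists(sidecar_path)) {
    stop(sprintf("missing sidecar `%s`; traces need a JSON sidecar with sample_rate_hz and I0_A (write with write_trace())",
                 sidecar_path), call. = FALSE)
  }
  sc <- jsonlite::read_json(sidecar_path)
  df <- utils::read.csv(path, colClasses = "character")
  if (!all(c("time_s", "current_A") %in% names(df))) {
    stop("trace CSV must have columns time_s,current_A", call. = FALSE)
  }
  df$time_s <- suppressWarnings(as.numeric(df$time_s))
  df$current_A <- suppressWarnings(as.numeric(df$current_A))
  bad <- which(!is.finite(df$time_s) | !is.finite(df$current_A))
  if (length(bad)) {
    stop(sprintf("malformed trace row at line %d", bad[1] + 1L), call. = FALSE)
  }
  new_rp_trace(tibble::as_tibble(df),
               sample_period_s = 1 / sc$sample_rate_hz, i0_A = sc$I0_A)
}

#' Write / read a frame sequence
#'
#' Frames are stored as a multi-page 8-bit grayscale TIFF plus a timestamp
#' CSV (`frame_index,time_s`, frame-start times) and a JSON sidecar with
#' the scale, exposure and channel-frame corners; the particle-free
#' template goes into a second TIFF next to the stack.
#'
#' @param frames A `frame_sequence`.
#' @param path TIFF path; `<path>.csv`, `<path>.json` and
#'   `<path>.template.tif` are written next to it.
#' @return `write_frames` returns `path` invisibly; `read_frames` a
#'   `frame_sequence`.
#' @export
write_frames <- function(frames, path) {
  stopifnot(inherits(frames, "frame_sequence"))
  tiff::writeTIFF(lapply(frames$frames, function(m) m / 255), path,
                  bits.per.sample = 8)
  tiff::writeTIFF(frames$template / 255, paste0(path, ".template.tif"),
                  bits.per.sample = 8)
  utils::write.csv(data.frame(frame_index = frames$frame_index,
                              time_s = format(frames$time_s, digits = 15,
                                              trim = TRUE)),
                   paste0(path, ".csv"), row.names = FALSE, quote = FALSE)
  fr <- frames$frame
  jsonlite::write_json(
    list(exposure_s = frames$exposure_s, scale_um_px = frames$scale_um_px,
         physical_length_um = fr$physical_length_um,
         entrance_px = fr$entrance_px, exit_px = fr$exit_px),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_frames
#' @export
read_frames <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  ts <- utils::read.csv(paste0(path, ".csv"))
  if (nrow(ts) != length(pages)) {
    stop(sprintf("timestamp count (%d) does not match page count (%d)",
                 nrow(ts), length(pages)), call. = FALSE)
  }
  if (is.unsorted(ts$time_s, strictly = TRUE)) {
    stop("frame timestamps must be strictly increasing", call. = FALSE)
  }
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  template_path <- paste0(path, ".template.tif")
  template <- if (file.exists(template_path)) {
    quantize8(tiff::readTIFF(template_path) * 255)
  } else NULL
  fr <- channel_frame(meta$entrance_px, meta$exit_px, meta$physical_length_um)
  structure(list(frames = lapply(pages, function(p) {
    if (length(dim(p)) == 3) p <- p[, , 1]
    quantize8(p * 255)
  }),
  frame_index = ts$frame_index, time_s = ts$time_s,
  exposure_s = meta$exposure_s, template = template, frame = fr,
  scale_um_px = meta$scale_um_px),
  class = "frame_sequence")
}

#' Write / read event tables as JSON lines
#'
#' One JSON object per row; list-columns (per-sample tuples, extrema) are
#' nested as arrays of objects. Numbers keep full precision.
#'
#' @param events An event tibble (RP, IM or matched).
#' @param path JSONL path.
#' @return `write_events` returns `path` invisibly; `read_events` a tibble.
#' @export
write_events <- function(events, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (r in seq_len(nrow(events))) {
    row <- as.list(events[r, ])
    row <- lapply(row, function(col) if (is.list(col)) col[[1]] else col)
    writeLines(jsonlite::toJSON(row, auto_unbox = TRUE, digits = NA,
                                dataframe = "rows", null = "null"), con)
  }
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  lines <- readLines(path)
  rows <- lapply(lines, function(l) {
    x <- jsonlite::fromJSON(l, simplifyVector = TRUE)
    tibble::as_tibble(lapply(x, function(v) {
      if (is.data.frame(v)) list(tibble::as_tibble(v)) else v
    }))
  })
  dplyr::bind_rows(rows)
}

#' Write a resistance map as a TSV grid
#'
#' @param map A `resistance_map`.
#' @param path TSV path.
#' @return `path`, invisibly.
#' @export
write_map <- function(map, path) {
  df <- data.frame(x_c_bin = map$x_c, y_c_bin = map$y_c, mean = map$mean_a,
                   std = map$sd_a, count = map$n)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
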