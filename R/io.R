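TRACK_HEADER <- c("track_id", "frame", "t_min", "x_um", "y_um")

# JSON sidecar recording how an artifact was generated
write_sidecar <- function(path, meta) {
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
}

#' Write a track table to CSV
#'
#' Emits the shared track schema `track_id,frame,t_min,x_um,y_um` plus a
#' JSON sidecar (`<path>.json`) with any spec/seed metadata attached to the
#' track set.
#'
#' @param tracks a [track_set].
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_tracks <- function(tracks, path) {
  df <- as.data.frame(tracks)[TRACK_HEADER]
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  write_sidecar(path, list(schema = paste(TRACK_HEADER, collapse = ","),
                           dt_min = attr(tracks, "dt_min"),
                           condition = attr(tracks, "condition"),
                           n_tracks = length(unique(df$track_id))))
  invisible(path)
}

#' Read a track table from CSV
#'
#' Validates the schema (exact header, numeric fields, no duplicate
#' (track_id, frame) pairs — offending line numbers are reported) and
#' returns the rows sorted by (track_id, t_min).
#'
#' @param path CSV path.
#' @param dt_min optional nominal frame interval; inferred when `NULL`.
#' @return a [track_set].
#' @export
read_tracks <- function(path, dt_min = NULL) {
  if (!file.exists(path)) ds_stop(paste("no such file:", path),
                                  "format_error")
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!identical(names(df), TRACK_HEADER))
    ds_stop(sprintf("bad header: expected '%s', got '%s'",
                    paste(TRACK_HEADER, collapse = ","),
                    paste(names(df), collapse = ",")), "format_error")
  num <- lapply(df[-1], function(col)
    suppressWarnings(as.numeric(as.character(col))))
  bad <- which(Reduce(`|`, lapply(num, is.na)) | !complete.cases(df))
  if (length(bad))
    ds_stop(sprintf("malformed rows at lines: %s",
                    paste(bad + 1L, collapse = ", ")), "format_error")
  df[-1] <- num
  dup <- which(duplicated(df[c("track_id", "frame")]))
  if (length(dup))
    ds_stop(sprintf("duplicate (track_id, frame) at lines: %s",
                    paste(dup + 1L, collapse = ", ")), "format_error")
  track_set(df, dt_min = dt_min)
}

#' Write a label mask as TIFF
#'
#' Integer labels are stored losslessly as 16-bit grayscale; the pixel size
#' goes into a JSON sidecar.
#'
#' @param mask a [label_mask] (labels must fit in 16 bits).
#' @param path output TIFF path.
#' @return the path, invisibly.
#' @export
write_labels <- function(mask, path) {
  if (max(mask$pixels) > 65535L)
    ds_stop("labels exceed 16-bit range", "format_error")
  tiff::writeTIFF(mask$pixels / 65535, path, bits.per.sample = 16L)
  write_sidecar(path, list(kind = "label_mask",
                           pixel_size_um = mask$pixel_size_um))
  invisible(path)
}

#' Read a label mask from TIFF
#'
#' @param path TIFF path written by [write_labels()] (or any integer-valued
#'   grayscale TIFF).
#' @param pixel_size_um pixel size override; when `NULL` the JSON sidecar
#'   is consulted, falling back to 1.
#' @return a [label_mask].
#' @export
read_labels <- function(path, pixel_size_um = NULL) {
  if (!file.exists(path)) ds_stop(paste("no such file:", path),
                                  "format_error")
  img <- tiff::readTIFF(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  vals <- img * 65535
  if (max(abs(vals - round(vals))) > 1e-6)
    ds_stop("TIFF does not contain integer labels", "format_error")
  if (is.null(pixel_size_um)) {
    side <- paste0(path, ".json")
    pixel_size_um <- if (file.exists(side))
      jsonlite::read_json(side)$pixel_size_um else 1
  }
  label_mask(matrix(as.integer(round(vals)), nrow(img)),
             pixel_size_um = pixel_size_um)
}

#' Write an intensity channel as 16-bit TIFF
#'
#' @param channel numeric matrix of non-negative intensities.
#' @param path output path.
#' @param max_value full-scale value mapped to 65535 (default 65535, i.e.
#'   intensities are stored as integer counts).
#' @return the path, invisibly.
#' @export
write_channel <- function(channel, path, max_value = 65535) {
  tiff::writeTIFF(pmin(pmax(channel / max_value, 0), 1), path,
                  bits.per.sample = 16L)
  write_sidecar(path, list(kind = "channel", max_value = max_value))
  invisible(path)
}

read_channel <- function(path, max_value = 65535) {
  img <- tiff::readTIFF(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  img * max_value
}

#' Assemble a spheroid record from channel TIFFs
#'
#' @param mask_path label TIFF path.
#' @param channel_paths named character vector of channel TIFF paths.
#' @param distance_mm,condition,spheroid_id metadata, see
#'   [spheroid_record()].
#' @return a [spheroid_record].
#' @export
read_channels <- function(mask_path, channel_paths, distance_mm = 0,
                          condition = NA_character_,
                          spheroid_id = "spheroid") {
  mask <- read_labels(mask_path)
  chans <- lapply(channel_paths, read_channel)
  names(chans) <- names(channel_paths)
  spheroid_record(mask, chans, distance_mm = distance_mm,
                  condition = condition, spheroid_id = spheroid_id)
}

#' Write / read a gradient profile CSV (`distance_mm,value`)
#'
#' @param profile a [gradient_profile].
#' @param path CSV path.
#' @return the path (write) or a [gradient_profile] (read).
#' @export
write_profile <- function(profile, path) {
  write.csv(data.frame(distance_mm = profile$distance_mm,
                       value = profile$value),
            path, row.names = FALSE, quote = FALSE)
  write_sidecar(path, list(kind = "gradient_profile",
                           value_kind = attr(profile, "value_kind")))
  invisible(path)
}

#' @rdname write_profile
#' @param value_kind value label used when no sidecar is present.
#' @export
read_profile <- function(path, value_kind = NULL) {
  if (!file.exists(path)) ds_stop(paste("no such file:", path),
                                  "format_error")
  df <- read.csv(path)
  if (!identical(names(df), c("distance_mm", "value")))
    ds_stop("profile CSV must have columns distance_mm,value",
            "format_error")
  if (is.null(value_kind)) {
    side <- paste0(path, ".json")
    value_kind <- if (file.exists(side))
      jsonlite::read_json(side)$value_kind else "value"
  }
  gradient_profile(df$distance_mm, df$value, value_kind)
}
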