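#' Label mask
#'
#' A 2D integer image assigning each pixel to background (0) or an object
#' label (positive integer), together with the physical pixel size. This is
#' the container for spheroid outlines consumed by [invasiveness_index()]
#' and friends.
#'
#' @param pixels integer matrix; 0 = background, k > 0 = object k.
#' @param pixel_size_um physical size of one pixel edge in micrometers.
#' @return an object of class `label_mask`.
#' @export
label_mask <- function(pixels, pixel_size_um = 1) {
  if (!is.matrix(pixels))
    ds_stop("pixels must be a matrix", "invalid_spec")
  if (any(pixels < 0) || any(pixels != round(pixels)))
    ds_stop("labels must be non-negative integers", "invalid_spec")
  if (!is.numeric(pixel_size_um) || pixel_size_um <= 0)
    ds_stop("pixel_size_um must be positive", "invalid_spec")
  structure(list(pixels = matrix(as.integer(pixels), nrow(pixels)),
                 pixel_size_um = pixel_size_um),
            class = "label_mask")
}

#' @export
print.label_mask <- function(x, ...) {
  labs <- setdiff(sort(unique(as.vector(x$pixels))), 0L)
  cat(sprintf("<label_mask> %d x %d px (%.3g um/px), %d object(s)\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size_um, length(labs)))
  invisible(x)
}

#' Point set
#'
#' Planar point cloud (e.g. nuclei centroids) in micrometers.
#'
#' @param x_um,y_um numeric coordinate vectors of equal length.
#' @return a data.frame with class `point_set` and columns `x_um`, `y_um`.
#' @export
point_set <- function(x_um, y_um) {
  if (length(x_um) != length(y_um))
    ds_stop("coordinate vectors must have equal length", "invalid_spec")
  structure(data.frame(x_um = as.numeric(x_um), y_um = as.numeric(y_um)),
            class = c("point_set", "data.frame"))
}

#' Track set
#'
#' Time-ordered positions of tracked cells. Stored as a long data.frame with
#' columns `track_id`, `frame`, `t_min`, `x_um`, `y_um`, sorted by
#' (track_id, t_min); the nominal sampling interval is kept as an attribute.
#'
#' @param df data.frame with the five schema columns.
#' @param dt_min nominal frame interval in minutes; inferred from the data
#'   when `NULL`.
#' @param condition optional free-text condition label.
#' @param distance_mm optional distance of the parent spheroid to the
#'   chamber opening.
#' @return a data.frame of class `track_set`.
#' @export
track_set <- function(df, dt_min = NULL, condition = NA_character_,
                      distance_mm = NA_real_) {
  req <- c("track_id", "frame", "t_min", "x_um", "y_um")
  if (!all(req %in% names(df)))
    ds_stop(sprintf("track table must have columns %s",
                    paste(req, collapse = ", ")), "format_error")
  df <- df[order(df$track_id, df$t_min), req, drop = FALSE]
  rownames(df) <- NULL
  if (anyDuplicated(df[c("track_id", "frame")]))
    ds_stop("duplicate (track_id, frame) rows", "format_error")
  if (is.null(dt_min)) {
    dts <- unlist(tapply(df$t_min, df$track_id, function(t) diff(t)))
    dt_min <- if (length(dts)) stats::median(dts) else NA_real_
  }
  structure(df, class = c("track_set", "data.frame"),
            dt_min = dt_min, condition = condition,
            distance_mm = distance_mm)
}

#' Split a track set into per-track data.frames
#'
#' @param ts a [track_set].
#' @return named list of single-track data.frames, time-sorted.
#' @export
track_list <- function(ts) {
  split(as.data.frame(ts), ts$track_id)
}

#' @export
print.track_set <- function(x, ...) {
  cat(sprintf("<track_set> %d track(s), %d samples, dt = %s min\n",
              length(unique(x$track_id)), nrow(x),
              format(attr(x, "dt_min"))))
  invisible(x)
}

#' Gradient profile
#'
#' A quantity sampled along the chamber axis: strictly increasing
#' non-negative distances (mm) paired with values, plus a label saying what
#' the values are (pH, concentration in nM, a ratio, an index...).
#'
#' @param distance_mm non-negative, strictly increasing distances.
#' @param value numeric values, same length.
#' @param value_kind label describing the value axis.
#' @return a data.frame of class `gradient_profile`.
#' @export
gradient_profile <- function(distance_mm, value, value_kind = "value") {
  if (length(distance_mm) != length(value))
    ds_stop("distance and value must have equal length", "invalid_spec")
  if (any(distance_mm < 0))
    ds_stop("distances must be non-negative", "invalid_spec")
  if (is.unsorted(distance_mm, strictly = TRUE))
    ds_stop("distances must be strictly increasing", "invalid_spec")
  structure(data.frame(distance_mm = as.numeric(distance_mm),
                       value = as.numeric(value)),
            class = c("gradient_profile", "data.frame"),
            value_kind = value_kind)
}

#' Spheroid record
#'
#' One spheroid's mask, its fluorescence channels, and its position
#' metadata: the distance to the chamber opening (which indexes the ischemic
#' gradient) and a free condition label such as "consumers" /
#' "no-consumers".
#'
#' @param mask a [label_mask].
#' @param channels named list of numeric matrices, all the same size as the
#'   mask.
#' @param distance_mm distance to the chamber opening, mm (>= 0).
#' @param condition condition label.
#' @param spheroid_id identifier used in output tables and warnings.
#' @return an object of class `spheroid_record`.
#' @export
spheroid_record <- function(mask, channels, distance_mm = 0,
                            condition = NA_character_,
                            spheroid_id = "spheroid") {
  if (!inherits(mask, "label_mask"))
    ds_stop("mask must be a label_mask", "invalid_spec")
  if (distance_mm < 0)
    ds_stop("distance_mm must be non-negative", "input_error")
  if (is.null(names(channels)) || any(!nzchar(names(channels))))
    ds_stop("channels must be a named list", "invalid_spec")
  dims <- dim(mask$pixels)
  for (nm in names(channels)) {
    if (!identical(dim(channels[[nm]]), dims))
      ds_stop(sprintf("channel '%s' shape differs from mask", nm),
              "format_error")
  }
  structure(list(mask = mask, channels = channels,
                 distance_mm = distance_mm, condition = condition,
                 spheroid_id = spheroid_id),
            class = "spheroid_record")
}
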