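#' Screen geometry for gaze coordinate transforms
#'
#' Describes the stimulus monitor as seen from the participant: the pixel
#' grid, the physical half-extents of the visible area, and the viewing
#' distance measured from the nasion along the perpendicular through the
#' screen center. All coordinate transforms in the package are defined
#' relative to this object.
#'
#' Pixel pitch may differ between axes; it is derived per axis as
#' `2 * half_extent_mm / extent_px` and never assumed square.
#'
#' @param width_px,height_px Screen resolution in pixels (positive integers).
#' @param half_width_mm,half_height_mm Half of the physical width/height of
#'   the displayed area, in millimeters.
#' @param distance_mm Nasion-to-screen distance in millimeters, measured
#'   along the perpendicular through the screen center.
#' @param sampling_rate_hz Nominal eye-tracker sampling rate in Hz.
#'
#' @return An object of class `screen_geometry`.
#' @examples
#' scr <- screen_geometry(1152, 864, 156.21, 113.445, 700, 500)
#' pixels_to_mm(576, 432, scr) # screen center -> origin
#' @export
screen_geometry <- function(width_px, height_px, half_width_mm,
                            half_height_mm, distance_mm,
                            sampling_rate_hz = 500) {
  vals <- c(width_px = width_px, height_px = height_px,
            half_width_mm = half_width_mm, half_height_mm = half_height_mm,
            distance_mm = distance_mm, sampling_rate_hz = sampling_rate_hz)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all screen geometry fields must be finite and strictly positive",
         call. = FALSE)
  }
  structure(
    list(width_px = as.integer(width_px), height_px = as.integer(height_px),
         half_width_mm = half_width_mm, half_height_mm = half_height_mm,
         distance_mm = distance_mm, sampling_rate_hz = sampling_rate_hz),
    class = "screen_geometry"
  )
}

#' @export
print.screen_geometry <- function(x, ...) {
  cat(sprintf(
    "<screen_geometry> %d x %d px, +/-%.2f x +/-%.3f mm, distance %.0f mm, %g Hz\n",
    x$width_px, x$height_px, x$half_width_mm, x$half_height_mm,
    x$distance_mm, x$sampling_rate_hz))
  invisible(x)
}

#' Read / write a screen-geometry YAML config
#'
#' The config carries `width_px`, `height_px`, `half_width_mm`,
#' `half_height_mm`, `distance_mm` and `sampling_rate_hz`.
#'
#' @param path Path to a YAML file.
#' @return `read_screen_config()` returns a [screen_geometry()] object.
#' @export
read_screen_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  need <- c("width_px", "height_px", "half_width_mm", "half_height_mm",
            "distance_mm")
  miss <- setdiff(need, names(cfg))
  if (length(miss) > 0) {
    stop("screen config is missing fields: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  screen_geometry(cfg$width_px, cfg$height_px, cfg$half_width_mm,
                  cfg$half_height_mm, cfg$distance_mm,
                  cfg$sampling_rate_hz %||% 500)
}

#' @rdname read_screen_config
#' @param screen A [screen_geometry()] object.
#' @export
write_screen_config <- function(screen, path) {
  yaml::write_yaml(unclass(screen), path)
  invisible(path)
}

#' Convert pixel coordinates to physical screen coordinates
#'
#' Pixels follow the tracker convention: origin at the top-left corner with y
#' increasing downward. Physical coordinates have the screen center as
#' origin with right and upward positive, so the y axis is flipped. The
#' implied gaze vector has a constant depth component `z_mm = distance_mm`.
#'
#' The transform is affine and exactly invertible by [mm_to_pixels()].
#' Out-of-screen coordinates are allowed (and map outside the physical
#' extents); they are the caller's to flag.
#'
#' @param x_px,y_px Numeric vectors of pixel coordinates.
#' @param screen A [screen_geometry()].
#' @return A tibble with columns `x_mm`, `y_mm`, `z_mm`.
#' @export
pixels_to_mm <- function(x_px, y_px, screen) {
  stopifnot(inherits(screen, "screen_geometry"))
  pitch_x <- 2 * screen$half_width_mm / screen$width_px
  pitch_y <- 2 * screen$half_height_mm / screen$height_px
  tibble::tibble(
    x_mm = (x_px - screen$width_px / 2) * pitch_x,
    y_mm = (screen$height_px / 2 - y_px) * pitch_y,
    z_mm = screen$distance_mm
  )
}

#' @rdname pixels_to_mm
#' @param x_mm,y_mm Numeric vectors of physical screen coordinates (mm).
#' @return `mm_to_pixels()` returns a tibble with columns `x_px`, `y_px`.
#' @export
mm_to_pixels <- function(x_mm, y_mm, screen) {
  stopifnot(inherits(screen, "screen_geometry"))
  pitch_x <- 2 * screen$half_width_mm / screen$width_px
  pitch_y <- 2 * screen$half_height_mm / screen$height_px
  tibble::tibble(
    x_px = x_mm / pitch_x + screen$width_px / 2,
    y_px = screen$height_px / 2 - y_mm / pitch_y
  )
}
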