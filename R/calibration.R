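#' Microscope calibration
#'
#' Pixel sizes and axial step used to convert pixel/layer coordinates into
#' micrometres. The default z-step of 5 um corresponds to typical confocal
#' z-stacks of cleared bone marrow.
#'
#' @param pixel_size_x,pixel_size_y Lateral pixel size in um/pixel (strictly
#'   positive). `pixel_size_y` defaults to `pixel_size_x`.
#' @param z_step Axial distance between consecutive image layers in um.
#'
#' @return An object of class `calibration`.
#' @examples
#' calibration(pixel_size_x = 0.62, z_step = 5)
#' @export
calibration <- function(pixel_size_x = 1, pixel_size_y = pixel_size_x, z_step = 5) {
  assert_scalar_number(pixel_size_x, "pixel_size_x")
  assert_scalar_number(pixel_size_y, "pixel_size_y")
  assert_scalar_number(z_step, "z_step")
  structure(
    list(
      pixel_size_x = pixel_size_x,
      pixel_size_y = pixel_size_y,
      z_step = z_step
    ),
    class = "calibration"
  )
}

#' @export
print.calibration <- function(x, ...) {
  cat(sprintf(
    "<calibration> pixel size %g x %g um/px, z-step %g um\n",
    x$pixel_size_x, x$pixel_size_y, x$z_step
  ))
  invisible(x)
}

as_calibration <- function(x) {
  if (inherits(x, "calibration")) return(x)
  if (is.list(x)) {
    return(calibration(
      pixel_size_x = x$pixel_size_x %||% 1,
      pixel_size_y = x$pixel_size_y %||% x$pixel_size_x %||% 1,
      z_step = x$z_step %||% 5
    ))
  }
  stop_spatcube("`calibration` must be created with calibration()")
}
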