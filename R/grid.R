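#' Azimuth-elevation direction grid
#'
#' Regular grid over the far-field sphere on which beam patterns are
#' evaluated. Azimuth spans \[-180, 180\] degrees (positive to the bat's
#' left), elevation \[-90, 90\] (positive dorsal).
#'
#' @param az_step,el_step Grid steps in degrees (default 1).
#' @param az_range,el_range Length-2 numeric ranges in degrees.
#' @return A `direction_grid` object: azimuth/elevation sample vectors plus
#'   the matrix of unit direction vectors, row-major over (azimuth,
#'   elevation).
#' @examples
#' g <- direction_grid(az_step = 5, el_step = 5)
#' dim(g$units)
#' @export
direction_grid <- function(az_step = 1, el_step = 1,
                           az_range = c(-180, 180), el_range = c(-90, 90)) {
  stopifnot(
    az_step > 0, el_step > 0,
    az_range[1] >= -180, az_range[2] <= 180, az_range[1] < az_range[2],
    el_range[1] >= -90, el_range[2] <= 90, el_range[1] < el_range[2]
  )
  azimuth <- seq(az_range[1], az_range[2], by = az_step)
  elevation <- seq(el_range[1], el_range[2], by = el_step)
  ae <- expand.grid(azimuth = azimuth, elevation = elevation)
  structure(
    list(
      azimuth = azimuth, elevation = elevation,
      units = sph_to_unit(ae$azimuth, ae$elevation)
    ),
    class = "direction_grid"
  )
}

#' @export
print.direction_grid <- function(x, ...) {
  cat(sprintf(
    "<direction_grid> %d x %d (az %g..%g, el %g..%g deg)\n",
    length(x$azimuth), length(x$elevation),
    min(x$azimuth), max(x$azimuth), min(x$elevation), max(x$elevation)
  ))
  invisible(x)
}

grid_dims <- function(grid) c(length(grid$azimuth), length(grid$elevation))
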