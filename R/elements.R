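# Mouth-aperture transmission elements. The array elements are mesh
# vertices along the mouth line; together with a tongue position they give
# the ranges r_n whose phase shifts exp(i k r_n) drive the coherent sum.

new_array_spec <- function(positions, side, mode, vertex = NULL,
                           normals = NULL) {
  structure(
    list(
      positions = positions, side = side, mode = mode,
      n = nrow(positions), vertex = vertex, normals = normals
    ),
    class = "array_spec"
  )
}

#' @export
print.array_spec <- function(x, ...) {
  cat(sprintf(
    "<array_spec> %d elements, side = %s, mode = %s\n", x$n, x$side, x$mode
  ))
  invisible(x)
}

#' Place transmission elements along the mouth opening
#'
#' Selects element positions among the mouth-line vertices of a head mesh.
#' Discrete mode picks `n` elements evenly spread by arc length
#' (representing gaps between clenched teeth); continuous mode walks the
#' seam picking nodes at a target `spacing` (representing the narrow gap of
#' parted lips). Elements are ordered rostral to caudal. `side = "both"`
#' mirrors the left-side elements across the sagittal plane.
#'
#' @param mesh A [build_simplified_head()] mesh with a populated mouth line.
#' @param side `"left"`, `"right"` or `"both"`.
#' @param mode `"discrete"` or `"continuous"`.
#' @param n Element count per side (discrete mode).
#' @param spacing Target inter-element arc spacing in mm (continuous mode).
#' @param shift Shift of the selected block along the seam, in elements
#'   toward the rostrum (negative) or caudal end (positive); used for the
#'   forward-array variants.
#' @param arc_range Length-2 fractional window of the seam arc (rostral 0
#'   to caudal 1) within which elements are placed.
#' @return An `array_spec` with element positions (mm) and outward surface
#'   normals at the elements.
#' @export
place_elements <- function(mesh, side = c("left", "right", "both"),
                           mode = c("discrete", "continuous"),
                           n = NULL, spacing = NULL, shift = 0,
                           arc_range = c(0, 1)) {
  side <- match.arg(side)
  mode <- match.arg(mode)
  pick_side <- if (side == "both") "left" else side
  ml <- dplyr::filter(mesh$mouth_line, .data$side == pick_side) |>
    dplyr::arrange(.data$position)
  if (nrow(ml) == 0) stop("mesh has no mouth-line vertices on side ", pick_side)
  stopifnot(length(arc_range) == 2, arc_range[1] >= 0, arc_range[2] <= 1,
            arc_range[1] < arc_range[2])
  pts_full <- mesh$vertices[ml$vertex, , drop = FALSE]
  arc_full <- c(0, cumsum(sqrt(rowSums(diff(pts_full)^2))))
  keep <- arc_full >= arc_range[1] * max(arc_full) - 1e-9 &
    arc_full <= arc_range[2] * max(arc_full) + 1e-9
  ml <- ml[keep, , drop = FALSE]
  pts <- pts_full[keep, , drop = FALSE]
  arc <- arc_full[keep] - arc_full[keep][1]

  if (mode == "discrete") {
    if (is.null(n)) stop("discrete mode requires `n`")
    if (n > nrow(ml)) {
      stop(sprintf("requested %d elements but only %d mouth-line nodes", n, nrow(ml)))
    }
    targets <- if (n == 1) max(arc) / 2 else seq(0, max(arc), length.out = n)
    sel <- vapply(targets, function(s) which.min(abs(arc - s)), integer(1))
    sel <- unique(sel)
  } else {
    if (is.null(spacing)) stop("continuous mode requires `spacing`")
    sel <- 1L
    last <- arc[1]
    repeat {
      target <- last + spacing
      cand <- which(arc > last + 1e-9)
      cand <- cand[cand > sel[length(sel)]]
      if (length(cand) == 0) break
      nxt <- cand[which.min(abs(arc[cand] - target))]
      if (arc[nxt] <= last + 1e-9) break
      sel <- c(sel, nxt)
      last <- arc[nxt]
    }
  }
  sel <- sel + as.integer(shift)
  if (any(sel < 1 | sel > nrow(ml))) {
    stop("element shift moves elements off the mouth line")
  }
  pos <- pts[sel, , drop = FALSE]
  vid <- ml$vertex[sel]
  nrm <- element_normals(mesh, pos)
  if (side == "both") {
    pos <- rbind(pos, pos %*% diag(c(1, -1, 1)))
    nrm <- rbind(nrm, nrm %*% diag(c(1, -1, 1)))
    vid <- c(vid, rep(NA_integer_, length(sel)))
  }
  new_array_spec(pos, side, mode, vertex = vid, normals = nrm)
}

# outward surface normal at each element: normal of the nearest face
element_normals <- function(mesh, positions) {
  geom <- mesh_face_geometry(mesh)
  t(apply(positions, 1, function(p) {
    i <- which.min(colSums((t(geom$centroids) - p)^2))
    geom$normals[i, ]
  }))
}

#' Tongue clicking position
#'
#' A point inside the mouth cavity from which the click originates. The
#' position must lie within the head's bounding box and not forward of the
#' mouth line.
#'
#' @param location Length-3 numeric, mm, head frame (x rostral, y left,
#'   z dorsal).
#' @param side Optional side label (`"left"`, `"right"` or `NA`).
#' @param mesh Optional `head_mesh` used to validate the location.
#' @return A `tongue_position` object.
#' @export
tongue_position <- function(location, side = NA_character_, mesh = NULL) {
  stopifnot(is.numeric(location), length(location) == 3)
  if (!is.null(mesh)) {
    bb_lo <- apply(mesh$vertices, 2, min)
    bb_hi <- apply(mesh$vertices, 2, max)
    if (any(location < bb_lo) || any(location > bb_hi)) {
      stop("tongue position lies outside the head bounding box")
    }
    if (nrow(mesh$mouth_line) > 0) {
      x_max <- max(mesh$vertices[mesh$mouth_line$vertex, 1])
      if (location[1] > x_max) {
        stop("tongue position lies forward of the mouth line (outside the cavity)")
      }
    }
  }
  structure(list(location = as.numeric(location), side = side),
            class = "tongue_position")
}

#' @export
print.tongue_position <- function(x, ...) {
  cat(sprintf(
    "<tongue_position> (%.1f, %.1f, %.1f) mm%s\n",
    x$location[1], x$location[2], x$location[3],
    if (is.na(x$side)) "" else paste0(", side = ", x$side)
  ))
  invisible(x)
}

#' Tongue-to-element ranges
#'
#' Euclidean distances from the tongue clicking location to each array
#' element, in mm. These ranges set the per-element phase shifts
#' `exp(i k r_n)` of the transmission-array model.
#'
#' @param tongue A [tongue_position()].
#' @param array An [place_elements()] spec.
#' @return Numeric vector of ranges, mm, one per element.
#' @export
element_ranges <- function(tongue, array) {
  d <- sweep(array$positions, 2, tongue$location)
  r <- sqrt(rowSums(d^2))
  if (any(r < 1e-9)) stop("tongue position coincides with an array element")
  unname(r)
}

#' Mirror an array spec across the sagittal plane
#'
#' @param array An `array_spec`.
#' @return The mirrored spec (y negated, side label swapped).
#' @export
mirror_array <- function(array) {
  array$positions <- array$positions %*% diag(c(1, -1, 1))
  if (!is.null(array$normals)) {
    array$normals <- array$normals %*% diag(c(1, -1, 1))
  }
  array$side <- switch(array$side, left = "right", right = "left", both = "both")
  array
}
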