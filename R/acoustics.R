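# Forward models of beam formation. The piston in an infinite baffle is the
# conventional comparator for mouth-emitting biosonar; the transmission
# array is the tongue-driven model: aperture elements radiating with phase
# shifts exp(i k r_n) set by their distances r_n to the clicking tongue,
# summed coherently (P_total = sum_n P_n exp(i k r_n)). In free field each
# element is a unit-amplitude monopole; with a head mesh the per-element
# fields come from the boundary-element solver.

DB_FLOOR <- -120  # dB floor replacing -Inf at exact pattern nulls

#' Circular-piston beam pattern
#'
#' Directivity of a uniformly vibrating circular piston of radius `a` in an
#' infinite rigid baffle: `D(theta) = 2 J1(ka sin theta) / (ka sin theta)`,
#' axisymmetric about the piston axis, 0 dB on axis. The multi-frequency
#' structure is concentric: higher frequencies give narrower main lobes.
#'
#' @param radius Piston radius in metres.
#' @param frequency Frequency (Hz); may be a vector for a multi-frequency
#'   pattern.
#' @param medium An [acoustic_medium()].
#' @param grid A [direction_grid()].
#' @param axis Piston axis (unit vector), default the head aim +x.
#' @return A `beam_pattern`.
#' @examples
#' b <- piston_beam(0.004, 35e3, grid = direction_grid(5, 5))
#' max(b$db)  # 0
#' @export
piston_beam <- function(radius, frequency, medium = acoustic_medium(),
                        grid = direction_grid(), axis = c(1, 0, 0)) {
  stopifnot(radius > 0, all(frequency > 0))
  axis <- axis / sqrt(sum(axis^2))
  ct <- pmin(1, pmax(-1, drop(grid$units %*% axis)))
  st <- sqrt(1 - ct^2)
  db <- vapply(frequency, function(f) {
    ka <- wavenumber(f, medium) * radius
    x <- ka * st
    d <- ifelse(x < 1e-12, 1, 2 * besselJ(x, 1) / ifelse(x < 1e-12, 1, x))
    d[ct < 0] <- 0  # the baffled piston radiates into the front half space
    pmax(20 * log10(pmax(abs(d), 10^(DB_FLOOR / 20))), DB_FLOOR)
  }, numeric(nrow(grid$units)))
  new_beam_pattern(db, grid, frequency,
                   metadata = list(model = "piston", radius = radius))
}

#' Far-field factor of a phased point-source array
#'
#' Coherent far-field sum of unit monopoles at `positions` with prescribed
#' per-element phases: `P(u) = sum_n exp(i (phi_n - k x_n . u))` (the
#' far-field path from element n in direction u is shorter by `x_n . u`).
#' This is the primitive behind the free-field transmission-array model
#' and the classical steering law `sin(theta_s) = dphi / (k d)`.
#'
#' @param positions Element positions, n x 3 matrix, mm.
#' @param phases Per-element phases in radians.
#' @param frequency Frequency, Hz.
#' @param medium An [acoustic_medium()].
#' @param grid A [direction_grid()].
#' @return Complex vector of the summed field, one value per grid direction.
#' @export
array_factor <- function(positions, phases, frequency,
                         medium = acoustic_medium(), grid = direction_grid()) {
  stopifnot(frequency > 0, nrow(positions) == length(phases))
  k <- wavenumber(frequency, medium)
  proj <- grid$units %*% t(positions / 1000)  # n_dir x n
  drop(exp(1i * (matrix(phases, nrow(proj), ncol(proj), byrow = TRUE) - k * proj)) %*%
         rep(1, length(phases)))
}

#' Free-field transmission-array beam pattern
#'
#' The tongue-driven phased-array model without a full head solve: each
#' mouth-line element radiates with the phase shift `exp(i k r_n)` set by
#' its tongue-to-element range. The phase factors carry no amplitude
#' weighting. Two per-element source models are available:
#' `"monopole"` (isotropic unit sources, the bare free-field sum) and
#' `"baffled"` (a Kirchhoff-style obliquity factor `(1 + cos g)/2` about
#' each element's outward surface normal, approximating the head-baffled
#' per-element field and suppressing the nonphysical rear lobes).
#'
#' @param array An [place_elements()] spec.
#' @param tongue A [tongue_position()].
#' @param frequency Frequency (Hz), possibly a vector.
#' @param medium An [acoustic_medium()].
#' @param grid A [direction_grid()].
#' @param element_model `"monopole"` or `"baffled"`.
#' @return A `beam_pattern` with metadata recording the configuration.
#' @export
freefield_array_beam <- function(array, tongue, frequency,
                                 medium = acoustic_medium(),
                                 grid = direction_grid(),
                                 element_model = c("monopole", "baffled")) {
  element_model <- match.arg(element_model)
  stopifnot(array$n >= 1, all(frequency > 0))
  r_m <- element_ranges(tongue, array) / 1000
  amp <- if (element_model == "baffled") {
    if (is.null(array$normals)) {
      stop("baffled element model requires element normals (see place_elements)")
    }
    (1 + grid$units %*% t(array$normals)) / 2
  } else {
    1
  }
  pos_m <- array$positions / 1000
  db <- vapply(frequency, function(f) {
    k <- wavenumber(f, medium)
    ph <- exp(1i * (matrix(k * r_m, nrow(grid$units), array$n, byrow = TRUE) -
                      k * (grid$units %*% t(pos_m))))
    p <- rowSums(amp * ph)
    pmax(20 * log10(pmax(Mod(p), 10^(DB_FLOOR / 20))), DB_FLOOR)
  }, numeric(nrow(grid$units)))
  new_beam_pattern(
    db, grid, frequency,
    metadata = list(
      model = "transmission_array", method = "freefield",
      element_model = element_model,
      tongue = tongue$location, n_elements = array$n, side = array$side
    )
  )
}

#' Coherently combine per-element fields with tongue-path phase shifts
#'
#' Implements the transmission-array sum `P_total = sum_n P_n exp(i k r_n)`:
#' the complex per-element far fields are phase-shifted by the tongue-to-
#' element ranges and summed, and the result is returned as a normalized
#' beam pattern. Adding a constant to every range changes `P_total` by a
#' global phase only and leaves the pattern unchanged.
#'
#' @param fields List of `element_field` objects sharing grid and frequency.
#' @param ranges Tongue-to-element ranges, mm (one per field).
#' @param medium An [acoustic_medium()].
#' @param metadata Optional metadata list stored on the result.
#' @return A `beam_pattern` at the fields' frequency.
#' @export
combine_elements <- function(fields, ranges, medium = acoustic_medium(),
                             metadata = list()) {
  stopifnot(length(fields) == length(ranges), length(fields) >= 1)
  f0 <- fields[[1]]
  for (f in fields) {
    if (!identical(dim(f$values), dim(f0$values)) ||
        !isTRUE(all.equal(f$frequency, f0$frequency)) ||
        !identical(f$grid$azimuth, f0$grid$azimuth) ||
        !identical(f$grid$elevation, f0$grid$elevation)) {
      stop("element fields must share grid and frequency")
    }
  }
  k <- wavenumber(f0$frequency, medium)
  total <- Reduce(`+`, Map(
    function(f, r) f$values * exp(1i * k * r / 1000), fields, ranges
  ))
  db <- pmax(20 * log10(pmax(Mod(total), 10^(DB_FLOOR / 20))), DB_FLOOR)
  new_beam_pattern(
    matrix(db, ncol = 1), f0$grid, f0$frequency,
    metadata = utils::modifyList(list(model = "transmission_array"), metadata)
  )
}

#' Transmission-array beam pattern (free-field or BEM)
#'
#' Evaluates the tongue-driven transmission-array model over one or more
#' frequencies. `method = "freefield"` (fast mode) treats elements as free
#' monopoles; `method = "bem"` computes each element's radiation in the
#' presence of the rigid head via the boundary-element solver, then combines
#' them coherently.
#'
#' @param array An [place_elements()] spec.
#' @param tongue A [tongue_position()].
#' @param frequencies Frequencies in Hz (default 25-55 kHz in 5 kHz steps).
#' @param mesh Head mesh (required for `method = "bem"`).
#' @param method `"freefield"` or `"bem"`.
#' @param medium An [acoustic_medium()].
#' @param grid A [direction_grid()].
#' @param element_model Per-element source model in fast mode; the default
#'   `"baffled"` approximates the head-baffled element fields (see
#'   [freefield_array_beam()]).
#' @return A multi-frequency `beam_pattern`.
#' @export
transmission_array_beam <- function(array, tongue,
                                    frequencies = seq(25e3, 55e3, by = 5e3),
                                    mesh = NULL,
                                    method = c("freefield", "bem"),
                                    medium = acoustic_medium(),
                                    grid = direction_grid(),
                                    element_model = "baffled") {
  method <- match.arg(method)
  stopifnot(length(frequencies) >= 1)
  if (method == "freefield") {
    return(freefield_array_beam(array, tongue, frequencies, medium, grid,
                                element_model = element_model))
  }
  if (is.null(mesh)) stop("BEM method requires a head mesh")
  ranges <- element_ranges(tongue, array)
  db <- vapply(frequencies, function(f) {
    fields <- lapply(seq_len(array$n), function(n) {
      bem_element_field(mesh, array$positions[n, ], f, medium, grid)
    })
    combine_elements(fields, ranges, medium)$db[, 1]
  }, numeric(nrow(grid$units)))
  new_beam_pattern(
    db, grid, frequencies,
    metadata = list(
      model = "transmission_array", method = "bem",
      tongue = tongue$location, n_elements = array$n, side = array$side
    )
  )
}
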