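# The beam_pattern class holds normalized beam energy (dB re maximum, so
# max = 0 dB at every frequency) over a direction grid, for one or more
# frequencies. Values are stored as an n_direction x n_frequency matrix
# (azimuth varying fastest within a direction column, matching the grid).

new_beam_pattern <- function(db, grid, frequency, metadata = list()) {
  db <- as.matrix(db)
  stopifnot(nrow(db) == nrow(grid$units), ncol(db) == length(frequency))
  # normalize: max per frequency exactly 0 dB
  db <- sweep(db, 2, apply(db, 2, max))
  structure(
    list(db = db, grid = grid, frequency = frequency, metadata = metadata),
    class = "beam_pattern"
  )
}

#' @export
print.beam_pattern <- function(x, ...) {
  cat(sprintf(
    "<beam_pattern> %s: %d directions x %d frequencies (%g-%g kHz)\n",
    x$metadata$model %||% "model", nrow(x$db), length(x$frequency),
    min(x$frequency) / 1e3, max(x$frequency) / 1e3
  ))
  invisible(x)
}

#' Extract one frequency slice of a beam pattern as a matrix
#'
#' @param beam A `beam_pattern`.
#' @param frequency Frequency in Hz; must match one of `beam$frequency`.
#' @return A matrix \[azimuth x elevation\] of normalized dB.
#' @export
beam_slice <- function(beam, frequency) {
  i <- match(frequency, beam$frequency)
  if (is.na(i)) stop("frequency ", frequency, " not present in beam pattern")
  matrix(beam$db[, i], nrow = length(beam$grid$azimuth))
}

#' @rdname tidy.beam_pattern
#' @method tidy beam_pattern
#' @export
tidy.beam_pattern <- function(x, ...) {
  tidyr::expand_grid(
    frequency = x$frequency,
    elevation = x$grid$elevation,
    azimuth = x$grid$azimuth
  ) |>
    dplyr::arrange(.data$frequency, .data$elevation, .data$azimuth) |>
    dplyr::mutate(db = as.vector(x$db))
}

#' Tidy a beam pattern into a long tibble
#'
#' Returns one row per (frequency, azimuth, elevation) with the normalized
#' energy in dB. This is also the CSV serialization format.
#'
#' @param x A `beam_pattern`.
#' @param ... Unused.
#' @return A tibble with columns `frequency`, `elevation`, `azimuth`, `db`.
#' @name tidy.beam_pattern
NULL

#' Write / read a beam pattern as long-format CSV
#'
#' Columns `frequency`, `elevation`, `azimuth`, `db`; grid and metadata are
#' recovered from the table on read.
#'
#' @param beam A `beam_pattern`.
#' @param path CSV path.
#' @return `write_beam_csv` returns `path` invisibly; `read_beam_csv`
#'   returns a `beam_pattern`.
#' @export
write_beam_csv <- function(beam, path) {
  utils::write.csv(tidy(beam), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_beam_csv
#' @export
read_beam_csv <- function(path) {
  df <- utils::read.csv(path)
  az <- sort(unique(df$azimuth))
  el <- sort(unique(df$elevation))
  fr <- sort(unique(df$frequency))
  grid <- direction_grid(
    az_step = if (length(az) > 1) az[2] - az[1] else 1,
    el_step = if (length(el) > 1) el[2] - el[1] else 1,
    az_range = range(az), el_range = range(el)
  )
  df <- dplyr::arrange(df, .data$frequency, .data$elevation, .data$azimuth)
  db <- matrix(df$db, nrow = length(az) * length(el), ncol = length(fr))
  new_beam_pattern(db, grid, fr, metadata = list(model = "csv"))
}

# bilinear interpolation of one frequency slice at arbitrary directions
beam_value_at <- function(beam, azimuth, elevation, frequency) {
  m <- beam_slice(beam, frequency)
  gaz <- beam$grid$azimuth
  gel <- beam$grid$elevation
  az <- pmin(pmax(azimuth, min(gaz)), max(gaz))
  el <- pmin(pmax(elevation, min(gel)), max(gel))
  ia <- pmin(findInterval(az, gaz), length(gaz) - 1)
  ie <- pmin(findInterval(el, gel), length(gel) - 1)
  ta <- (az - gaz[ia]) / (gaz[ia + 1] - gaz[ia])
  te <- (el - gel[ie]) / (gel[ie + 1] - gel[ie])
  m[cbind(ia, ie)] * (1 - ta) * (1 - te) +
    m[cbind(ia + 1, ie)] * ta * (1 - te) +
    m[cbind(ia, ie + 1)] * (1 - ta) * te +
    m[cbind(ia + 1, ie + 1)] * ta * te
}
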