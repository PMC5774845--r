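# Exterior Helmholtz boundary-element solver for radiation of a point
# source in the presence of a rigid (zero normal velocity) closed surface.
#
# Formulation: direct collocation with piecewise-constant pressure on flat
# triangles. With G(x, y) = exp(ikR)/(4 pi R), time convention exp(-i w t),
# and surface normals pointing into the fluid, the total surface pressure
# satisfies
#     (1/2) p(x) + pv int_S dG/dn_y(x, y) p(y) dS = p_inc(x),  x on S,
# where p_inc is the free-field monopole. The flat-element self term of the
# double-layer kernel vanishes (the collocation point lies in the element
# plane), so the diagonal is exactly 1/2. Irregular interior resonance
# frequencies are handled by CHIEF: extra collocation rows at interior
# points x0 where  int_S dG/dn_y p dS = p_inc(x0), solved by least
# squares. Signs validated against the analytic monopole-plus-rigid-sphere
# series.

# Dunavant degree-4 quadrature on the unit triangle (barycentric, weights
# sum to 1)
TRI_QUAD <- local({
  a <- 0.445948490915965; b <- 0.091576213509771
  wa <- 0.223381589678011; wb <- 0.109951743655322
  list(
    bary = rbind(
      c(1 - 2 * a, a, a), c(a, 1 - 2 * a, a), c(a, a, 1 - 2 * a),
      c(1 - 2 * b, b, b), c(b, 1 - 2 * b, b), c(b, b, 1 - 2 * b)
    ),
    w = c(wa, wa, wa, wb, wb, wb)
  )
})

# free-field monopole and its kernel helpers (positions in metres)
monopole_pressure <- function(x, source) {
  d <- sweep(x, 2, source)
  r <- sqrt(rowSums(d^2))
  exp(1i * attr(x, "k") * r) / (4 * pi * r)
}

# assemble the double-layer collocation matrix D_ij = pv int_Tj dG/dn dS
bem_double_layer <- function(X, geom, k) {
  n_el <- nrow(X)
  D <- matrix(0 + 0i, n_el, n_el)
  An <- X %*% t(geom$normals)           # X_i . n_j
  for (q in seq_along(TRI_QUAD$w)) {
    b <- TRI_QUAD$bary[q, ]
    Y <- b[1] * geom$va + b[2] * geom$vb + b[3] * geom$vc
    R2 <- outer(rowSums(X^2), rep(1, n_el)) +
      outer(rep(1, n_el), rowSums(Y^2)) - 2 * (X %*% t(Y))
    R <- sqrt(pmax(R2, 1e-300))
    dn <- An - outer(rep(1, n_el), rowSums(Y * geom$normals))  # (X-Y).n_j
    kern <- exp(1i * k * R) * (1i * k * R - 1) / (4 * pi * R^2) * (dn / R)
    diag(kern) <- 0
    D <- D + TRI_QUAD$w[q] *
      kern * outer(rep(1, n_el), geom$areas)
  }
  D
}

# solve for surface pressure given a monopole source (all in metres)
bem_surface_pressure <- function(geom, source, k, n_chief = 4) {
  X <- geom$centroids
  n_el <- nrow(X)
  D <- bem_double_layer(X, geom, k)
  A <- diag(n_el) / 2 + D
  src_d <- sweep(X, 2, source)
  rhs <- exp(1i * k * sqrt(rowSums(src_d^2))) / (4 * pi * sqrt(rowSums(src_d^2)))

  if (n_chief > 0) {
    ctr <- colMeans(geom$centroids)
    span <- apply(geom$centroids, 2, function(v) diff(range(v)))
    dirs <- rbind(
      c(0, 0, 0), c(1, 1, 1), c(-1, 1, -1), c(1, -1, -1), c(-1, -1, 1),
      c(1, 0, -1)
    )[seq_len(n_chief), , drop = FALSE]
    Xi <- sweep(dirs * 0.17, 2, span, `*`)
    Xi <- sweep(Xi, 2, ctr, `+`)
    Dc <- matrix(0 + 0i, n_chief, n_el)
    Anc <- Xi %*% t(geom$normals)
    for (q in seq_along(TRI_QUAD$w)) {
      b <- TRI_QUAD$bary[q, ]
      Y <- b[1] * geom$va + b[2] * geom$vb + b[3] * geom$vc
      R2 <- outer(rowSums(Xi^2), rep(1, n_el)) +
        outer(rep(1, n_chief), rowSums(Y^2)) - 2 * (Xi %*% t(Y))
      R <- sqrt(R2)
      dn <- Anc - outer(rep(1, n_chief), rowSums(Y * geom$normals))
      kern <- exp(1i * k * R) * (1i * k * R - 1) / (4 * pi * R^2) * (dn / R)
      Dc <- Dc + TRI_QUAD$w[q] * kern * outer(rep(1, n_chief), geom$areas)
    }
    di <- sweep(Xi, 2, source)
    rc <- sqrt(rowSums(di^2))
    A <- rbind(A, Dc)
    rhs <- c(rhs, exp(1i * k * rc) / (4 * pi * rc))
  }

  p <- qr.solve(A, rhs)
  # least-squares residual: CHIEF rows are consistent only to discretization
  # error, so the tolerance is loose relative to a square direct solve
  res <- sqrt(sum(Mod(A %*% p - rhs)^2) / sum(Mod(rhs)^2))
  if (res > 1e-3) {
    stop(sprintf("BEM solve did not converge (relative residual %.2e)", res))
  }
  p
}

# far-field directivity (coefficient of exp(ikr)/r) of incident + scattered
bem_far_pattern <- function(geom, p_surf, source, k, grid) {
  U <- grid$units
  # incident monopole far field
  F_tot <- exp(-1i * k * drop(U %*% source)) / (4 * pi)
  for (q in seq_along(TRI_QUAD$w)) {
    b <- TRI_QUAD$bary[q, ]
    Y <- b[1] * geom$va + b[2] * geom$vb + b[3] * geom$vc
    ph <- exp(-1i * k * (U %*% t(Y)))          # n_dir x n_el
    wcol <- TRI_QUAD$w[q] * geom$areas * p_surf
    F_tot <- F_tot - (1i * k / (4 * pi)) *
      drop(((U %*% t(geom$normals)) * ph) %*% wcol)
  }
  F_tot
}

#' Far-field radiation of a monopole near a rigid mesh (BEM)
#'
#' Solves the exterior Helmholtz problem for a unit monopole radiating in
#' the presence of a rigid closed surface and evaluates the total far field
#' on a direction grid. Collocation with piecewise-constant elements;
#' interior (CHIEF) points guard against irregular interior resonances.
#'
#' @param mesh A `head_mesh` (coordinates in mm).
#' @param source Length-3 source position, mm. Must lie off the surface.
#' @param frequency Frequency, Hz.
#' @param medium An [acoustic_medium()].
#' @param grid A [direction_grid()].
#' @param n_chief Number of interior stabilization points (0 disables).
#' @return An `element_field`: complex far-field values (coefficient of
#'   `exp(ikr)/r`) per grid direction, plus grid and frequency.
#' @export
bem_far_field <- function(mesh, source, frequency,
                          medium = acoustic_medium(),
                          grid = direction_grid(5, 5), n_chief = 4) {
  stopifnot(frequency > 0, length(source) == 3)
  k <- wavenumber(frequency, medium)
  lambda_mm <- 1000 * medium$sound_speed / frequency
  edges <- mesh_edge_stats(mesh)
  if (edges["max"] > lambda_mm / 5) {
    stop(sprintf(
      "mesh too coarse: max edge %.2f mm exceeds lambda/5 = %.2f mm",
      edges["max"], lambda_mm / 5
    ))
  }
  if (edges["max"] > lambda_mm / 6) {
    warning(sprintf(
      "mesh edge %.2f mm exceeds lambda/6 = %.2f mm; accuracy may degrade",
      edges["max"], lambda_mm / 6
    ))
  }
  geom <- mesh_face_geometry(mesh)
  geom_m <- list(
    centroids = geom$centroids / 1000, normals = geom$normals,
    areas = geom$areas / 1e6,
    va = geom$va / 1000, vb = geom$vb / 1000, vc = geom$vc / 1000
  )
  src <- source / 1000
  p <- bem_surface_pressure(geom_m, src, k, n_chief = n_chief)
  vals <- bem_far_pattern(geom_m, p, src, k, grid)
  structure(
    list(values = vals, grid = grid, frequency = frequency,
         surface_pressure = p),
    class = "element_field"
  )
}

#' Per-element radiated field for the transmission-array model
#'
#' Places a unit monopole just outside the head surface at a mouth-line
#' element (offset one mean edge length along the local face normal) and
#' returns its BEM far field. These fields are combined coherently by
#' [combine_elements()].
#'
#' @param mesh A `head_mesh`, mm.
#' @param element_position Length-3 position on (or near) the surface, mm.
#' @param frequency Frequency, Hz.
#' @param medium An [acoustic_medium()].
#' @param grid A [direction_grid()].
#' @param ... Passed to [bem_far_field()].
#' @return An `element_field`.
#' @export
bem_element_field <- function(mesh, element_position, frequency,
                              medium = acoustic_medium(),
                              grid = direction_grid(5, 5), ...) {
  geom <- mesh_face_geometry(mesh)
  d <- sweep(geom$centroids, 2, element_position)
  dist <- sqrt(rowSums(d^2))
  i <- which.min(dist)
  edge <- mesh_edge_stats(mesh)["mean"]
  if (dist[i] > edge) {
    stop(sprintf(
      "element position is %.2f mm from the surface (> one edge length %.2f mm)",
      dist[i], edge
    ))
  }
  src <- element_position + edge * geom$normals[i, ]
  bem_far_field(mesh, src, frequency, medium, grid, ...)
}

#' @export
print.element_field <- function(x, ...) {
  cat(sprintf(
    "<element_field> %d directions at %.1f kHz\n",
    length(x$values), x$frequency / 1e3
  ))
  invisible(x)
}
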