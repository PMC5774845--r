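# Head meshes are closed triangulated surfaces in millimetres, with an
# ordered set of vertices tagged along the narrow mouth opening (the lip
# seam). The simplified head is the canonical geometry: a latitude-longitude
# ellipsoid tapered toward the rostrum, with optional compact-support ear
# bumps, scaled so its bounding box matches the requested head dimensions.

new_head_mesh <- function(vertices, triangles, mouth_line, provenance, params = list()) {
  structure(
    list(
      vertices = vertices, triangles = triangles,
      mouth_line = mouth_line, provenance = provenance, params = params
    ),
    class = "head_mesh"
  )
}

#' @export
print.head_mesh <- function(x, ...) {
  cat(sprintf(
    "<head_mesh> %d vertices, %d triangles, %d mouth-line nodes (%s)\n",
    nrow(x$vertices), nrow(x$triangles), nrow(x$mouth_line), x$provenance
  ))
  invisible(x)
}

#' Build the simplified artificial bat head
#'
#' Constructs a closed, consistently oriented triangulated head: an
#' ellipsoid tapered toward the rostrum (+x), with optional ear bumps on the
#' upper rear, scaled so the axis-aligned bounding box is exactly
#' `length` x `width` x `height`. Vertices along the lip seam (a horizontal
#' ring slightly below the mid-plane, restricted to the rostral arc) are
#' tagged as the mouth line, ordered rostral to caudal within each side.
#'
#' The construction is deterministic: identical parameters give a
#' byte-identical mesh.
#'
#' @param length,width,height Head dimensions in mm (x, y, z).
#' @param rostrum_taper Fractional narrowing of the rostral half at the tip
#'   (0 = none).
#' @param ears Logical; add ear bumps on the upper rear of the head.
#' @param ear_height Radial ear bump amplitude as a fraction of local radius.
#' @param mouth_colat Colatitude (degrees from dorsal pole) of the lip seam
#'   row; slightly over 90 puts the mouth just below the mid-plane.
#' @param mouth_half_angle Half-width of the mouth arc around the rostral
#'   midline, degrees of longitude.
#' @param edge_target Target edge length along the seam, mm; controls mesh
#'   resolution.
#' @return A `head_mesh` object.
#' @examples
#' m <- build_simplified_head(40, 25, 25, edge_target = 2)
#' range(m$vertices[, 1])
#' @export
build_simplified_head <- function(length = 40, width = 25, height = 25,
                                  rostrum_taper = 0.55, ears = TRUE,
                                  ear_height = 0.25, mouth_colat = 102,
                                  mouth_half_angle = 60, edge_target = 0.5) {
  stopifnot(length > 0, width > 0, height > 0, edge_target > 0,
            rostrum_taper >= 0, rostrum_taper < 1)
  rx <- length / 2; ry <- width / 2; rz <- height / 2

  # resolution from the target edge length; counts rounded so that vertices
  # sit exactly at the +/-x, +/-y extremes and at the dorsal/ventral poles,
  # making the bounding box exact
  circ <- 2 * pi * sqrt((rx^2 + ry^2) / 2)
  merid <- pi * sqrt((ry^2 + rz^2) / 2)
  n_phi <- max(24, 4 * round(circ / edge_target / 4))
  n_theta <- max(12, 2 * round(merid / edge_target / 2))

  theta <- (1:(n_theta - 1)) * pi / n_theta        # colatitude, excl. poles
  psi <- (0:(n_phi - 1)) * 2 * pi / n_phi          # longitude, 0 = rostral
  tp <- expand.grid(psi = psi, theta = theta)      # psi varies fastest
  st <- sin(tp$theta); ct <- cos(tp$theta)
  x0 <- st * cos(tp$psi); y0 <- st * sin(tp$psi); z0 <- ct

  # rostral taper: shrink y and z toward the axis for x0 > 0
  s <- ifelse(x0 > 0, 1 - rostrum_taper * x0^2, 1)
  verts <- cbind(rx * x0, ry * s * y0, rz * s * z0)

  if (ears) {
    for (sgn in c(1, -1)) {
      ctr <- sph_to_unit(sgn * 130, 45)[1, ]
      gamma <- acos(pmin(1, pmax(-1, x0 * ctr[1] + y0 * ctr[2] + z0 * ctr[3])))
      r_ear <- deg2rad(25)
      bump <- ifelse(gamma < r_ear, ear_height * (1 - (gamma / r_ear)^2)^2, 0)
      verts <- verts * (1 + bump)
    }
  }
  verts <- rbind(verts, c(0, 0, rz), c(0, 0, -rz))  # dorsal, ventral poles
  np <- (n_theta - 1) * n_phi + 1
  sp <- np + 1

  idx <- function(i, j) (i - 1) * n_phi + ((j - 1) %% n_phi) + 1
  tris <- vector("list", n_theta)
  i <- 1:(n_theta - 2)
  if (n_theta > 2) {
    j <- rep(1:n_phi, each = n_theta - 2)
    ii <- rep(i, times = n_phi)
    v1 <- idx(ii, j); v2 <- idx(ii, j + 1)
    v3 <- idx(ii + 1, j + 1); v4 <- idx(ii + 1, j)
    tris[[1]] <- cbind(v1, v2, v3)
    tris[[2]] <- cbind(v1, v3, v4)
  }
  jj <- 1:n_phi
  tris[[3]] <- cbind(rep(np, n_phi), idx(1, jj + 1), idx(1, jj))
  tris[[4]] <- cbind(rep(sp, n_phi), idx(n_theta - 1, jj), idx(n_theta - 1, jj + 1))
  triangles <- do.call(rbind, tris)
  dimnames(triangles) <- NULL

  if (mesh_volume(verts, triangles) < 0) triangles <- triangles[, c(1, 3, 2)]
  if (!edges_consistent(triangles)) {
    stop("simplified head construction produced a non-manifold mesh")
  }

  # mouth line: rostral arc of the seam row
  i_m <- which.min(abs(theta - deg2rad(mouth_colat)))
  psi_deg <- rad2deg(psi)
  psi_signed <- ifelse(psi_deg > 180, psi_deg - 360, psi_deg)
  sel <- which(abs(psi_signed) <= mouth_half_angle & psi_signed != 0)
  vid <- idx(i_m, sel)
  side <- ifelse(psi_signed[sel] > 0, "left", "right")
  # rostral -> caudal within each side = increasing |psi|
  ord <- order(side, abs(psi_signed[sel]))
  mouth_line <- tibble::tibble(
    vertex = vid[ord], side = side[ord]
  ) |>
    dplyr::group_by(side) |>
    dplyr::mutate(position = dplyr::row_number()) |>
    dplyr::ungroup()

  new_head_mesh(
    verts, triangles, mouth_line,
    provenance = if (ears) "simplified" else "variant",
    params = list(
      length = length, width = width, height = height,
      rostrum_taper = rostrum_taper, ears = ears, ear_height = ear_height,
      mouth_colat = mouth_colat, mouth_half_angle = mouth_half_angle,
      edge_target = edge_target
    )
  )
}

#' Triangulated sphere (subdivided icosahedron)
#'
#' Reference scatterer for validating the boundary-element solver against
#' the analytic point-source-plus-rigid-sphere series.
#'
#' @param radius Sphere radius (same units as downstream use).
#' @param subdivisions Number of 4-to-1 refinements of the icosahedron
#'   (edge length roughly `1.05 * radius / 2^subdivisions`).
#' @return A `head_mesh` object with an empty mouth line.
#' @export
sphere_mesh <- function(radius = 1, subdivisions = 2) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1)
  )
  v <- normalize_rows(v)
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2)
  )
  for (s in seq_len(subdivisions)) {
    cache <- new.env(hash = TRUE)
    nv <- nrow(v)
    vlist <- list(v)
    midpoint <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      hit <- cache[[key]]
      if (!is.null(hit)) return(hit)
      nv <<- nv + 1
      vlist[[base::length(vlist) + 1]] <<- normalize_rows(v[a, ] + v[b, ])
      cache[[key]] <- nv
      nv
    }
    nf <- matrix(0L, nrow = 4 * nrow(f), ncol = 3)
    for (t in seq_len(nrow(f))) {
      a <- f[t, 1]; b <- f[t, 2]; cc <- f[t, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, cc); ca <- midpoint(cc, a)
      nf[4 * t - 3, ] <- c(a, ab, ca)
      nf[4 * t - 2, ] <- c(b, bc, ab)
      nf[4 * t - 1, ] <- c(cc, ca, bc)
      nf[4 * t, ] <- c(ab, bc, ca)
    }
    v <- do.call(rbind, vlist)
    f <- nf
  }
  if (mesh_volume(v * radius, f) < 0) f <- f[, c(1, 3, 2)]
  new_head_mesh(
    v * radius, f,
    mouth_line = tibble::tibble(vertex = integer(), side = character(),
                                position = integer()),
    provenance = "variant",
    params = list(radius = radius, subdivisions = subdivisions)
  )
}

# --- mesh measures -----------------------------------------------------------

mesh_volume <- function(vertices, triangles) {
  a <- vertices[triangles[, 1], , drop = FALSE]
  b <- vertices[triangles[, 2], , drop = FALSE]
  cc <- vertices[triangles[, 3], , drop = FALSE]
  cr <- cbind(
    b[, 2] * cc[, 3] - b[, 3] * cc[, 2],
    b[, 3] * cc[, 1] - b[, 1] * cc[, 3],
    b[, 1] * cc[, 2] - b[, 2] * cc[, 1]
  )
  sum(rowSums(a * cr)) / 6
}

# every directed edge must appear exactly once (closed, consistently
# oriented 2-manifold)
edges_consistent <- function(triangles) {
  e <- rbind(
    triangles[, c(1, 2)], triangles[, c(2, 3)], triangles[, c(3, 1)]
  )
  keys <- paste(e[, 1], e[, 2])
  rkeys <- paste(e[, 2], e[, 1])
  !anyDuplicated(keys) && all(keys %in% rkeys)
}

#' Check that a mesh is closed and consistently oriented
#'
#' @param mesh A `head_mesh`.
#' @return `TRUE` if every directed edge occurs exactly once and its reverse
#'   occurs in a neighbouring triangle.
#' @export
mesh_is_watertight <- function(mesh) {
  edges_consistent(mesh$triangles)
}

mesh_face_geometry <- function(mesh) {
  v <- mesh$vertices; f <- mesh$triangles
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  cc <- v[f[, 3], , drop = FALSE]
  u <- b - a; w <- cc - a
  cr <- cbind(
    u[, 2] * w[, 3] - u[, 3] * w[, 2],
    u[, 3] * w[, 1] - u[, 1] * w[, 3],
    u[, 1] * w[, 2] - u[, 2] * w[, 1]
  )
  nrm <- sqrt(rowSums(cr^2))
  list(
    centroids = (a + b + cc) / 3,
    normals = cr / nrm,
    areas = nrm / 2,
    va = a, vb = b, vc = cc
  )
}

mesh_edge_stats <- function(mesh) {
  f <- mesh$triangles; v <- mesh$vertices
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  len <- sqrt(rowSums((v[e[, 1], ] - v[e[, 2], ])^2))
  c(mean = mean(len), max = max(len))
}

#' Apply a rigid transform to a mesh
#'
#' @param mesh A `head_mesh`.
#' @param rotation 3x3 rotation matrix.
#' @param translation Length-3 vector, mm.
#' @return The transformed `head_mesh`.
#' @export
transform_mesh <- function(mesh, rotation = diag(3), translation = c(0, 0, 0)) {
  mesh$vertices <- mesh$vertices %*% t(rotation) +
    matrix(translation, nrow(mesh$vertices), 3, byrow = TRUE)
  mesh
}
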