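# Plain-text mesh interchange: ASCII STL and Wavefront OBJ, with the mouth
# line persisted in a JSON sidecar (<path>.annot.json). OBJ preserves vertex
# indexing exactly; STL stores per-facet vertices, so shared vertices are
# re-merged on read by exact coordinate match.

#' Write a mesh to STL or OBJ
#'
#' The format follows the file extension (`.stl` ASCII or `.obj`).
#' Coordinates are written with 17 significant digits so a write/read round
#' trip reproduces them exactly. The mouth line and provenance go to a JSON
#' sidecar at `<path>.annot.json`.
#'
#' @param mesh A `head_mesh`.
#' @param path Output file path ending in `.stl` or `.obj`.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path) {
  ext <- tolower(tools::file_ext(path))
  v <- mesh$vertices; f <- mesh$triangles
  if (ext == "obj") {
    lines <- c(
      sprintf("v %.17g %.17g %.17g", v[, 1], v[, 2], v[, 3]),
      sprintf("f %d %d %d", f[, 1], f[, 2], f[, 3])
    )
    writeLines(lines, path)
  } else if (ext == "stl") {
    geom <- mesh_face_geometry(mesh)
    tri_txt <- sprintf(
      paste0(
        " facet normal %.17g %.17g %.17g\n  outer loop\n",
        "   vertex %.17g %.17g %.17g\n   vertex %.17g %.17g %.17g\n",
        "   vertex %.17g %.17g %.17g\n  endloop\n endfacet"
      ),
      geom$normals[, 1], geom$normals[, 2], geom$normals[, 3],
      geom$va[, 1], geom$va[, 2], geom$va[, 3],
      geom$vb[, 1], geom$vb[, 2], geom$vb[, 3],
      geom$vc[, 1], geom$vc[, 2], geom$vc[, 3]
    )
    writeLines(c("solid mesh", tri_txt, "endsolid mesh"), path)
  } else {
    stop("unknown mesh extension: ", ext)
  }
  jsonlite::write_json(
    list(
      mouth_line = mesh$mouth_line,
      provenance = mesh$provenance,
      params = mesh$params
    ),
    paste0(path, ".annot.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Read a mesh from STL or OBJ
#'
#' Reads ASCII STL or OBJ (triangles only; polygonal OBJ faces are an
#' error). If a `<path>.annot.json` sidecar exists, the mouth line and
#' provenance are restored. Meshes whose faces are consistently inverted
#' (negative enclosed volume) are reoriented with a warning.
#'
#' @param path Input file path.
#' @return A `head_mesh`.
#' @export
read_mesh <- function(path) {
  ext <- tolower(tools::file_ext(path))
  lines <- readLines(path)
  if (ext == "obj") {
    vl <- lines[startsWith(lines, "v ")]
    fl <- lines[startsWith(lines, "f ")]
    v <- do.call(rbind, lapply(strsplit(trimws(sub("^v", "", vl)), "\\s+"),
                               as.numeric))
    ftok <- strsplit(trimws(sub("^f", "", fl)), "\\s+")
    if (any(base::lengths(ftok) != 3)) {
      stop("OBJ contains non-triangulated faces")
    }
    f <- do.call(rbind, lapply(ftok, function(t) as.integer(sub("/.*", "", t))))
  } else if (ext == "stl") {
    vl <- grep("^\\s*vertex", lines, value = TRUE)
    if (length(vl) == 0 || length(vl) %% 3 != 0) {
      stop("malformed ASCII STL (vertex count not a multiple of 3)")
    }
    coords <- do.call(rbind, lapply(
      strsplit(trimws(sub("^\\s*vertex", "", vl)), "\\s+"), as.numeric
    ))
    key <- paste(
      sprintf("%.17g", coords[, 1]), sprintf("%.17g", coords[, 2]),
      sprintf("%.17g", coords[, 3])
    )
    uk <- !duplicated(key)
    v <- coords[uk, , drop = FALSE]
    f <- matrix(match(key, key[uk]), ncol = 3, byrow = TRUE)
  } else {
    stop("unknown mesh extension: ", ext)
  }
  if (any(is.na(v)) || any(is.na(f))) stop("failed to parse mesh file: ", path)

  mouth_line <- tibble::tibble(vertex = integer(), side = character(),
                               position = integer())
  provenance <- "variant"
  params <- list()
  sidecar <- paste0(path, ".annot.json")
  if (file.exists(sidecar)) {
    ann <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (!is.null(ann$mouth_line) && NROW(ann$mouth_line) > 0) {
      mouth_line <- tibble::as_tibble(ann$mouth_line)
    }
    provenance <- ann$provenance %||% provenance
    params <- ann$params %||% params
  }
  mesh <- new_head_mesh(v, f, mouth_line, provenance, params)
  if (mesh_volume(v, f) < 0) {
    warning("mesh faces point inward; reorienting")
    mesh$triangles <- f[, c(1, 3, 2)]
  }
  if (!mesh_is_watertight(mesh)) {
    warning("mesh is not a closed, consistently oriented surface")
  }
  mesh
}
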