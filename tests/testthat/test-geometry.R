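test_that("simplified head honours its dimensional and topological contract", {
  m <- fixture_head()
  bbox <- apply(m$vertices, 2, function(v) diff(range(v)))
  expect_equal(unname(bbox), c(40, 25, 25), tolerance = 1e-12)
  expect_true(mesh_is_watertight(m))
  expect_gt(lingualsonar:::mesh_volume(m$vertices, m$triangles), 0)

  # deterministic: identical parameters give byte-identical meshes
  m2 <- build_simplified_head(edge_target = 1)
  expect_identical(m$vertices, m2$vertices)
  expect_identical(m$triangles, m2$triangles)
})

test_that("ear bumps are a local edit and removal flags the variant", {
  m_ears <- fixture_head()
  m_bald <- build_simplified_head(edge_target = 1, ears = FALSE)
  expect_identical(dim(m_ears$vertices), dim(m_bald$vertices))
  same <- rowSums(abs(m_ears$vertices - m_bald$vertices)) == 0
  # most vertices identical; the differing ones form the two ear patches
  expect_gt(mean(same), 0.75)
  expect_lt(mean(same), 1)
  expect_identical(m_bald$provenance, "variant")
  expect_true(mesh_is_watertight(m_bald))
  # bounding box unchanged: the bumps stay inside the ellipsoid extremes
  expect_equal(
    apply(m_ears$vertices, 2, range),
    apply(m_bald$vertices, 2, range),
    tolerance = 1e-12
  )
})

test_that("mouth line is populated on both sides with adequate density", {
  # at the default 0.5 mm seam resolution each side of the ~13 mm lip seam
  # carries well over the minimal 8 nodes
  m <- build_simplified_head()  # default edge_target = 0.5
  counts <- table(m$mouth_line$side)
  expect_gte(min(counts), 8)
  expect_setequal(names(counts), c("left", "right"))
  expect_true(all(m$mouth_line$vertex >= 1 &
                    m$mouth_line$vertex <= nrow(m$vertices)))
  # left/right tags partition by the sagittal plane
  y <- m$vertices[m$mouth_line$vertex, 2]
  expect_true(all(y[m$mouth_line$side == "left"] > 0))
  expect_true(all(y[m$mouth_line$side == "right"] < 0))
})

test_that("element placement respects side, mirroring and spacing contracts", {
  m <- fixture_head()
  left4 <- place_elements(m, "left", "discrete", n = 4)
  expect_equal(left4$n, 4)
  expect_true(all(left4$positions[, 2] > 0))

  both4 <- place_elements(m, "both", "discrete", n = 4)
  expect_equal(both4$n, 8)
  mirrored <- both4$positions[1:4, ] %*% diag(c(1, -1, 1))
  expect_equal(unname(both4$positions[5:8, ]), unname(mirrored))

  cont <- place_elements(m, "left", "continuous", spacing = 1)
  gaps <- sqrt(rowSums(diff(cont$positions)^2))
  expect_true(all(gaps >= 0.5 & gaps <= 1.5))

  expect_error(place_elements(m, "left", "discrete", n = 1000),
               "mouth-line nodes")
  # normals are unit outward vectors
  expect_equal(unname(rowSums(left4$normals^2)), rep(1, 4), tolerance = 1e-9)
})

test_that("element ranges are Euclidean distances with the expected symmetries", {
  arr <- lingualsonar:::new_array_spec(rbind(c(3, 4, 0), c(3, -4, 0)), "both", "discrete")
  tng <- tongue_position(c(0, 0, 0))
  r <- element_ranges(tng, arr)
  expect_equal(r, c(5, 5))  # 3-4-5 triangles, symmetric pair

  expect_error(
    element_ranges(tongue_position(c(3, 4, 0)), arr),
    "coincides"
  )

  # invariance under a rigid transform applied jointly
  m <- fixture_head()
  arr2 <- place_elements(m, "left", "discrete", n = 5)
  tng2 <- tongue_position(c(10, 2, -3))
  r0 <- element_ranges(tng2, arr2)
  R <- lingualsonar:::rotation_about(c(1, 2, 3) / sqrt(14), 0.7)
  tvec <- c(5, -2, 11)
  arr2$positions <- arr2$positions %*% t(R) +
    matrix(tvec, nrow(arr2$positions), 3, byrow = TRUE)
  tng2r <- tongue_position(drop(R %*% c(10, 2, -3)) + tvec)
  expect_equal(element_ranges(tng2r, arr2), r0, tolerance = 1e-9)

  # bilateral symmetry: mirroring array and tongue leaves ranges unchanged
  arr3 <- place_elements(m, "left", "discrete", n = 5)
  tngL <- tongue_position(c(10, 2, -3))
  tngR <- tongue_position(c(10, -2, -3))
  expect_equal(
    element_ranges(tngR, mirror_array(arr3)),
    element_ranges(tngL, arr3),
    tolerance = 1e-12
  )
})

test_that("tongue positions are validated against the mouth cavity", {
  m <- fixture_head()
  expect_s3_class(tongue_position(c(10, 2, -3), "left", mesh = m),
                  "tongue_position")
  expect_error(tongue_position(c(100, 0, 0), mesh = m), "bounding box")
  expect_error(tongue_position(c(19.9, 0, 0), mesh = m), "forward")
})

test_that("mesh files round-trip through OBJ and STL", {
  m <- build_simplified_head(edge_target = 3)
  tmp <- withr::local_tempdir()

  obj <- file.path(tmp, "head.obj")
  write_mesh(m, obj)
  m_obj <- read_mesh(obj)
  expect_equal(m_obj$vertices, unname(m$vertices))
  expect_equal(m_obj$triangles, m$triangles)
  expect_equal(m_obj$mouth_line$vertex, m$mouth_line$vertex)
  expect_identical(m_obj$provenance, m$provenance)

  stl <- file.path(tmp, "head.stl")
  write_mesh(m, stl)
  m_stl <- read_mesh(stl)
  # STL stores per-facet vertices; compare the coordinate sets and measures
  key <- function(v) sort(apply(round(v, 9), 1, paste, collapse = "/"))
  expect_identical(key(m_stl$vertices), key(m$vertices))
  expect_equal(lingualsonar:::mesh_volume(m_stl$vertices, m_stl$triangles),
               lingualsonar:::mesh_volume(m$vertices, m$triangles), tolerance = 1e-9)

  expect_error(write_mesh(m, file.path(tmp, "head.ply")), "extension")
  quad <- file.path(tmp, "quad.obj")
  writeLines(c("v 0 0 0", "v 1 0 0", "v 1 1 0", "v 0 1 0", "f 1 2 3 4"),
             quad)
  expect_error(read_mesh(quad), "non-triangulated")
})

test_that("a mesh with inverted faces is reoriented on read", {
  m <- build_simplified_head(edge_target = 3)
  tmp <- withr::local_tempdir()
  flipped <- m
  flipped$triangles <- m$triangles[, c(1, 3, 2)]
  p <- file.path(tmp, "flipped.obj")
  write_mesh(flipped, p)
  expect_warning(m_back <- read_mesh(p), "reorient")
  expect_gt(lingualsonar:::mesh_volume(m_back$vertices, m_back$triangles), 0)
})
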