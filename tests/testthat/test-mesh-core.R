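test_that("mesh constructor enforces its invariants", {
  expect_error(triangle_mesh(rbind(c(0, 0, 0), c(1, 0, 0)), matrix(1:3, 1)),
               "at least 3 vertices")
  expect_error(triangle_mesh(diag(3), matrix(c(1, 2, 4), 1)), "out of range")
  expect_error(triangle_mesh(diag(3), matrix(c(1, 2, 2), 1)), "repeated")
  m <- triangle_mesh(diag(3), matrix(c(1, 2, 3), 1))
  expect_s3_class(m, "triangle_mesh")
  expect_identical(dim(m$faces), c(1L, 3L))
})

test_that("OFF round-trip preserves a tetrahedron and the unit cube", {
  tet <- tet_mesh()
  p <- withr::local_tempfile(fileext = ".off")
  write_mesh(tet, p)
  back <- read_mesh(p)
  expect_equal(back$vertices, tet$vertices, tolerance = 1e-6)
  expect_identical(back$faces, tet$faces)
  expect_identical(nrow(back$vertices), 4L)
  expect_identical(nrow(back$faces), 4L)

  cube <- cube_mesh()
  p2 <- withr::local_tempfile(fileext = ".off")
  write_mesh(cube, p2)
  back2 <- read_mesh(p2)
  expect_identical(nrow(back2$vertices), 8L)
  expect_identical(nrow(back2$faces), 12L)
})

test_that("all writable formats round-trip geometry", {
  m <- icosphere(1)
  for (fmt in c("off", "obj", "ply")) {
    p <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_mesh(m, p)
    back <- read_mesh(p)
    expect_equal(back$vertices, m$vertices, tolerance = 1e-6)
    expect_identical(back$faces, m$faces)
  }
  # binary little-endian PLY is exact
  p <- withr::local_tempfile(fileext = ".ply")
  write_mesh(m, p, binary = TRUE)
  back <- read_mesh(p)
  expect_identical(back$vertices, m$vertices)
  expect_identical(back$faces, m$faces)
  # STL stores facets independently; topology and geometry survive even
  # though vertex order need not
  p <- withr::local_tempfile(fileext = ".stl")
  write_mesh(m, p)
  back <- read_mesh(p)
  expect_identical(nrow(back$faces), nrow(m$faces))
  expect_equal(mesh_surface_area(back), mesh_surface_area(m),
               tolerance = 1e-9)
  expect_equal(mesh_volume(back), mesh_volume(m), tolerance = 1e-9)
})

test_that("the same mesh written as PLY and OBJ re-reads identically", {
  m <- icosphere(1)
  p1 <- withr::local_tempfile(fileext = ".ply")
  p2 <- withr::local_tempfile(fileext = ".obj")
  write_mesh(m, p1)
  write_mesh(m, p2)
  a <- read_mesh(p1)
  b <- read_mesh(p2)
  expect_equal(a$vertices, b$vertices, tolerance = 1e-12)
  expect_identical(a$faces, b$faces)
})

test_that("polygonal faces are fan-triangulated on read", {
  p <- withr::local_tempfile(fileext = ".obj")
  writeLines(c("v 0 0 0", "v 1 0 0", "v 1 1 0", "v 0 1 0", "f 1 2 3 4"), p)
  m <- read_mesh(p)
  expect_identical(nrow(m$faces), 2L)
  expect_identical(m$faces, rbind(c(1L, 2L, 3L), c(1L, 3L, 4L)))

  p2 <- withr::local_tempfile(fileext = ".off")
  writeLines(c("OFF", "4 1 0", "0 0 0", "1 0 0", "1 1 0", "0 1 0",
               "4 0 1 2 3"), p2)
  m2 <- read_mesh(p2)
  expect_identical(nrow(m2$faces), 2L)
})

test_that("unreadable and degenerate files raise I/O errors", {
  expect_error(read_mesh("no/such/file.off"), "no such file")
  p <- withr::local_tempfile(fileext = ".obj")
  writeLines(c("v 0 0 0", "v 1 0 0", "v 0 1 0"), p)  # vertices, no faces
  expect_error(read_mesh(p), "empty mesh|face")
  expect_error(write_mesh(structure(list(vertices = matrix(0, 0, 3),
                                         faces = matrix(0L, 0, 3)),
                                    class = "triangle_mesh"),
                          tempfile(fileext = ".off")),
               "at least 3 vertices")
})

test_that("ROI extraction is the masked image", {
  img <- matrix(c(10, 30, 20, 40), 2, 2)
  expect_identical(extract_roi(img, matrix(1, 2, 2)), img)
  expect_identical(extract_roi(img, matrix(0, 2, 2)), matrix(0, 2, 2))
  expect_identical(extract_roi(img, matrix(c(1, 0, 0, 1), 2, 2)),
                   matrix(c(10, 0, 0, 40), 2, 2))
  # 0/255 mask encodings normalize the same way
  expect_identical(extract_roi(img, matrix(c(255, 0, 0, 255), 2, 2)),
                   matrix(c(10, 0, 0, 40), 2, 2))
  expect_error(extract_roi(img, matrix(0, 3, 2)), "dimensions differ")
})

test_that("PNG round-trip preserves an ROI image", {
  img <- matrix(runif(30 * 20), 30, 20)
  p <- withr::local_tempfile(fileext = ".png")
  write_gray_png(img, p)
  back <- read_gray_png(p)
  expect_equal(back, img, tolerance = 1 / 255)
})

test_that("hole percentage matches hand counts", {
  r <- hole_report(tet_mesh())
  expect_identical(r$total_edges, 6L)
  expect_identical(r$boundary_edges, 0L)
  expect_equal(r$hole_percentage, 0)
  expect_true(r$passed)

  r <- hole_report(single_triangle())
  expect_equal(r$hole_percentage, 100)
  expect_false(r$passed)

  r <- hole_report(square_mesh())
  expect_identical(r$total_edges, 5L)
  expect_identical(r$boundary_edges, 4L)
  expect_equal(r$hole_percentage, 80)
  expect_false(r$passed)
})

test_that("hole percentage is invariant under vertex permutation and rigid motion", {
  set.seed(1)
  m <- punch_holes(icosphere(2), 12L, seed = 4)
  base <- hole_report(m)$hole_percentage
  perm <- sample(nrow(m$vertices))
  inv <- order(perm)
  m2 <- triangle_mesh(m$vertices[perm, ],
                      matrix(inv[m$faces], ncol = 3))
  expect_equal(hole_report(m2)$hole_percentage, base)
  m3 <- apply_rigid(m, random_rigid_transform())
  expect_equal(hole_report(m3)$hole_percentage, base)
})

test_that("qc_filter implements 'more than threshold' exclusion", {
  pct <- function(m) hole_report(m)$hole_percentage
  meshes <- list(watertight = tet_mesh(), open = square_mesh())
  res <- suppressMessages(qc_filter(meshes, threshold = 10))
  expect_named(res$retained, "watertight")
  expect_named(res$excluded, "open")
  expect_identical(nrow(res$reports), 2L)
  expect_identical(res$reports$passed, c(TRUE, FALSE))

  # boundary semantics: exactly at threshold is retained, above is excluded
  m <- punch_holes(icosphere(2), 1L, seed = 1)
  at <- pct(m)
  res2 <- qc_filter(list(m), threshold = at)
  expect_length(res2$retained, 1L)
  res3 <- suppressMessages(qc_filter(list(m), threshold = at - 1e-9))
  expect_length(res3$excluded, 1L)

  # extreme thresholds
  batch <- list(tet_mesh(), square_mesh(), single_triangle())
  expect_length(qc_filter(batch, 100)$retained, 3L)
  expect_length(suppressMessages(qc_filter(batch, 0))$retained, 1L)
  # empty input
  empty <- qc_filter(list())
  expect_length(empty$retained, 0L)
  expect_identical(nrow(empty$reports), 0L)
})

test_that("excluded meshes are logged with their hole percentage", {
  expect_message(qc_filter(list(bad = single_triangle())), "100.00% holes")
})

test_that("orientation repair gives outward normals and positive volume", {
  cube <- cube_mesh()
  flipped <- cube
  flipped$faces[c(2, 5, 9), ] <- flipped$faces[c(2, 5, 9), c(1, 3, 2)]
  fixed <- orient_mesh(flipped)
  expect_equal(meshgat:::signed_volume(fixed), 1)
})
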