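test_that("covariance eigenvalues recover degenerate geometries", {
  expect_equal(unname(covariance_eigenvalues(cbind(0:3, 0, 0))),
               c(1, 0, 0))
  square <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0))
  ev <- covariance_eigenvalues(square)
  expect_equal(unname(ev[3]), 0)
  expect_equal(sum(ev), 1, tolerance = 1e-9)
  expect_true(all(diff(ev) <= 1e-12))
  expect_error(covariance_eigenvalues(matrix(1, 5, 3)), "degenerate")
  expect_error(covariance_eigenvalues(diag(3)), "at least 4")
})

test_that("uniform sphere samples are nearly isotropic", {
  set.seed(7)
  u <- matrix(rnorm(3 * 20000), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  ev <- covariance_eigenvalues(u)
  expect_true(all(abs(ev - 1 / 3) < 0.02))
  # global anisotropy of an isotropic cloud is near zero
  expect_lt((ev[1] - ev[3]) / ev[1], 0.05)
})

test_that("closed-form volume, area, sphericity on reference solids", {
  cube <- cube_mesh()
  expect_equal(mesh_volume(cube), 1, tolerance = 1e-12)
  expect_equal(mesh_surface_area(cube), 6, tolerance = 1e-12)
  expect_equal(mesh_sphericity(cube), pi^(1 / 3) * 6^(2 / 3) / 6,
               tolerance = 1e-12)
  expect_equal(mesh_volume(tet_mesh()), 1 / 6, tolerance = 1e-12)
  tri_area <- mesh_surface_area(single_triangle())
  expect_equal(tri_area, 0.5, tolerance = 1e-12)
})

test_that("volume is translation-invariant for closed meshes and flagged otherwise", {
  cube <- cube_mesh()
  shifted <- cube
  shifted$vertices <- sweep(shifted$vertices, 2, c(10, -4, 3), `+`)
  expect_equal(mesh_volume(shifted), 1, tolerance = 1e-9)
  expect_warning(mesh_volume(square_mesh()), "not watertight")
  expect_error(mesh_sphericity(square_mesh()), "qc_filter")
})

test_that("icosphere refinement approaches the sphere from below", {
  vols <- vapply(0:3, function(s) mesh_volume(icosphere(s)), 1.0)
  areas <- vapply(0:3, function(s) mesh_surface_area(icosphere(s)), 1.0)
  sph <- vapply(0:3, function(s) mesh_sphericity(icosphere(s)), 1.0)
  expect_true(all(diff(vols) > 0))
  expect_true(all(vols < 4 * pi / 3))
  expect_true(all(diff(areas) > 0))
  expect_true(all(areas < 4 * pi))
  expect_true(all(diff(sph) > 0))
  expect_true(all(sph <= 1))
  expect_gt(sph[4], 0.999)
})

test_that("bounding-box distances on the unit cube", {
  bb <- bounding_box_distances(cube_mesh())
  expect_equal(unname(bb["bb_min"]), 0)
  expect_equal(unname(bb["bb_max"]), sqrt(3), tolerance = 1e-12)
  # any mesh: bb_max bounded by the box diagonal
  m <- make_benign_mesh(seed = 1)
  bb2 <- bounding_box_distances(m)
  diag_len <- sqrt(sum((apply(m$vertices, 2, max) -
                        apply(m$vertices, 2, min))^2))
  expect_lte(bb2["bb_max"], diag_len + 1e-12)
  # face variant: extreme vertices touch the box
  bbf <- bounding_box_distances(cube_mesh(), mode = "face")
  expect_equal(unname(bbf["bb_min"]), 0)
})

test_that("farthest distance equals the O(n^2) brute force", {
  expect_equal(farthest_distance(cube_mesh()), sqrt(3), tolerance = 1e-12)
  collinear <- triangle_mesh(cbind(c(0, 1, 2, 3), 0, 0),
                             rbind(c(1, 2, 3), c(2, 3, 4)))
  expect_equal(farthest_distance(collinear), 3)
  set.seed(5)
  v <- matrix(rnorm(600), ncol = 3)
  brute <- 0
  for (i in 1:199) for (j in (i + 1):200) {
    brute <- max(brute, sqrt(sum((v[i, ] - v[j, ])^2)))
  }
  expect_equal(farthest_distance(v), brute, tolerance = 1e-12)
})

test_that("centroid distance matches its definition and scales linearly", {
  ico <- icosphere(3)
  expect_equal(centroid_distance(ico), 1, tolerance = 5e-3)
  shifted <- ico
  shifted$vertices <- sweep(shifted$vertices, 2, c(3, 2, 1), `+`)
  expect_equal(centroid_distance(shifted), centroid_distance(ico),
               tolerance = 1e-9)
  scaled <- ico
  scaled$vertices <- 2.5 * scaled$vertices
  expect_equal(centroid_distance(scaled), 2.5 * centroid_distance(ico),
               tolerance = 1e-9)
  # brute-force recomputation
  m <- make_benign_mesh(shape_params(subdivisions = 1L), seed = 2)
  a <- meshgat:::face_areas(m)
  fc <- (m$vertices[m$faces[, 1], ] + m$vertices[m$faces[, 2], ] +
         m$vertices[m$faces[, 3], ]) / 3
  ctr <- colSums(fc * a) / sum(a)
  brute <- mean(sqrt(rowSums(sweep(m$vertices, 2, ctr)^2)))
  expect_equal(centroid_distance(m), brute, tolerance = 1e-12)
})

test_that("local eigen features respect their bounds", {
  m <- make_malignant_mesh(seed = 3)
  tri <- meshgat:::local_eigen_triples(m$vertices, 30)
  C <- mesh_curvature(m, triples = tri)
  A <- mesh_anisotropy(m, triples = tri)
  E <- mesh_eigen_entropy(m, triples = tri)
  expect_gte(C, 0); expect_lte(C, 1 / 3 + 1e-12)
  expect_gte(A, 0); expect_lte(A, 1)
  expect_gte(E, 0); expect_lte(E, log(3) + 1e-9)
  # flat plane: lambda3 = 0 at interior sites
  expect_lt(mesh_curvature(plane_mesh()), 1e-9)
  # curved surface exceeds flat patch at equal k
  expect_gt(mesh_curvature(icosphere(2)), mesh_curvature(plane_mesh(13)))
})

test_that("eigen entropy closed forms at degenerate sites", {
  plogp <- function(l) -sum(ifelse(l > 0, l * log(l), 0))
  expect_equal(plogp(c(1, 0, 0)), 0)
  expect_equal(plogp(rep(1 / 3, 3)), log(3))
})

test_that("the ten features obey rigid-motion and scaling laws", {
  m <- make_malignant_mesh(seed = 9)
  base <- extract_features(m)
  set.seed(11)
  for (rep in 1:3) {
    tf <- random_rigid_transform()
    rigid <- extract_features(apply_rigid(m, tf))
    for (f in c("sphericity", "anisotropy", "eigen_entropy", "curvature",
                "volume", "surface_area", "farthest_distance",
                "centroid_distance")) {
      expect_equal(rigid[[f]], base[[f]], tolerance = 1e-6)
    }
    s <- runif(1, 0.5, 3)
    scaled <- extract_features(apply_rigid(m, tf, scale = s))
    expect_equal(scaled[["volume"]], s^3 * base[["volume"]],
                 tolerance = 1e-6)
    expect_equal(scaled[["surface_area"]], s^2 * base[["surface_area"]],
                 tolerance = 1e-6)
    expect_equal(scaled[["farthest_distance"]],
                 s * base[["farthest_distance"]], tolerance = 1e-6)
    expect_equal(scaled[["sphericity"]], base[["sphericity"]],
                 tolerance = 1e-6)
    expect_equal(scaled[["curvature"]], base[["curvature"]],
                 tolerance = 1e-6)
  }
})

test_that("extract_features is deterministic with ten finite fields", {
  m <- make_benign_mesh(seed = 21)
  f1 <- extract_features(m)
  f2 <- extract_features(m)
  expect_identical(f1, f2)
  expect_length(f1, 10L)
  expect_true(all(is.finite(f1)))
  expect_named(f1, meshgat:::feature_names)
})

test_that("feature tables have the 12-column shape and survive CSV", {
  ds <- make_dataset(5, 3, seed = 2)
  tab <- build_feature_table(ds$meshes, ds$labels)
  expect_identical(dim(tab), c(8L, 12L))
  expect_identical(tab$unique_id, 1:8)
  expect_identical(names(tab),
                   c("unique_id", meshgat:::feature_names, "target"))
  p <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(tab, p)
  back <- read_feature_table(p)
  expect_identical(back$unique_id, tab$unique_id)
  expect_identical(back$target, tab$target)
  for (f in meshgat:::feature_names) {
    expect_equal(back[[f]], tab[[f]], tolerance = 1e-12)
  }
  expect_error(build_feature_table(ds$meshes, c("benign", "odd")),
               "label")
})
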