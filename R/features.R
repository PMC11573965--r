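#' Normalized covariance eigenvalues of a point set
#'
#' Eigenvalues of the coordinate covariance of a set of 3D points, sorted
#' descending, clamped at zero and normalized to sum to one. These
#' eigenvalue triples (lambda1 >= lambda2 >= lambda3 >= 0) parameterize
#' local shape: (1,0,0) is linear, (1/2,1/2,0) planar, (1/3,1/3,1/3)
#' isotropic. In `"local"` mode the covariance is computed per point over its
#' `k` nearest neighbors and the per-point triples are averaged.
#'
#' @param points n x 3 numeric matrix, n >= 4.
#' @param mode `"global"` (one covariance over all points) or `"local"`
#'   (per-point k-nearest-neighbor covariances, averaged).
#' @param k Neighborhood size for local mode (>= 4, capped at n).
#' @return Named numeric vector `c(lambda1, lambda2, lambda3)` summing to 1.
#' @examples
#' covariance_eigenvalues(cbind(0:3, 0, 0))  # collinear: (1, 0, 0)
#' @export
covariance_eigenvalues <- function(points, mode = c("global", "local"),
                                   k = 30L) {
  mode <- match.arg(mode)
  points <- as.matrix(points)
  if (nrow(points) < 4L) stop("need at least 4 points")
  if (mode == "global") {
    normalize_eigen(eigen(stats::cov(points), symmetric = TRUE,
                          only.values = TRUE)$values)
  } else {
    tri <- local_eigen_triples(points, k)
    out <- colMeans(tri, na.rm = TRUE)
    names(out) <- c("lambda1", "lambda2", "lambda3")
    out
  }
}

normalize_eigen <- function(ev) {
  ev <- sort(pmax(ev, 0), decreasing = TRUE)
  s <- sum(ev)
  if (s <= 0) stop("degenerate point set: zero covariance")
  out <- ev / s
  names(out) <- c("lambda1", "lambda2", "lambda3")
  out
}

# Per-point normalized eigenvalue triples over k-NN neighborhoods
# (neighbors include the point itself; ties broken by vertex index).
# Rows with degenerate (zero) covariance are NA.
local_eigen_triples <- function(points, k = 30L) {
  n <- nrow(points)
  k <- min(as.integer(k), n)
  if (k < 4L) stop("local eigen analysis needs k >= 4 (and >= 4 points)")
  d2 <- as.matrix(stats::dist(points))^2
  out <- matrix(NA_real_, n, 3L)
  for (i in seq_len(n)) {
    nb <- order(d2[i, ])[seq_len(k)]   # order() breaks ties by index
    p <- points[nb, , drop = FALSE]
    cv <- stats::cov(p)
    ev <- sort(pmax(eigen(cv, symmetric = TRUE, only.values = TRUE)$values, 0),
               decreasing = TRUE)
    s <- sum(ev)
    if (s > 0) out[i, ] <- ev / s
  }
  if (all(is.na(out[, 1L]))) stop("degenerate point set: zero covariance")
  colnames(out) <- c("lambda1", "lambda2", "lambda3")
  out
}

#' Structural mesh features from local covariance eigenvalues
#'
#' Per-vertex normalized eigenvalue triples over k-nearest-neighbor
#' neighborhoods are summarized into three scalars:
#' curvature `C = mean(lambda3 / (lambda1 + lambda2 + lambda3))`, bounded in
#' \[0, 1/3\]; anisotropy `A = mean((lambda1 - lambda3) / lambda1)`, bounded
#' in \[0, 1\]; and eigen entropy `E = mean(-sum(lambda_i log lambda_i))`,
#' the Shannon entropy of the eigenvalue distribution, bounded in
#' \[0, log 3\]. Vertices with a degenerate neighborhood (lambda1 = 0) are
#' skipped with a warning.
#'
#' @param mesh A [triangle_mesh()].
#' @param k Neighborhood size (default 30, capped at the vertex count).
#' @param triples Optional precomputed [local_eigen_triples] matrix, so the
#'   three features can share one eigen-analysis pass.
#' @return A single numeric value.
#' @export
mesh_curvature <- function(mesh, k = 30L, triples = NULL) {
  tri <- triples %||% local_eigen_triples(mesh$vertices, k)
  mean(tri[, 3L] / rowSums(tri), na.rm = TRUE)
}

#' @rdname mesh_curvature
#' @export
mesh_anisotropy <- function(mesh, k = 30L, triples = NULL) {
  tri <- triples %||% local_eigen_triples(mesh$vertices, k)
  ok <- !is.na(tri[, 1L]) & tri[, 1L] > 0
  if (!any(ok)) stop("all neighborhoods degenerate: anisotropy undefined")
  if (!all(ok)) warning(sum(!ok), " degenerate neighborhood(s) skipped")
  mean((tri[ok, 1L] - tri[ok, 3L]) / tri[ok, 1L])
}

#' @rdname mesh_curvature
#' @export
mesh_eigen_entropy <- function(mesh, k = 30L, triples = NULL) {
  tri <- triples %||% local_eigen_triples(mesh$vertices, k)
  plogp <- function(x) ifelse(x > 0, x * log(x), 0)
  mean(-rowSums(plogp(tri)), na.rm = TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Enclosed volume of a triangle mesh
#'
#' Absolute value of the signed-tetrahedra sum
#' `sum((1/6) (v1 x v2) . v3)` over faces. Exact and
#' translation-invariant for watertight meshes; for meshes with boundary the
#' value is approximate and flagged with a warning.
#'
#' @param mesh A [triangle_mesh()] (consistent orientation is applied).
#' @param check_watertight Warn when the mesh has boundary edges.
#' @return Nonnegative volume in mesh units cubed.
#' @export
mesh_volume <- function(mesh, check_watertight = TRUE) {
  if (check_watertight && hole_report(mesh)$boundary_edges > 0L) {
    warning("mesh is not watertight: volume is approximate")
  }
  abs(signed_volume(orient_mesh(mesh)))
}

#' Surface area of a triangle mesh
#'
#' `sum(0.5 * ||(v2 - v1) x (v3 - v1)||)` over faces.
#'
#' @param mesh A [triangle_mesh()].
#' @return Nonnegative area in mesh units squared.
#' @export
mesh_surface_area <- function(mesh) {
  sum(face_areas(mesh))
}

#' Sphericity of a watertight mesh
#'
#' The isoperimetric ratio `S = pi^(1/3) (6 V)^(2/3) / Sa`, equal to 1 for a
#' perfect sphere and strictly below 1 for any other closed surface. Round,
#' smooth lesions score high; spiculated, irregular lesions score low.
#'
#' @param mesh A watertight [triangle_mesh()].
#' @param check_watertight Error on meshes with boundary edges (default);
#'   such meshes should have been removed by [qc_filter()].
#' @return Sphericity in (0, 1\].
#' @export
mesh_sphericity <- function(mesh, check_watertight = TRUE) {
  if (check_watertight && hole_report(mesh)$boundary_edges > 0L) {
    stop("sphericity requires a watertight mesh; run qc_filter() first")
  }
  v <- mesh_volume(mesh, check_watertight = FALSE)
  sa <- mesh_surface_area(mesh)
  if (v <= 0 || sa <= 0) stop("degenerate mesh: zero volume or area")
  pi^(1 / 3) * (6 * v)^(2 / 3) / sa
}

#' Distances between mesh vertices and their bounding box
#'
#' With `mode = "corner"` (default) the Euclidean distances between every
#' vertex and each of the eight axis-aligned bounding-box corners are
#' computed; `bb_min` is the smallest and `bb_max` the largest such
#' vertex-corner distance. With `mode = "face"` the per-vertex distance to
#' the nearest box face is used instead (its minimum is identically zero on
#' the extreme vertices).
#'
#' @param mesh A [triangle_mesh()].
#' @param mode `"corner"` or `"face"`.
#' @return Named vector `c(bb_min, bb_max)`.
#' @export
bounding_box_distances <- function(mesh, mode = c("corner", "face")) {
  mode <- match.arg(mode)
  v <- mesh$vertices
  lo <- apply(v, 2L, min)
  hi <- apply(v, 2L, max)
  if (mode == "corner") {
    corners <- as.matrix(expand.grid(c(lo[1L], hi[1L]), c(lo[2L], hi[2L]),
                                     c(lo[3L], hi[3L])))
    dmin <- Inf
    dmax <- -Inf
    for (i in seq_len(8L)) {
      d <- sqrt(rowSums(sweep(v, 2L, corners[i, ], `-`)^2))
      dmin <- min(dmin, min(d))
      dmax <- max(dmax, max(d))
    }
    c(bb_min = dmin, bb_max = dmax)
  } else {
    dface <- pmin(v[, 1L] - lo[1L], hi[1L] - v[, 1L]) |>
      pmin(v[, 2L] - lo[2L], hi[2L] - v[, 2L]) |>
      pmin(v[, 3L] - lo[3L], hi[3L] - v[, 3L])
    c(bb_min = min(dface), bb_max = max(dface))
  }
}

#' Mesh diameter: the farthest vertex pair
#'
#' Maximum pairwise Euclidean distance between vertices, exact with respect
#' to the brute-force definition.
#'
#' @param mesh A [triangle_mesh()] (or any object with >= 2 vertex rows).
#' @return The largest vertex-to-vertex distance.
#' @export
farthest_distance <- function(mesh) {
  v <- if (inherits(mesh, "triangle_mesh")) mesh$vertices else as.matrix(mesh)
  if (nrow(v) < 2L) stop("need at least 2 vertices")
  max(stats::dist(v))
}

#' Mean distance from the face-centroid to the vertices
#'
#' The mesh centroid is the area-weighted mean of the face centroids (the
#' central location of all mesh faces); the feature is the mean Euclidean
#' distance from that centroid to all vertices.
#'
#' @param mesh A [triangle_mesh()].
#' @return Nonnegative distance in mesh units.
#' @export
centroid_distance <- function(mesh) {
  a <- face_areas(mesh)
  if (sum(a) <= 0) stop("total face area is zero")
  v <- mesh$vertices
  f <- mesh$faces
  fc <- (v[f[, 1L], , drop = FALSE] + v[f[, 2L], , drop = FALSE] +
         v[f[, 3L], , drop = FALSE]) / 3
  centroid <- colSums(fc * a) / sum(a)
  mean(sqrt(rowSums(sweep(v, 2L, centroid, `-`)^2)))
}

#' Feature extraction configuration
#'
#' @param k Neighborhood size for the local eigen features. Default 30.
#' @param bb_mode Bounding-box distance variant, `"corner"` or `"face"`.
#' @param normalize Rescale the mesh to unit bounding-box diagonal before
#'   computing features (affects only the size-dependent features).
#' @param check_watertight Enforce watertightness for sphericity/volume.
#' @return A list of class `feature_config`.
#' @export
feature_config <- function(k = 30L, bb_mode = c("corner", "face"),
                           normalize = FALSE, check_watertight = TRUE) {
  structure(list(k = as.integer(k), bb_mode = match.arg(bb_mode),
                 normalize = normalize, check_watertight = check_watertight),
            class = "feature_config")
}

feature_names <- c("sphericity", "anisotropy", "eigen_entropy", "curvature",
                   "farthest_distance", "centroid_distance",
                   "bb_min_distance", "bb_max_distance",
                   "volume", "surface_area")

#' Extract the ten mesh features
#'
#' Computes the full feature vector of a tumor mesh: sphericity, anisotropy,
#' eigen entropy, curvature (sharing a single per-vertex eigen-analysis
#' pass), farthest distance, centroid distance, bounding-box min/max
#' distances, volume and surface area. Deterministic for a fixed
#' configuration.
#'
#' @param mesh A [triangle_mesh()] that passed quality control.
#' @param config A [feature_config()].
#' @return Named numeric vector of length 10.
#' @examples
#' extract_features(icosphere(2))
#' @export
extract_features <- function(mesh, config = feature_config()) {
  validate_mesh(mesh)
  if (config$normalize) {
    diag_len <- sqrt(sum((apply(mesh$vertices, 2L, max) -
                          apply(mesh$vertices, 2L, min))^2))
    mesh$vertices <- mesh$vertices / diag_len
  }
  triples <- local_eigen_triples(mesh$vertices, config$k)
  bb <- bounding_box_distances(mesh, config$bb_mode)
  out <- c(
    sphericity = mesh_sphericity(mesh,
                                 check_watertight = config$check_watertight),
    anisotropy = mesh_anisotropy(mesh, triples = triples),
    eigen_entropy = mesh_eigen_entropy(mesh, triples = triples),
    curvature = mesh_curvature(mesh, triples = triples),
    farthest_distance = farthest_distance(mesh),
    centroid_distance = centroid_distance(mesh),
    bb_min_distance = unname(bb["bb_min"]),
    bb_max_distance = unname(bb["bb_max"]),
    volume = mesh_volume(mesh, check_watertight = FALSE),
    surface_area = mesh_surface_area(mesh)
  )
  stopifnot(all(is.finite(out)))
  out
}

#' Assemble the per-mesh feature table
#'
#' One row per mesh, in input order: a 1-based unique ID, the ten feature
#' columns, and the class label. This is the table from which the
#' sample-similarity graph and the classifier operate.
#'
#' @param meshes Named or unnamed list of [triangle_mesh()] objects.
#' @param labels Character vector (or factor) of `"benign"`/`"malignant"`
#'   labels, one per mesh, or a data.frame with columns `mesh_id` and
#'   `target` as produced by [make_dataset()].
#' @param config A [feature_config()].
#' @return A data.frame with columns `unique_id`, the ten features, `target`.
#' @export
build_feature_table <- function(meshes, labels, config = feature_config()) {
  if (is.data.frame(labels)) {
    ids <- names(meshes) %||% as.character(seq_along(meshes))
    labels <- labels$target[match(ids, labels$mesh_id)]
  }
  labels <- as.character(labels)
  if (length(labels) != length(meshes) || anyNA(labels)) {
    stop("every mesh needs a benign/malignant label")
  }
  if (!all(labels %in% c("benign", "malignant"))) {
    stop("labels must be 'benign' or 'malignant'")
  }
  feats <- t(vapply(meshes, extract_features, numeric(10L), config = config))
  out <- data.frame(unique_id = seq_along(meshes), feats, target = labels,
                    row.names = NULL)
  names(out) <- c("unique_id", feature_names, "target")
  out
}

#' Read / write a feature table as CSV
#'
#' @param table A feature table from [build_feature_table()].
#' @param path CSV path.
#' @return `read_feature_table()`: the feature table data.frame.
#' @export
write_feature_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  expect <- c("unique_id", feature_names, "target")
  if (!identical(names(out), expect)) {
    stop("not a feature table: expected columns ",
         paste(expect, collapse = ", "))
  }
  out
}
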