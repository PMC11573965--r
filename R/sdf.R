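#' @name signed_distance
#' @title Signed distance from a point to a triangle mesh surface
NULL

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

# Unit face normals, n_faces x 3 (zero rows for degenerate triangles).
face_normals <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1L], , drop = FALSE]
  ab <- v[f[, 2L], , drop = FALSE] - a
  ac <- v[f[, 3L], , drop = FALSE] - a
  n <- cbind(ab[, 2L] * ac[, 3L] - ab[, 3L] * ac[, 2L],
             ab[, 3L] * ac[, 1L] - ab[, 1L] * ac[, 3L],
             ab[, 1L] * ac[, 2L] - ab[, 2L] * ac[, 1L])
  len <- sqrt(rowSums(n^2))
  n / ifelse(len > 0, len, 1)
}

face_areas <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1L], , drop = FALSE]
  ab <- v[f[, 2L], , drop = FALSE] - a
  ac <- v[f[, 3L], , drop = FALSE] - a
  n <- cbind(ab[, 2L] * ac[, 3L] - ab[, 3L] * ac[, 2L],
             ab[, 3L] * ac[, 1L] - ab[, 1L] * ac[, 3L],
             ab[, 1L] * ac[, 2L] - ab[, 2L] * ac[, 1L])
  0.5 * sqrt(rowSums(n^2))
}

#' Make triangle winding consistent and outward
#'
#' Propagates a consistent winding across shared edges (breadth-first over the
#' face adjacency of each connected component) and, for meshes enclosing a
#' volume, flips everything if the signed volume comes out negative, so that
#' face normals point outward. Signed-distance queries assume this
#' orientation.
#'
#' @param mesh A [triangle_mesh()].
#' @return The mesh with consistently oriented faces.
#' @export
orient_mesh <- function(mesh) {
  f <- mesh$faces
  nf <- nrow(f)
  # map undirected edge -> incident faces
  e <- face_edges(mesh)
  key <- paste(e[, 1L], e[, 2L])
  face_of_edge <- rep(seq_len(nf), 3L)
  by_edge <- split(face_of_edge, key)
  # directed-edge sets per face, used to test relative winding
  dir_edges <- function(tri) rbind(tri[c(1L, 2L)], tri[c(2L, 3L)], tri[c(3L, 1L)])
  visited <- rep(FALSE, nf)
  flipped <- rep(FALSE, nf)
  adj <- by_edge[lengths(by_edge) == 2L]
  nbr <- new.env(hash = TRUE)
  for (pair in adj) {
    a <- as.character(pair[1L]); b <- as.character(pair[2L])
    nbr[[a]] <- c(nbr[[a]], pair[2L])
    nbr[[b]] <- c(nbr[[b]], pair[1L])
  }
  for (start in seq_len(nf)) {
    if (visited[start]) next
    queue <- start
    visited[start] <- TRUE
    while (length(queue)) {
      cur <- queue[[1L]]
      queue <- queue[-1L]
      tri_cur <- f[cur, ]
      if (flipped[cur]) tri_cur <- tri_cur[c(1L, 3L, 2L)]
      de_cur <- dir_edges(tri_cur)
      for (nx in nbr[[as.character(cur)]]) {
        if (visited[nx]) next
        tri_nx <- f[nx, ]
        de_nx <- dir_edges(tri_nx)
        # consistent iff shared edge traversed in opposite directions
        same_dir <- any(de_cur[, 1L] %in% de_nx[, 1L] &
                        de_cur[, 2L] %in% de_nx[, 2L] &
                        paste(de_cur[, 1L], de_cur[, 2L]) %in%
                          paste(de_nx[, 1L], de_nx[, 2L]))
        flipped[nx] <- same_dir
        visited[nx] <- TRUE
        queue <- c(queue, nx)
      }
    }
  }
  if (any(flipped)) {
    f[flipped, ] <- f[flipped, c(1L, 3L, 2L), drop = FALSE]
    mesh$faces <- f
  }
  # outward: positive enclosed volume for closed meshes
  if (signed_volume(mesh) < 0) {
    mesh$faces <- mesh$faces[, c(1L, 3L, 2L), drop = FALSE]
  }
  mesh
}

signed_volume <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  v1 <- v[f[, 1L], , drop = FALSE]
  v2 <- v[f[, 2L], , drop = FALSE]
  v3 <- v[f[, 3L], , drop = FALSE]
  cr <- cbind(v1[, 2L] * v2[, 3L] - v1[, 3L] * v2[, 2L],
              v1[, 3L] * v2[, 1L] - v1[, 1L] * v2[, 3L],
              v1[, 1L] * v2[, 2L] - v1[, 2L] * v2[, 1L])
  sum(rowSums(cr * v3)) / 6
}

# Closest point on each triangle to point p, vectorized over triangles.
# Returns list(points = m x 3, dist2 = m, region = m) where region codes
# 1,2,3 = vertices A,B,C; 4,5,6 = edges AB, AC, BC; 7 = face interior.
closest_point_on_triangles <- function(p, v1, v2, v3) {
  ab <- v2 - v1
  ac <- v3 - v1
  ap <- sweep(-v1, 2L, p, `+`)
  d1 <- rowSums(ab * ap)
  d2 <- rowSums(ac * ap)
  bp <- sweep(-v2, 2L, p, `+`)
  d3 <- rowSums(ab * bp)
  d4 <- rowSums(ac * bp)
  cp <- sweep(-v3, 2L, p, `+`)
  d5 <- rowSums(ab * cp)
  d6 <- rowSums(ac * cp)
  vc <- d1 * d4 - d3 * d2
  vb <- d5 * d2 - d1 * d6
  va <- d3 * d6 - d5 * d4

  m <- nrow(v1)
  out <- matrix(0, m, 3L)
  region <- integer(m)
  done <- rep(FALSE, m)

  take <- function(mask) mask & !done
  # vertex regions
  i <- take(d1 <= 0 & d2 <= 0)
  out[i, ] <- v1[i, , drop = FALSE]; region[i] <- 1L; done[i] <- TRUE
  i <- take(d3 >= 0 & d4 <= d3)
  out[i, ] <- v2[i, , drop = FALSE]; region[i] <- 2L; done[i] <- TRUE
  i <- take(d6 >= 0 & d5 <= d6)
  out[i, ] <- v3[i, , drop = FALSE]; region[i] <- 3L; done[i] <- TRUE
  # edge AB
  i <- take(vc <= 0 & d1 >= 0 & d3 <= 0)
  if (any(i)) {
    t <- d1[i] / (d1[i] - d3[i])
    out[i, ] <- v1[i, , drop = FALSE] + ab[i, , drop = FALSE] * t
    region[i] <- 4L; done[i] <- TRUE
  }
  # edge AC
  i <- take(vb <= 0 & d2 >= 0 & d6 <= 0)
  if (any(i)) {
    t <- d2[i] / (d2[i] - d6[i])
    out[i, ] <- v1[i, , drop = FALSE] + ac[i, , drop = FALSE] * t
    region[i] <- 5L; done[i] <- TRUE
  }
  # edge BC
  i <- take(va <= 0 & (d4 - d3) >= 0 & (d5 - d6) >= 0)
  if (any(i)) {
    t <- (d4[i] - d3[i]) / ((d4[i] - d3[i]) + (d5[i] - d6[i]))
    out[i, ] <- v2[i, , drop = FALSE] +
      (v3[i, , drop = FALSE] - v2[i, , drop = FALSE]) * t
    region[i] <- 6L; done[i] <- TRUE
  }
  # interior
  i <- !done
  if (any(i)) {
    denom <- va[i] + vb[i] + vc[i]
    denom[denom == 0] <- .Machine$double.eps
    v <- vb[i] / denom
    w <- vc[i] / denom
    out[i, ] <- v1[i, , drop = FALSE] + ab[i, , drop = FALSE] * v +
      ac[i, , drop = FALSE] * w
    region[i] <- 7L
  }
  diff <- sweep(out, 2L, p, `-`)
  list(points = out, dist2 = rowSums(diff^2), region = region)
}

# Precompute per-mesh data for signed-distance queries: face normals plus
# angle-weighted vertex pseudo-normals and edge pseudo-normals.
sdf_precompute <- function(mesh) {
  mesh <- orient_mesh(mesh)
  v <- mesh$vertices
  f <- mesh$faces
  fn <- face_normals(mesh)
  # angle-weighted vertex pseudo-normals
  vn <- matrix(0, nrow(v), 3L)
  for (j in 1:3) {
    i0 <- f[, j]
    i1 <- f[, (j %% 3L) + 1L]
    i2 <- f[, ((j + 1L) %% 3L) + 1L]
    e1 <- v[i1, , drop = FALSE] - v[i0, , drop = FALSE]
    e2 <- v[i2, , drop = FALSE] - v[i0, , drop = FALSE]
    l1 <- sqrt(rowSums(e1^2)); l2 <- sqrt(rowSums(e2^2))
    cosang <- rowSums(e1 * e2) / pmax(l1 * l2, .Machine$double.eps)
    ang <- acos(pmin(pmax(cosang, -1), 1))
    w <- fn * ang
    for (k in 1:3) vn[, k] <- vn[, k] + tapply_add(w[, k], i0, nrow(v))
  }
  len <- sqrt(rowSums(vn^2))
  vn <- vn / ifelse(len > 0, len, 1)
  # edge pseudo-normals: mean of incident face normals
  e <- face_edges(mesh)
  key <- paste(e[, 1L], e[, 2L])
  face_idx <- rep(seq_len(nrow(f)), 3L)
  en_sum <- rowsum(fn[face_idx, , drop = FALSE], key)
  elen <- sqrt(rowSums(en_sum^2))
  en <- en_sum / ifelse(elen > 0, elen, 1)
  list(mesh = mesh, face_normals = fn, vertex_normals = vn,
       edge_normals = en, edge_keys = rownames(en_sum))
}

tapply_add <- function(x, idx, n) {
  out <- numeric(n)
  s <- rowsum(x, idx)
  out[as.integer(rownames(s))] <- s
  out
}

#' Signed distance from a point to a mesh surface
#'
#' Finds the closest point on the surface over all triangles, the offset
#' vector from that projection to the query point, the unsigned Euclidean
#' distance, and the sign of the distance: positive outside the surface,
#' negative inside. The sign is the sign of the dot product between the
#' offset and the surface normal at the projection; when the projection lands
#' on an edge or vertex, where the face normal is ambiguous, the
#' angle-weighted pseudo-normal of that feature is used instead.
#'
#' @param p Numeric length-3 point.
#' @param mesh A [triangle_mesh()] with consistent outward orientation
#'   (orientation is fixed internally via [orient_mesh()]).
#' @param data Optional precomputed query data (internal; reuse across many
#'   queries against the same mesh).
#' @return A list of class `signed_distance_result`: `projection` (closest
#'   surface point), `offset` (`p - projection`), `unsigned_distance`,
#'   `signed_distance`, and `surface_normal_at_projection` (unit vector).
#' @examples
#' tet <- triangle_mesh(
#'   rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
#'   rbind(c(1, 3, 2), c(1, 2, 4), c(2, 3, 4), c(1, 4, 3))
#' )
#' signed_distance(c(2, 0, 0), tet)$signed_distance  # +1: outside
#' @export
signed_distance <- function(p, mesh, data = NULL) {
  stopifnot(length(p) == 3L)
  if (is.null(data)) data <- sdf_precompute(mesh)
  mesh <- data$mesh
  v <- mesh$vertices
  f <- mesh$faces
  v1 <- v[f[, 1L], , drop = FALSE]
  v2 <- v[f[, 2L], , drop = FALSE]
  v3 <- v[f[, 3L], , drop = FALSE]
  cp <- closest_point_on_triangles(p, v1, v2, v3)
  best <- which.min(cp$dist2)
  proj <- cp$points[best, ]
  region <- cp$region[best]
  normal <- switch(region,
    data$vertex_normals[f[best, 1L], ],            # 1: vertex A
    data$vertex_normals[f[best, 2L], ],            # 2: vertex B
    data$vertex_normals[f[best, 3L], ],            # 3: vertex C
    edge_pseudo_normal(data, f[best, 1L], f[best, 2L]),  # 4: edge AB
    edge_pseudo_normal(data, f[best, 1L], f[best, 3L]),  # 5: edge AC
    edge_pseudo_normal(data, f[best, 2L], f[best, 3L]),  # 6: edge BC
    data$face_normals[best, ]                      # 7: interior
  )
  if (sum(normal^2) == 0) {
    # degenerate nearest triangle: fall back to nearest vertex pseudo-normal
    dv <- sweep(v, 2L, p, `-`)
    normal <- data$vertex_normals[which.min(rowSums(dv^2)), ]
  }
  offset <- p - proj
  d <- sqrt(sum(offset^2))
  s <- if (d == 0) 0 else d * sign(sum(offset * normal))
  structure(list(projection = proj,
                 offset = offset,
                 unsigned_distance = d,
                 signed_distance = s,
                 surface_normal_at_projection = normal),
            class = "signed_distance_result")
}

edge_pseudo_normal <- function(data, i, j) {
  key <- paste(min(i, j), max(i, j))
  data$edge_normals[match(key, data$edge_keys), ]
}

#' @export
print.signed_distance_result <- function(x, ...) {
  cat(sprintf("signed distance %.6g (unsigned %.6g)\n",
              x$signed_distance, x$unsigned_distance))
  invisible(x)
}

#' Signed distances for many query points
#'
#' @param points n x 3 matrix of query points.
#' @inheritParams signed_distance
#' @return Numeric vector of signed distances.
#' @export
signed_distances <- function(points, mesh) {
  points <- as.matrix(points)
  data <- sdf_precompute(mesh)
  apply(points, 1L, function(p) signed_distance(p, mesh, data)$signed_distance)
}
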