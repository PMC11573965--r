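# Small reference meshes built in code.

# axis-aligned unit cube [0,1]^3, 8 vertices / 12 triangles, outward faces
cube_mesh <- function() {
  v <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))
  dimnames(v) <- NULL
  f <- rbind(
    c(1, 3, 2), c(2, 3, 4),    # z = 0
    c(5, 6, 7), c(6, 8, 7),    # z = 1
    c(1, 2, 5), c(2, 6, 5),    # y = 0
    c(3, 7, 4), c(4, 7, 8),    # y = 1
    c(1, 5, 3), c(3, 5, 7),    # x = 0
    c(2, 4, 6), c(4, 8, 6)     # x = 1
  )
  orient_mesh(triangle_mesh(v, f))
}

# regular unit-corner tetrahedron (closed)
tet_mesh <- function() {
  orient_mesh(triangle_mesh(
    rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
    rbind(c(1, 3, 2), c(1, 2, 4), c(2, 3, 4), c(1, 4, 3))
  ))
}

single_triangle <- function() {
  triangle_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                matrix(c(1, 2, 3), 1))
}

# two triangles sharing the diagonal of a unit square (open)
square_mesh <- function() {
  triangle_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0)),
                rbind(c(1, 2, 3), c(1, 3, 4)))
}

# flat triangulated grid patch in the z = 0 plane
plane_mesh <- function(n = 10) {
  g <- expand.grid(x = seq(0, 1, length.out = n),
                   y = seq(0, 1, length.out = n))
  v <- cbind(g$x, g$y, 0)
  idx <- function(i, j) (j - 1L) * n + i
  f <- NULL
  for (j in seq_len(n - 1L)) {
    for (i in seq_len(n - 1L)) {
      f <- rbind(f, c(idx(i, j), idx(i + 1L, j), idx(i, j + 1L)),
                 c(idx(i + 1L, j), idx(i + 1L, j + 1L), idx(i, j + 1L)))
    }
  }
  triangle_mesh(v, f)
}

random_rigid_transform <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  list(rot = q, shift = rnorm(3, sd = 5))
}

apply_rigid <- function(mesh, tf, scale = 1) {
  mesh$vertices <- sweep(scale * mesh$vertices %*% tf$rot, 2, tf$shift, `+`)
  mesh
}

# small synthetic feature table without meshes
random_feature_table <- function(n, seed = 1) {
  set.seed(seed)
  tab <- data.frame(unique_id = seq_len(n),
                    matrix(rnorm(10 * n), n, 10,
                           dimnames = list(NULL, meshgat:::feature_names)),
                    target = rep_len(c("benign", "malignant"), n))
  tab
}

# independent scalar closest-point oracle: evaluates all 7 candidate
# projections (plane, three clamped edges, three vertices) per triangle
brute_force_closest <- function(p, mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  best <- Inf
  best_pt <- NULL
  seg_closest <- function(p, a, b) {
    t <- sum((p - a) * (b - a)) / sum((b - a)^2)
    a + min(max(t, 0), 1) * (b - a)
  }
  for (i in seq_len(nrow(f))) {
    A <- v[f[i, 1], ]; B <- v[f[i, 2], ]; C <- v[f[i, 3], ]
    nrm <- c((B - A)[2] * (C - A)[3] - (B - A)[3] * (C - A)[2],
             (B - A)[3] * (C - A)[1] - (B - A)[1] * (C - A)[3],
             (B - A)[1] * (C - A)[2] - (B - A)[2] * (C - A)[1])
    cands <- list(A, B, C,
                  seg_closest(p, A, B), seg_closest(p, A, C),
                  seg_closest(p, B, C))
    if (sum(nrm^2) > 0) {
      nrm <- nrm / sqrt(sum(nrm^2))
      proj <- p - sum((p - A) * nrm) * nrm
      # barycentric test for plane projection
      m <- cbind(B - A, C - A)
      uv <- tryCatch(qr.solve(crossprod(m), crossprod(m, proj - A)),
                     error = function(e) NULL)
      if (!is.null(uv) && uv[1] >= 0 && uv[2] >= 0 && sum(uv) <= 1) {
        cands <- c(cands, list(proj))
      }
    }
    for (q in cands) {
      d <- sum((p - q)^2)
      if (d < best) {
        best <- d
        best_pt <- q
      }
    }
  }
  list(point = best_pt, distance = sqrt(best))
}
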