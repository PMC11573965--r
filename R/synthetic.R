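#' Unit icosphere mesh
#'
#' Subdivided icosahedron projected onto the unit sphere; the base primitive
#' for all synthetic tumor shapes. Subdivision level 0 is the icosahedron
#' (12 vertices, 20 faces); each level quadruples the face count.
#'
#' @param subdivisions Number of 4-to-1 triangle subdivisions (>= 0).
#' @param radius Sphere radius. Default 1.
#' @return A watertight [triangle_mesh()].
#' @examples
#' icosphere(2)  # 162 vertices, 320 faces
#' @export
icosphere <- function(subdivisions = 2L, radius = 1) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c( phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1)
  )
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2)
  )
  for (s in seq_len(subdivisions)) {
    mids <- new.env(hash = TRUE)
    nv <- nrow(v)
    newv <- list()
    midpoint <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      hit <- mids[[key]]
      if (!is.null(hit)) return(hit)
      m <- v[i, ] + v[j, ]
      m <- m / sqrt(sum(m^2))
      newv[[length(newv) + 1L]] <<- m
      idx <- nv + length(newv)
      mids[[key]] <- idx
      idx
    }
    newf <- matrix(0L, nrow(f) * 4L, 3L)
    for (t in seq_len(nrow(f))) {
      a <- f[t, 1L]; b <- f[t, 2L]; c3 <- f[t, 3L]
      ab <- midpoint(a, b); bc <- midpoint(b, c3); ca <- midpoint(c3, a)
      newf[(t - 1L) * 4L + 1:4, ] <- rbind(
        c(a, ab, ca), c(b, bc, ab), c(c3, ca, bc), c(ab, bc, ca))
    }
    v <- rbind(v, do.call(rbind, newv))
    f <- newf
  }
  triangle_mesh(v * radius, f)
}

#' Shape parameters for the synthetic tumor generator
#'
#' The generator deforms a subdivided icosphere radially: an ellipsoid base
#' (semi-axes), a smooth low-order lobulation of the radius, optional sharp
#' Gaussian radial spikes at random unit directions (spiculation), and
#' per-vertex radial Gaussian noise (surface roughness). All deformations are
#' radial, so the mesh stays watertight by construction.
#'
#' @param semi_axes Positive length-3 vector of ellipsoid semi-axes
#'   (mesh coordinate units).
#' @param lobe_amp Amplitudes of the smooth radial modulation components
#'   (dimensionless fractions of the local radius, >= 0). A vector gives
#'   several superimposed components, e.g. a low-frequency macrolobulation
#'   plus a high-frequency microlobulation.
#' @param lobe_freq Angular frequencies of the lobulation components (small
#'   integers, recycled against `lobe_amp`).
#' @param n_spikes Number of radial spikes (>= 0).
#' @param spike_amp Spike amplitude as a fraction of the local radius (>= 0).
#' @param spike_sharp Angular width of each spike in radians (> 0); smaller
#'   is sharper.
#' @param noise_sd Standard deviation of per-vertex radial noise
#'   (fraction of local radius, >= 0).
#' @param subdivisions Icosphere subdivision level of the template.
#' @return A list of class `shape_params`.
#' @export
shape_params <- function(semi_axes = c(1, 0.9, 0.8),
                         lobe_amp = 0.3, lobe_freq = 2,
                         n_spikes = 0L, spike_amp = 0,
                         spike_sharp = 0.3,
                         noise_sd = 0.005,
                         subdivisions = 2L) {
  if (any(semi_axes <= 0)) stop("semi_axes must be positive")
  if (any(lobe_amp < 0) || spike_amp < 0 || noise_sd < 0) {
    stop("amplitudes must be nonnegative")
  }
  lobe_freq <- rep_len(lobe_freq, length(lobe_amp))
  structure(list(semi_axes = semi_axes, lobe_amp = lobe_amp,
                 lobe_freq = lobe_freq, n_spikes = as.integer(n_spikes),
                 spike_amp = spike_amp, spike_sharp = spike_sharp,
                 noise_sd = noise_sd, subdivisions = as.integer(subdivisions)),
            class = "shape_params")
}

random_unit_vectors <- function(n) {
  m <- matrix(stats::rnorm(3L * n), n, 3L)
  m / sqrt(rowSums(m^2))
}

random_rotation <- function() {
  qr_res <- qr(matrix(stats::rnorm(9L), 3L, 3L))
  q <- qr.Q(qr_res)
  if (det(q) < 0) q[, 1L] <- -q[, 1L]
  q
}

# Core radial construction shared by the benign and malignant wrappers.
make_tumor_mesh <- function(params, seed) {
  stopifnot(inherits(params, "shape_params"))
  if (!missing(seed) && !is.null(seed)) set.seed(seed)
  base <- icosphere(params$subdivisions)
  u <- base$vertices                       # unit directions
  ax <- params$semi_axes
  # radial function of the ellipsoid along direction u
  r_ell <- 1 / sqrt((u[, 1L] / ax[1L])^2 + (u[, 2L] / ax[2L])^2 +
                    (u[, 3L] / ax[3L])^2)
  modulation <- rep(1, nrow(u))
  for (j in seq_along(params$lobe_amp)) {
    if (params$lobe_amp[j] <= 0) next
    rot <- random_rotation()
    ur <- u %*% rot
    th <- acos(pmin(pmax(ur[, 3L], -1), 1))
    ph <- atan2(ur[, 2L], ur[, 1L])
    modulation <- modulation + params$lobe_amp[j] *
      cos(params$lobe_freq[j] * th) * cos(params$lobe_freq[j] * ph)
  }
  if (params$n_spikes > 0L) {
    dirs <- random_unit_vectors(params$n_spikes)
    ang <- acos(pmin(pmax(u %*% t(dirs), -1), 1))   # nv x n_spikes
    bumps <- params$spike_amp * exp(-(ang / params$spike_sharp)^2)
    modulation <- modulation + rowSums(bumps)
  }
  if (params$noise_sd > 0) {
    modulation <- modulation + stats::rnorm(nrow(u), sd = params$noise_sd)
  }
  r <- r_ell * pmax(modulation, 0.05)
  triangle_mesh(u * r, base$faces)
}

#' Generate a synthetic benign-like tumor mesh
#'
#' Benign lesions are emulated as smooth, round-to-oval closed surfaces: an
#' ellipsoid with gentle low-order lobulation and small surface noise, no
#' spiculation. The mesh is watertight by construction and deterministic for
#' a fixed seed.
#'
#' @param params A [shape_params()]; defaults to the benign preset.
#' @param seed Integer RNG seed.
#' @return A [triangle_mesh()].
#' @export
make_benign_mesh <- function(params = shape_params(), seed = NULL) {
  make_tumor_mesh(params, seed)
}

#' Generate a synthetic malignant-like tumor mesh
#'
#' Malignant lesions are emulated as larger, elongated, spiculated and rough
#' surfaces: the benign construction plus radial Gaussian spikes at random
#' directions and stronger surface noise. With `spike_amp = 0` and identical
#' parameters the construction reduces exactly to the benign one.
#'
#' @param params A [shape_params()]; defaults to the malignant preset
#'   ([malignant_params()] at separation 1).
#' @param seed Integer RNG seed.
#' @return A [triangle_mesh()].
#' @export
make_malignant_mesh <- function(params = malignant_params(), seed = NULL) {
  make_tumor_mesh(params, seed)
}

#' Class presets for the generator
#'
#' `benign_params()` and `malignant_params()` return the [shape_params()]
#' defining each class at a given class separation. Benign lesions are
#' smooth-to-macrolobulated ovals (one low-frequency lobulation component,
#' tiny surface noise, no spiculation), mirroring the round/oval smooth
#' margins of typical benign masses. Malignant lesions add, scaled by
#' `separation`: overall size growth and mild elongation, a high-frequency
#' microlobulation component, radial spikes (spiculation), and stronger
#' surface roughness. At `separation = 0` the malignant preset equals the
#' benign one (the null model).
#'
#' @param separation Class-separation scale in \[0, 1\].
#' @param scale Overall size multiplier (per-mesh jitter enters here).
#' @return A [shape_params()].
#' @export
benign_params <- function(separation = 0.8, scale = 1) {
  shape_params(
    semi_axes = scale * c(1, 0.9, 0.8),
    lobe_amp = 0.3, lobe_freq = 2,
    n_spikes = 0L, spike_amp = 0,
    spike_sharp = 0.3,
    noise_sd = 0.005,
    subdivisions = 2L
  )
}

#' @rdname benign_params
#' @export
malignant_params <- function(separation = 0.8, scale = 1) {
  s <- separation
  shape_params(
    semi_axes = scale * (1 + 0.35 * s) * c(1 + 0.15 * s, 0.9, 0.8),
    lobe_amp = c(0.3, 0.2 * s), lobe_freq = c(2, 6),
    n_spikes = if (s > 0) 14L else 0L,
    spike_amp = 0.55 * s,
    spike_sharp = 0.3,
    noise_sd = 0.005 + 0.025 * s,
    subdivisions = 2L
  )
}

#' Generate a labeled synthetic mesh dataset
#'
#' Draws `n_benign` benign-like and `n_malignant` malignant-like meshes with
#' per-mesh parameter jitter (size and amplitude variation within each class)
#' so that within-class variance is nonzero. `separation` scales every
#' between-class contrast; at 0 the two classes are drawn from the same
#' distribution.
#'
#' @param n_benign,n_malignant Class sizes. Defaults mirror the 294/151
#'   benign/malignant imbalance of the motivating breast-ultrasound cohort.
#' @param separation Class separation in \[0, 1\]. Default 0.8.
#' @param seed Integer RNG seed; the draw is fully reproducible.
#' @param subdivisions Icosphere subdivision level for all meshes.
#' @return A list with `meshes` (named list of [triangle_mesh()]) and
#'   `labels` (data.frame `mesh_id`, `target` with levels benign/malignant).
#' @examples
#' ds <- make_dataset(6, 3, separation = 1, seed = 1)
#' table(ds$labels$target)
#' @export
make_dataset <- function(n_benign = 294L, n_malignant = 151L,
                         separation = 0.8, seed = 1L, subdivisions = 2L) {
  stopifnot(n_benign >= 0L, n_malignant >= 0L,
            separation >= 0, separation <= 1)
  set.seed(seed)
  meshes <- vector("list", n_benign + n_malignant)
  labels <- character(n_benign + n_malignant)
  k <- 0L
  # per-mesh jitter: macrolobulation amplitude/frequency and overall size
  # vary within both classes identically; malignant-only amplitudes get an
  # extra lognormal jitter so the spiculation strength varies too
  for (i in seq_len(n_benign)) {
    k <- k + 1L
    p <- benign_params(separation, scale = exp(stats::rnorm(1L, sd = 0.12)))
    p$subdivisions <- as.integer(subdivisions)
    p$lobe_amp[1L] <- stats::runif(1L, 0.15, 0.5)
    p$lobe_freq[1L] <- sample(2:3, 1L)
    meshes[[k]] <- make_tumor_mesh(p)
    labels[k] <- "benign"
  }
  for (i in seq_len(n_malignant)) {
    k <- k + 1L
    p <- malignant_params(separation,
                          scale = exp(stats::rnorm(1L, sd = 0.12)))
    p$subdivisions <- as.integer(subdivisions)
    p$lobe_amp[1L] <- stats::runif(1L, 0.15, 0.5)
    p$lobe_freq[1L] <- sample(2:3, 1L)
    jit <- exp(stats::rnorm(1L, sd = 0.2))
    p$lobe_amp[-1L] <- p$lobe_amp[-1L] * jit
    if (p$spike_amp > 0) {
      p$spike_amp <- p$spike_amp * exp(stats::rnorm(1L, sd = 0.2))
      p$n_spikes <- p$n_spikes + sample(-3:3, 1L)
    }
    meshes[[k]] <- make_tumor_mesh(p)
    labels[k] <- "malignant"
  }
  names(meshes) <- sprintf("mesh_%03d", seq_along(meshes))
  list(meshes = meshes,
       labels = data.frame(mesh_id = names(meshes), target = labels))
}

#' Punch random holes into a mesh
#'
#' Removes `n_faces` random faces, turning their edges into boundary edges;
#' used to exercise the hole quality control on otherwise watertight
#' synthetic meshes.
#'
#' @param mesh A [triangle_mesh()].
#' @param n_faces Number of faces to delete.
#' @param seed Integer RNG seed.
#' @return The damaged mesh.
#' @export
punch_holes <- function(mesh, n_faces = 1L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(n_faces < nrow(mesh$faces))
  drop <- sample.int(nrow(mesh$faces), n_faces)
  triangle_mesh(mesh$vertices, mesh$faces[-drop, , drop = FALSE])
}
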