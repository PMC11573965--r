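#' Construct a triangle mesh
#'
#' A `triangle_mesh` stores vertex coordinates and triangular faces and is the
#' object every geometric operation in the package consumes.
#'
#' @param vertices Numeric matrix with one row per vertex and three columns
#'   (x, y, z), in arbitrary length units.
#' @param faces Integer matrix with one row per triangle and three columns of
#'   1-based vertex indices.
#' @param validate Check the mesh invariants (indices in range, three distinct
#'   vertices per face). Default `TRUE`.
#' @return An object of class `triangle_mesh`: a list with elements
#'   `vertices` (n x 3 numeric) and `faces` (m x 3 integer).
#' @examples
#' tet <- triangle_mesh(
#'   rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
#'   rbind(c(1, 3, 2), c(1, 2, 4), c(2, 3, 4), c(1, 4, 3))
#' )
#' tet
#' @export
triangle_mesh <- function(vertices, faces, validate = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("`vertices` must have three columns")
  if (ncol(faces) != 3L) stop("`faces` must have three columns")
  dimnames(vertices) <- NULL
  dimnames(faces) <- NULL
  mesh <- structure(list(vertices = vertices, faces = faces),
                    class = "triangle_mesh")
  if (validate) validate_mesh(mesh)
  mesh
}

validate_mesh <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  if (nrow(v) < 3L) stop("mesh must have at least 3 vertices")
  if (nrow(f) < 1L) stop("mesh must have at least 1 face")
  if (anyNA(v) || anyNA(f)) stop("mesh contains missing values")
  if (min(f) < 1L || max(f) > nrow(v)) {
    stop("face indices out of range [1, ", nrow(v), "]")
  }
  degen <- f[, 1L] == f[, 2L] | f[, 1L] == f[, 3L] | f[, 2L] == f[, 3L]
  if (any(degen)) {
    stop(sum(degen), " face(s) with repeated vertex indices")
  }
  invisible(mesh)
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat("triangle_mesh:", nrow(x$vertices), "vertices,",
      nrow(x$faces), "faces\n")
  bb <- apply(x$vertices, 2L, range)
  cat(sprintf("  bbox x [%.4g, %.4g] y [%.4g, %.4g] z [%.4g, %.4g]\n",
              bb[1, 1], bb[2, 1], bb[1, 2], bb[2, 2], bb[1, 3], bb[2, 3]))
  invisible(x)
}

# Fan-triangulate a polygon given as a vector of >= 3 vertex indices.
fan_triangulate <- function(idx) {
  n <- length(idx)
  if (n == 3L) return(matrix(idx, nrow = 1L))
  cbind(idx[1L], idx[seq.int(2L, n - 1L)], idx[seq.int(3L, n)])
}

bind_faces <- function(flist, path) {
  if (!length(flist)) stop("empty mesh: '", path, "' has no faces")
  do.call(rbind, flist)
}

guess_format <- function(path) {
  ext <- tolower(sub(".*\\.", "", basename(path)))
  if (!ext %in% c("ply", "obj", "off", "stl")) {
    stop("cannot guess mesh format from extension '", ext,
         "'; pass `format` explicitly")
  }
  ext
}

#' Read a triangle mesh from file
#'
#' Supports ascii OFF, Wavefront OBJ, PLY (ascii and binary little-endian) and
#' ascii STL. Polygonal faces with more than three vertices are
#' fan-triangulated. Vertex order is preserved as stored in the file; for STL,
#' which repeats vertices per facet, exactly coincident vertices are merged so
#' that surface topology (shared edges) is recovered.
#'
#' @param path Path to the mesh file.
#' @param format One of `"auto"`, `"ply"`, `"obj"`, `"off"`, `"stl"`.
#'   `"auto"` (default) guesses from the file extension.
#' @return A [triangle_mesh()].
#' @seealso [write_mesh()]
#' @export
read_mesh <- function(path, format = c("auto", "ply", "obj", "off", "stl")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read mesh: no such file '", path, "'")
  if (format == "auto") format <- guess_format(path)
  mesh <- switch(format,
    off = read_off(path),
    obj = read_obj(path),
    ply = read_ply(path),
    stl = read_stl(path)
  )
  if (is.null(mesh$faces) || nrow(mesh$faces) == 0L) {
    stop("empty mesh: '", path, "' has no faces")
  }
  validate_mesh(mesh)
  mesh
}

#' Write a triangle mesh to file
#'
#' @param mesh A [triangle_mesh()].
#' @param path Output path.
#' @param format One of `"auto"`, `"ply"`, `"obj"`, `"off"`, `"stl"`;
#'   `"auto"` guesses from the extension.
#' @param binary For PLY only: write binary little-endian instead of ascii.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path,
                       format = c("auto", "ply", "obj", "off", "stl"),
                       binary = FALSE) {
  format <- match.arg(format)
  validate_mesh(mesh)
  if (format == "auto") format <- guess_format(path)
  switch(format,
    off = write_off(mesh, path),
    obj = write_obj(mesh, path),
    ply = write_ply(mesh, path, binary = binary),
    stl = write_stl(mesh, path)
  )
  invisible(path)
}

read_off <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (toupper(lines[1L]) == "OFF") lines <- lines[-1L]
  counts <- scan(text = lines[1L], quiet = TRUE)
  nv <- counts[1L]
  nf <- counts[2L]
  body <- scan(text = lines[-1L], quiet = TRUE)
  verts <- matrix(body[seq_len(3L * nv)], ncol = 3L, byrow = TRUE)
  pos <- 3L * nv
  faces <- vector("list", nf)
  for (i in seq_len(nf)) {
    k <- body[pos + 1L]
    idx <- body[pos + 1L + seq_len(k)] + 1L  # OFF is 0-based
    faces[[i]] <- fan_triangulate(as.integer(idx))
    pos <- pos + 1L + k
  }
  triangle_mesh(verts, bind_faces(faces, path), validate = FALSE)
}

write_off <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("OFF", con)
  writeLines(sprintf("%d %d 0", nrow(mesh$vertices), nrow(mesh$faces)), con)
  writeLines(apply(mesh$vertices, 1L,
                   function(v) paste(format(v, digits = 17), collapse = " ")),
             con)
  writeLines(paste(3L, mesh$faces[, 1L] - 1L, mesh$faces[, 2L] - 1L,
                   mesh$faces[, 3L] - 1L), con)
}

read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vlines <- lines[startsWith(lines, "v ")]
  flines <- lines[startsWith(lines, "f ")]
  verts <- matrix(scan(text = gsub("^v ", "", vlines), quiet = TRUE),
                  ncol = 3L, byrow = TRUE)
  faces <- lapply(flines, function(l) {
    toks <- strsplit(trimws(sub("^f ", "", l)), "[[:space:]]+")[[1L]]
    idx <- as.integer(sub("/.*", "", toks))  # drop texture/normal refs
    fan_triangulate(idx)
  })
  triangle_mesh(verts, bind_faces(faces, path), validate = FALSE)
}

write_obj <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(apply(mesh$vertices, 1L, function(v)
    paste("v", paste(format(v, digits = 17), collapse = " "))), con)
  writeLines(paste("f", mesh$faces[, 1L], mesh$faces[, 2L],
                   mesh$faces[, 3L]), con)
}

read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  # Header is always ascii, one declaration per line.
  header <- character()
  repeat {
    line <- read_ascii_line(con)
    header <- c(header, line)
    if (line == "end_header") break
  }
  fmt_line <- grep("^format ", header, value = TRUE)
  fmt <- strsplit(fmt_line, "[[:space:]]+")[[1L]][2L]
  elems <- parse_ply_header(header)
  if (fmt == "ascii") {
    read_ply_ascii(con, elems)
  } else if (fmt == "binary_little_endian") {
    read_ply_binary(con, elems, endian = "little")
  } else if (fmt == "binary_big_endian") {
    read_ply_binary(con, elems, endian = "big")
  } else {
    stop("unsupported PLY format: ", fmt)
  }
}

read_ascii_line <- function(con) {
  chars <- character()
  repeat {
    ch <- readChar(con, 1L, useBytes = TRUE)
    if (length(ch) == 0L) stop("unexpected end of PLY header")
    if (ch == "\n") break
    chars <- c(chars, ch)
  }
  sub("\r$", "", paste(chars, collapse = ""))
}

parse_ply_header <- function(header) {
  elems <- list()
  current <- NULL
  for (line in header) {
    toks <- strsplit(trimws(line), "[[:space:]]+")[[1L]]
    if (toks[1L] == "element") {
      if (!is.null(current)) elems[[current$name]] <- current
      current <- list(name = toks[2L], count = as.integer(toks[3L]),
                      props = list())
    } else if (toks[1L] == "property") {
      if (toks[2L] == "list") {
        current$props[[length(current$props) + 1L]] <-
          list(name = toks[5L], type = toks[4L], list = TRUE,
               count_type = toks[3L])
      } else {
        current$props[[length(current$props) + 1L]] <-
          list(name = toks[3L], type = toks[2L], list = FALSE)
      }
    }
  }
  if (!is.null(current)) elems[[current$name]] <- current
  elems
}

ply_type_info <- function(type) {
  switch(type,
    char = , int8 = list(what = integer(), size = 1L, signed = TRUE),
    uchar = , uint8 = list(what = integer(), size = 1L, signed = FALSE),
    short = , int16 = list(what = integer(), size = 2L, signed = TRUE),
    ushort = , uint16 = list(what = integer(), size = 2L, signed = FALSE),
    int = , int32 = list(what = integer(), size = 4L, signed = TRUE),
    uint = , uint32 = list(what = integer(), size = 4L, signed = TRUE),
    float = , float32 = list(what = double(), size = 4L, signed = TRUE),
    double = , float64 = list(what = double(), size = 8L, signed = TRUE),
    stop("unknown PLY type: ", type)
  )
}

read_ply_ascii <- function(con, elems) {
  rest <- readLines(con, warn = FALSE)
  rest <- trimws(rest)
  rest <- rest[nzchar(rest)]
  row <- 1L
  verts <- NULL
  faces <- NULL
  for (el in elems) {
    if (el$name == "vertex") {
      pnames <- vapply(el$props, `[[`, "", "name")
      vals <- matrix(scan(text = rest[seq.int(row, row + el$count - 1L)],
                          quiet = TRUE),
                     nrow = el$count, byrow = TRUE)
      verts <- vals[, match(c("x", "y", "z"), pnames), drop = FALSE]
      row <- row + el$count
    } else if (el$name == "face") {
      flist <- lapply(rest[seq.int(row, row + el$count - 1L)], function(l) {
        nums <- scan(text = l, quiet = TRUE)
        fan_triangulate(as.integer(nums[1L + seq_len(nums[1L])]) + 1L)
      })
      faces <- bind_faces(flist, "PLY face element")
      row <- row + el$count
    } else {
      row <- row + el$count
    }
  }
  triangle_mesh(verts, faces, validate = FALSE)
}

read_ply_binary <- function(con, elems, endian) {
  verts <- NULL
  faces <- NULL
  for (el in elems) {
    if (el$name == "vertex" && !any(vapply(el$props, `[[`, TRUE, "list"))) {
      types <- vapply(el$props, `[[`, "", "type")
      pnames <- vapply(el$props, `[[`, "", "name")
      uniform <- length(unique(types)) == 1L
      if (uniform) {
        info <- ply_type_info(types[1L])
        vals <- readBin(con, info$what, n = el$count * length(types),
                        size = info$size, signed = info$signed,
                        endian = endian)
        vals <- matrix(as.double(vals), nrow = el$count, byrow = TRUE)
      } else {
        vals <- matrix(0, nrow = el$count, ncol = length(types))
        for (i in seq_len(el$count)) {
          for (j in seq_along(types)) {
            info <- ply_type_info(types[j])
            vals[i, j] <- as.double(
              readBin(con, info$what, n = 1L, size = info$size,
                      signed = info$signed, endian = endian))
          }
        }
      }
      verts <- vals[, match(c("x", "y", "z"), pnames), drop = FALSE]
    } else if (el$name == "face") {
      lp <- el$props[[1L]]
      cinfo <- ply_type_info(lp$count_type)
      iinfo <- ply_type_info(lp$type)
      flist <- vector("list", el$count)
      for (i in seq_len(el$count)) {
        k <- readBin(con, cinfo$what, n = 1L, size = cinfo$size,
                     signed = cinfo$signed, endian = endian)
        idx <- readBin(con, iinfo$what, n = k, size = iinfo$size,
                       signed = iinfo$signed, endian = endian)
        flist[[i]] <- fan_triangulate(as.integer(idx) + 1L)
      }
      faces <- bind_faces(flist, "PLY face element")
    } else {
      # skip unknown scalar elements
      for (i in seq_len(el$count)) {
        for (p in el$props) {
          info <- ply_type_info(p$type)
          if (isTRUE(p$list)) {
            cinfo <- ply_type_info(p$count_type)
            k <- readBin(con, cinfo$what, 1L, cinfo$size, cinfo$signed,
                         endian = endian)
            readBin(con, info$what, k, info$size, info$signed, endian = endian)
          } else {
            readBin(con, info$what, 1L, info$size, info$signed,
                    endian = endian)
          }
        }
      }
    }
  }
  triangle_mesh(verts, faces, validate = FALSE)
}

write_ply <- function(mesh, path, binary = FALSE) {
  nv <- nrow(mesh$vertices)
  nf <- nrow(mesh$faces)
  header <- c(
    "ply",
    if (binary) "format binary_little_endian 1.0" else "format ascii 1.0",
    sprintf("element vertex %d", nv),
    "property double x", "property double y", "property double z",
    sprintf("element face %d", nf),
    "property list uchar int vertex_indices",
    "end_header"
  )
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeChar(paste0(paste(header, collapse = "\n"), "\n"), con,
              eos = NULL, useBytes = TRUE)
    writeBin(as.double(t(mesh$vertices)), con, size = 8L, endian = "little")
    f0 <- t(cbind(3L, mesh$faces - 1L))
    for (i in seq_len(nf)) {
      writeBin(as.raw(3L), con)
      writeBin(as.integer(mesh$faces[i, ] - 1L), con, size = 4L,
               endian = "little")
    }
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(header, con)
    writeLines(apply(mesh$vertices, 1L,
                     function(v) paste(format(v, digits = 17),
                                       collapse = " ")), con)
    writeLines(paste(3L, mesh$faces[, 1L] - 1L, mesh$faces[, 2L] - 1L,
                     mesh$faces[, 3L] - 1L), con)
  }
}

read_stl <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!any(grepl("^\\s*solid", lines[1L]))) {
    stop("only ascii STL is supported; file does not start with 'solid'")
  }
  vlines <- grep("^\\s*vertex\\s", lines, value = TRUE)
  coords <- matrix(scan(text = gsub("^\\s*vertex\\s+", "", vlines),
                        quiet = TRUE), ncol = 3L, byrow = TRUE)
  if (nrow(coords) %% 3L != 0L) stop("malformed STL: vertex count not multiple of 3")
  # merge exactly coincident vertices to recover shared-edge topology
  key <- apply(coords, 1L, function(v) paste(format(v, digits = 17),
                                             collapse = ","))
  uniq <- !duplicated(key)
  vmap <- match(key, key[uniq])
  verts <- coords[uniq, , drop = FALSE]
  faces <- matrix(vmap, ncol = 3L, byrow = TRUE)
  triangle_mesh(verts, faces, validate = FALSE)
}

write_stl <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("solid mesh", con)
  v <- mesh$vertices
  f <- mesh$faces
  n <- face_normals(mesh)
  for (i in seq_len(nrow(f))) {
    writeLines(sprintf("  facet normal %s",
                       paste(format(n[i, ], digits = 17), collapse = " ")),
               con)
    writeLines("    outer loop", con)
    for (j in 1:3) {
      writeLines(sprintf("      vertex %s",
                         paste(format(v[f[i, j], ], digits = 17),
                               collapse = " ")), con)
    }
    writeLines("    endloop", con)
    writeLines("  endfacet", con)
  }
  writeLines("endsolid mesh", con)
}

#' Extract a tumor region of interest from a grayscale image
#'
#' Applies the ground-truth mask to the raw image: pixels under the mask
#' foreground are kept, everything else is set to zero. This is the masking
#' (bitwise AND) step that isolates the lesion before any shape analysis.
#'
#' @param image Numeric matrix, the grayscale image.
#' @param mask Numeric matrix of the same dimensions; foreground is any value
#'   greater than zero (0/1 and 0/255 encodings both work).
#' @return A matrix of the same dimensions as `image` with background zeroed.
#' @examples
#' img <- matrix(c(10, 30, 20, 40), 2, 2)
#' extract_roi(img, matrix(c(1, 0, 0, 1), 2, 2))
#' @export
extract_roi <- function(image, mask) {
  image <- as.matrix(image)
  mask <- as.matrix(mask)
  if (!identical(dim(image), dim(mask))) {
    stop("image (", paste(dim(image), collapse = "x"),
         ") and mask (", paste(dim(mask), collapse = "x"),
         ") dimensions differ")
  }
  image * (mask > 0)
}

#' Read / write 8-bit grayscale PNG as a matrix
#'
#' Thin wrappers over the png package. Multi-channel images are collapsed to
#' grayscale by averaging the color channels.
#'
#' @param path PNG file path.
#' @return `read_gray_png()`: a numeric matrix with values in \[0, 1\].
#' @export
read_gray_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) {
    img <- apply(img[, , seq_len(min(3L, dim(img)[3L])), drop = FALSE],
                 c(1L, 2L), mean)
  }
  img
}

#' @rdname read_gray_png
#' @param image Numeric matrix in \[0, 1\].
#' @export
write_gray_png <- function(image, path) {
  png::writePNG(pmin(pmax(image, 0), 1), path)
  invisible(path)
}

# ---- edges, holes, QC --------------------------------------------------------

# All undirected edges of a mesh as a 2-column matrix (lo, hi), one row per
# face-edge occurrence.
face_edges <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1L, 2L)], f[, c(2L, 3L)], f[, c(3L, 1L)])
  cbind(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
}

edge_face_count <- function(mesh) {
  e <- face_edges(mesh)
  key <- paste(e[, 1L], e[, 2L])
  tab <- table(key)
  list(total = length(tab), counts = as.integer(tab))
}

#' Quantify mesh holes as the boundary-edge fraction
#'
#' A boundary edge belongs to exactly one triangle and is the discrete
#' signature of a hole in the surface. The hole percentage of a mesh is
#' `100 * boundary_edges / total_edges`; a watertight mesh scores 0. Meshes
#' whose hole percentage exceeds the threshold fail quality control
#' (strictly greater than: a mesh at exactly the threshold passes).
#'
#' @param mesh A [triangle_mesh()].
#' @param threshold Hole percentage above which the mesh fails QC. Default 10.
#' @return An object of class `mesh_qc_report`: list with `total_edges`,
#'   `boundary_edges`, `hole_percentage`, `passed`, `threshold`.
#' @examples
#' tri <- triangle_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
#'                      matrix(c(1, 2, 3), 1))
#' hole_report(tri)  # a lone triangle is 100% boundary
#' @export
hole_report <- function(mesh, threshold = 10) {
  validate_mesh(mesh)
  ec <- edge_face_count(mesh)
  boundary <- sum(ec$counts == 1L)
  pct <- 100 * boundary / ec$total
  structure(list(total_edges = ec$total,
                 boundary_edges = boundary,
                 hole_percentage = pct,
                 passed = pct <= threshold,
                 threshold = threshold),
            class = "mesh_qc_report")
}

#' @export
print.mesh_qc_report <- function(x, ...) {
  cat(sprintf("mesh QC: %d/%d boundary edges (%.2f%% holes) -> %s (threshold %g%%)\n",
              x$boundary_edges, x$total_edges, x$hole_percentage,
              if (x$passed) "PASS" else "FAIL", x$threshold))
  invisible(x)
}

#' Filter a batch of meshes on hole percentage
#'
#' Retains meshes whose hole percentage is at most `threshold` percent and
#' excludes the rest ("more than `threshold` percent compromised"). Every
#' excluded mesh is logged with its hole percentage.
#'
#' @param meshes List of [triangle_mesh()] objects, optionally named.
#' @param threshold Hole percentage cutoff in \[0, 100\]. Default 10.
#' @param quiet Suppress the per-exclusion messages.
#' @return List with `retained` and `excluded` (both lists of meshes) and
#'   `reports`, a data.frame with one row per input mesh
#'   (`mesh_id`, `total_edges`, `boundary_edges`, `hole_percentage`, `passed`).
#' @export
qc_filter <- function(meshes, threshold = 10, quiet = FALSE) {
  stopifnot(threshold >= 0, threshold <= 100)
  if (length(meshes) == 0L) {
    return(list(retained = list(), excluded = list(),
                reports = data.frame(mesh_id = character(),
                                     total_edges = integer(),
                                     boundary_edges = integer(),
                                     hole_percentage = double(),
                                     passed = logical())))
  }
  ids <- names(meshes)
  if (is.null(ids)) ids <- as.character(seq_along(meshes))
  reps <- lapply(meshes, hole_report, threshold = threshold)
  passed <- vapply(reps, `[[`, TRUE, "passed")
  reports <- data.frame(
    mesh_id = ids,
    total_edges = vapply(reps, `[[`, 1L, "total_edges"),
    boundary_edges = vapply(reps, `[[`, 1L, "boundary_edges"),
    hole_percentage = vapply(reps, `[[`, 1.0, "hole_percentage"),
    passed = passed,
    row.names = NULL
  )
  if (!quiet && any(!passed)) {
    for (i in which(!passed)) {
      message(sprintf("qc_filter: excluding mesh '%s' (%.2f%% holes)",
                      ids[i], reports$hole_percentage[i]))
    }
  }
  list(retained = meshes[passed], excluded = meshes[!passed],
       reports = reports)
}
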