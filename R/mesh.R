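#' Triangle mesh of one anatomical structure
#'
#' Container for a named triangle mesh in world millimetre coordinates with a
#' criticality flag. Faces with (near-)zero area are removed at construction;
#' the tolerance is 1e-12 mm^2, so every retained triangle has a well-defined
#' plane for distance queries.
#'
#' @param vertices numeric matrix, one vertex per row (x, y, z in mm).
#' @param faces integer matrix, one triangle per row, 1-based vertex indices.
#' @param name structure name.
#' @param label integer label the structure carries in a label volume, or `NA`.
#' @param critical logical; is the structure a collision obstacle for the drill?
#' @return An object of class `structure_mesh` with fields `name`, `label`,
#'   `critical`, `vertices`, `faces`.
#' @export
structure_mesh <- function(vertices, faces, name = "structure",
                           label = NA_integer_, critical = FALSE) {
  vertices <- matrix(as.numeric(vertices), ncol = 3)
  faces <- matrix(as.integer(faces), ncol = 3)
  if (nrow(vertices) > 0 && any(!is.finite(vertices)))
    stop("mesh vertices must be finite")
  if (nrow(faces) > 0) {
    if (min(faces) < 1L || max(faces) > nrow(vertices))
      stop("face indices out of range")
    rep_ok <- faces[, 1] != faces[, 2] & faces[, 1] != faces[, 3] &
      faces[, 2] != faces[, 3]
    faces <- faces[rep_ok, , drop = FALSE]
    areas <- .triangle_areas(vertices, faces)
    faces <- faces[areas > 1e-12, , drop = FALSE]
  }
  structure(list(name = as.character(name), label = as.integer(label),
                 critical = isTRUE(critical), vertices = vertices,
                 faces = faces, cache = new.env(parent = emptyenv())),
            class = "structure_mesh")
}

.triangle_areas <- function(vertices, faces) {
  if (nrow(faces) == 0) return(numeric(0))
  a <- vertices[faces[, 1], , drop = FALSE]
  u <- vertices[faces[, 2], , drop = FALSE] - a
  w <- vertices[faces[, 3], , drop = FALSE] - a
  cx <- u[, 2] * w[, 3] - u[, 3] * w[, 2]
  cy <- u[, 3] * w[, 1] - u[, 1] * w[, 3]
  cz <- u[, 1] * w[, 2] - u[, 2] * w[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

#' Total surface area of a mesh
#' @param mesh a [structure_mesh()].
#' @return area in mm^2.
#' @export
mesh_area <- function(mesh) sum(.triangle_areas(mesh$vertices, mesh$faces))

#' Triangle centroids of a mesh
#' @param mesh a [structure_mesh()].
#' @return numeric matrix, one centroid per face (mm).
#' @export
mesh_centroids <- function(mesh) {
  (mesh$vertices[mesh$faces[, 1], , drop = FALSE] +
     mesh$vertices[mesh$faces[, 2], , drop = FALSE] +
     mesh$vertices[mesh$faces[, 3], , drop = FALSE]) / 3
}

# Undirected edge table: k x 2 matrix of sorted vertex-index pairs, one row
# per face edge (3 per face, with multiplicity).
.mesh_edges <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
}

#' Is a mesh closed (watertight)?
#'
#' A mesh is closed when every undirected edge is shared by exactly two
#' faces. Closedness is what makes inside/outside containment queries
#' well-defined; surfaces extracted by [extract_surface()] are closed by
#' construction (boundary padding).
#'
#' @param mesh a [structure_mesh()].
#' @return logical.
#' @export
mesh_is_closed <- function(mesh) {
  if (nrow(mesh$faces) == 0) return(FALSE)
  cached <- mesh$cache$closed
  if (!is.null(cached)) return(cached)
  e <- .mesh_edges(mesh)
  counts <- table(paste(e[, 1], e[, 2]))
  closed <- all(counts == 2L)
  mesh$cache$closed <- closed
  closed
}

# Build (or fetch the cached) spatial index over the mesh triangles.
.mesh_bvh <- function(mesh) {
  b <- mesh$cache$bvh
  if (is.null(b)) {
    b <- cpp_bvh_build(mesh$vertices, mesh$faces - 1L)
    mesh$cache$bvh <- b
  }
  b
}

#' @export
print.structure_mesh <- function(x, ...) {
  cat(sprintf("<structure_mesh> %s%s: %d vertices, %d faces%s\n",
              x$name,
              if (is.na(x$label)) "" else sprintf(" (label %d)", x$label),
              nrow(x$vertices), nrow(x$faces),
              if (x$critical) ", critical" else ""))
  invisible(x)
}

# ---------------------------------------------------------------------------
# STL / PLY input-output
# ---------------------------------------------------------------------------

#' Write a mesh to STL
#'
#' Binary little-endian STL by default (the de-facto interchange format for
#' surgical planning meshes); `ascii = TRUE` writes the text dialect. STL
#' stores a triangle soup: vertex connectivity is recovered on read by exact
#' coordinate matching.
#'
#' @param mesh a [structure_mesh()].
#' @param path output path.
#' @param ascii write ASCII STL instead of binary.
#' @return `path`, invisibly.
#' @export
write_stl <- function(mesh, path, ascii = FALSE) {
  v <- mesh$vertices
  f <- mesh$faces
  p1 <- v[f[, 1], , drop = FALSE]
  p2 <- v[f[, 2], , drop = FALSE]
  p3 <- v[f[, 3], , drop = FALSE]
  u <- p2 - p1; w <- p3 - p1
  n <- cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
             u[, 3] * w[, 1] - u[, 1] * w[, 3],
             u[, 1] * w[, 2] - u[, 2] * w[, 1])
  len <- sqrt(rowSums(n^2))
  len[len == 0] <- 1
  n <- n / len
  m <- nrow(f)
  if (ascii) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("solid %s", mesh$name), con)
    if (m > 0) {
      block <- sprintf(
        "facet normal %.9g %.9g %.9g\nouter loop\nvertex %.9g %.9g %.9g\nvertex %.9g %.9g %.9g\nvertex %.9g %.9g %.9g\nendloop\nendfacet",
        n[, 1], n[, 2], n[, 3],
        p1[, 1], p1[, 2], p1[, 3],
        p2[, 1], p2[, 2], p2[, 3],
        p3[, 1], p3[, 2], p3[, 3])
      writeLines(block, con)
    }
    writeLines(sprintf("endsolid %s", mesh$name), con)
    return(invisible(path))
  }
  con <- file(path, "wb")
  on.exit(close(con))
  header <- charToRaw(sprintf("%-80s", paste("multiport mesh", mesh$name)))[1:80]
  writeBin(header, con)
  writeBin(as.integer(m), con, size = 4, endian = "little")
  if (m > 0) {
    # 12 float32 per facet (normal + 3 vertices) + 2 attribute bytes
    dat <- t(cbind(n, p1, p2, p3)) # 12 x m
    fl <- writeBin(as.numeric(dat), raw(), size = 4, endian = "little")
    dim(fl) <- c(48L, m)
    rec <- rbind(fl, matrix(as.raw(0), 2L, m))
    writeBin(as.vector(rec), con)
  }
  invisible(path)
}

#' Read a mesh from STL (binary or ASCII)
#'
#' @param path STL file.
#' @inheritParams structure_mesh
#' @return a [structure_mesh()].
#' @export
read_stl <- function(path, name = NULL, label = NA_integer_, critical = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(name)) name <- sub("\\.[sS][tT][lL]$", "", basename(path))
  sz <- file.info(path)$size
  is_binary <- FALSE
  if (sz >= 84) {
    con <- file(path, "rb")
    invisible(readBin(con, "raw", 80))
    m <- readBin(con, "integer", 1, size = 4, endian = "little")
    close(con)
    if (!is.na(m) && sz == 84 + 50 * m) is_binary <- TRUE
  }
  if (is_binary) {
    con <- file(path, "rb")
    on.exit(close(con))
    invisible(readBin(con, "raw", 80))
    m <- readBin(con, "integer", 1, size = 4, endian = "little")
    rec <- readBin(con, "raw", 50 * m)
    dim(rec) <- c(50L, m)
    fl <- readBin(as.vector(rec[1:48, , drop = FALSE]), "numeric",
                  12 * m, size = 4, endian = "little")
    dim(fl) <- c(12L, m)
    tri <- t(fl[4:12, , drop = FALSE]) # m x 9, vertices only
  } else {
    lines <- readLines(path, warn = FALSE)
    vl <- grep("^\\s*vertex", lines, value = TRUE)
    nums <- lapply(strsplit(trimws(vl), "\\s+"),
                   function(x) as.numeric(x[2:4]))
    pts <- do.call(rbind, nums)
    if (is.null(pts) || nrow(pts) %% 3 != 0) stop("malformed ASCII STL")
    m <- nrow(pts) / 3
    tri <- cbind(pts[seq(1, by = 3, length.out = m), , drop = FALSE],
                 pts[seq(2, by = 3, length.out = m), , drop = FALSE],
                 pts[seq(3, by = 3, length.out = m), , drop = FALSE])
  }
  pts <- rbind(tri[, 1:3, drop = FALSE], tri[, 4:6, drop = FALSE],
               tri[, 7:9, drop = FALSE])
  key <- paste(pts[, 1], pts[, 2], pts[, 3])
  uid <- !duplicated(key)
  verts <- pts[uid, , drop = FALSE]
  idx <- match(key, key[uid])
  m <- nrow(tri)
  faces <- cbind(idx[seq_len(m)], idx[m + seq_len(m)], idx[2 * m + seq_len(m)])
  structure_mesh(verts, faces, name = name, label = label, critical = critical)
}

#' Write a mesh to ASCII PLY
#'
#' Full double precision (`%.17g`), so a write/read round trip is exact.
#'
#' @inheritParams write_stl
#' @return `path`, invisibly.
#' @export
write_ply <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  v <- mesh$vertices
  f <- mesh$faces - 1L
  writeLines(c("ply", "format ascii 1.0",
               sprintf("comment multiport mesh %s", mesh$name),
               sprintf("element vertex %d", nrow(v)),
               "property double x", "property double y", "property double z",
               sprintf("element face %d", nrow(f)),
               "property list uchar int vertex_indices", "end_header"), con)
  if (nrow(v) > 0)
    writeLines(sprintf("%.17g %.17g %.17g", v[, 1], v[, 2], v[, 3]), con)
  if (nrow(f) > 0)
    writeLines(sprintf("3 %d %d %d", f[, 1], f[, 2], f[, 3]), con)
  invisible(path)
}

#' Read an ASCII PLY mesh
#' @inheritParams read_stl
#' @return a [structure_mesh()].
#' @export
read_ply <- function(path, name = NULL, label = NA_integer_, critical = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(name)) name <- sub("\\.[pP][lL][yY]$", "", basename(path))
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0 || trimws(lines[1]) != "ply") stop("not a PLY file")
  hdr_end <- which(trimws(lines) == "end_header")[1]
  if (is.na(hdr_end)) stop("malformed PLY header")
  hdr <- lines[seq_len(hdr_end)]
  nv <- as.integer(sub(".*element vertex\\s+", "", grep("element vertex", hdr, value = TRUE)[1]))
  nf <- as.integer(sub(".*element face\\s+", "", grep("element face", hdr, value = TRUE)[1]))
  body <- lines[(hdr_end + 1):length(lines)]
  vrows <- strsplit(trimws(body[seq_len(nv)]), "\\s+")
  verts <- do.call(rbind, lapply(vrows, function(x) as.numeric(x[1:3])))
  frows <- strsplit(trimws(body[nv + seq_len(nf)]), "\\s+")
  faces <- do.call(rbind, lapply(frows, function(x) as.integer(x[2:4]) + 1L))
  structure_mesh(verts, faces, name = name, label = label, critical = critical)
}

#' Closed cylinder mesh around a drill axis
#'
#' Used for exporting planned trajectories as STL for inspection in any mesh
#' viewer.
#'
#' @param a,b axis endpoints (mm).
#' @param radius cylinder radius (mm).
#' @param n number of circumferential facets.
#' @param name mesh name.
#' @return a [structure_mesh()].
#' @export
cylinder_mesh <- function(a, b, radius, n = 24, name = "cylinder") {
  axis <- b - a
  len <- sqrt(sum(axis^2))
  if (len <= 0) stop("degenerate cylinder axis")
  w <- axis / len
  u <- .orthonormal_to(w)
  v <- .cross3(w, u)
  th <- 2 * pi * (seq_len(n) - 1) / n
  ring <- outer(cos(th), u) * radius + outer(sin(th), v) * radius
  bot <- sweep(ring, 2, a, "+")
  top <- sweep(ring, 2, b, "+")
  verts <- rbind(bot, top, a, b)
  ia <- 2 * n + 1; ib <- 2 * n + 2
  nxt <- c(seq_len(n)[-1], 1L)
  side1 <- cbind(seq_len(n), nxt, n + seq_len(n))
  side2 <- cbind(nxt, n + nxt, n + seq_len(n))
  capa <- cbind(ia, nxt, seq_len(n))
  capb <- cbind(ib, n + seq_len(n), n + nxt)
  structure_mesh(verts, rbind(side1, side2, capa, capb), name = name)
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
}

.orthonormal_to <- function(w) {
  ref <- if (abs(w[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- .cross3(w, ref)
  u / sqrt(sum(u^2))
}
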