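#' Drill-axis segment
#'
#' @param a entry-side endpoint (mm).
#' @param b target-side endpoint (mm).
#' @return An object of class `segment` with fields `a`, `b`, `length`.
#' @export
segment <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != 3 || length(b) != 3 || any(!is.finite(c(a, b))))
    stop("segment endpoints must be finite 3-vectors")
  len <- sqrt(sum((b - a)^2))
  if (len <= 0) stop("degenerate segment: |b - a| must be > 0")
  structure(list(a = a, b = b, length = len), class = "segment")
}

#' @export
print.segment <- function(x, ...) {
  cat(sprintf("<segment> (%.3g, %.3g, %.3g) -> (%.3g, %.3g, %.3g), %.3g mm\n",
              x$a[1], x$a[2], x$a[3], x$b[1], x$b[2], x$b[3], x$length))
  invisible(x)
}

.as_segment <- function(seg) {
  if (!inherits(seg, "segment")) stop("expected a segment object")
  seg
}

#' Point-to-segment distance
#'
#' Euclidean distance from a point to the closest point of the closed
#' segment (the perpendicular foot when interior, otherwise the nearer
#' endpoint).
#'
#' @param p point (mm).
#' @param seg a [segment()].
#' @return distance in mm.
#' @export
point_segment_distance <- function(p, seg) {
  seg <- .as_segment(seg)
  p <- as.numeric(p)
  if (length(p) != 3 || any(!is.finite(p))) stop("p must be a finite 3-vector")
  cpp_point_segment_distance(p, seg$a, seg$b)
}

#' Segment-to-triangle distance
#'
#' Minimum Euclidean distance between a closed segment and a closed
#' triangle; 0 when they intersect.
#'
#' @param seg a [segment()].
#' @param tri 3 x 3 numeric matrix, one triangle vertex per row (mm).
#' @return distance in mm.
#' @export
segment_triangle_distance <- function(seg, tri) {
  seg <- .as_segment(seg)
  tri <- matrix(as.numeric(tri), 3, 3)
  if (any(!is.finite(tri))) stop("triangle vertices must be finite")
  if (.triangle_areas(tri, matrix(1:3, 1)) <= 1e-12)
    stop("degenerate triangle")
  cpp_segment_triangle(seg$a, seg$b, tri[1, ], tri[2, ], tri[3, ])$distance
}

.clearance_result <- function(distance, structure_name, triangle_index,
                              point_axis, point_mesh) {
  structure(list(distance = distance,
                 structure_name = structure_name,
                 triangle_index = triangle_index,
                 closest_point_on_axis = point_axis,
                 closest_point_on_mesh = point_mesh),
            class = "clearance_result")
}

#' @export
print.clearance_result <- function(x, ...) {
  cat(sprintf("<clearance> %.6g mm to %s (triangle %s)\n",
              x$distance, x$structure_name,
              ifelse(is.na(x$triangle_index), "-", x$triangle_index)))
  invisible(x)
}

#' Minimum distance from a drill axis to a structure mesh
#'
#' Minimum over all mesh triangles of the segment-triangle distance, with the
#' argmin triangle and the witness points on axis and mesh. The accelerated
#' method uses a bounding-volume hierarchy over the triangles and returns
#' distances identical to the exhaustive scan (the pruning bound is exact, so
#' no triangle that could attain the minimum is skipped).
#'
#' Note that for a segment lying entirely *inside* a closed mesh this is the
#' distance to the wall, not zero; containment is the business of
#' [capsule_is_free()].
#'
#' @param seg a [segment()].
#' @param mesh a non-empty [structure_mesh()].
#' @param method `"accelerated"` (default) or `"brute"`.
#' @return a `clearance_result` with fields `distance` (mm),
#'   `structure_name`, `triangle_index`, `closest_point_on_axis`,
#'   `closest_point_on_mesh`.
#' @export
mesh_clearance <- function(seg, mesh, method = c("accelerated", "brute")) {
  seg <- .as_segment(seg)
  method <- match.arg(method)
  stopifnot(inherits(mesh, "structure_mesh"))
  if (nrow(mesh$faces) == 0)
    stop("mesh_clearance on an empty mesh; handle 'no critical structures' explicitly")
  res <- if (method == "brute") {
    cpp_mesh_clearance_brute(seg$a, seg$b, mesh$vertices, mesh$faces - 1L)
  } else {
    cpp_bvh_clearance(.mesh_bvh(mesh), seg$a, seg$b)
  }
  .clearance_result(res$distance, mesh$name, res$triangle,
                    res$point_axis, res$point_mesh)
}

#' Is a drill capsule free of all critical structures?
#'
#' A capsule of radius `radius` around the segment is collision-free iff the
#' minimum axis clearance over all meshes is `>= radius` (non-strict, so
#' grazing contact at exactly the required clearance passes) and the axis is
#' not contained in any closed mesh. Containment is decided by ray-parity
#' tests at the entry, target and midpoint of the axis, which also rejects a
#' piercing axis in the degenerate `radius = 0` case. For a non-watertight
#' mesh the containment test is skipped with a warning and only the triangle
#' distance is used.
#'
#' @param seg a [segment()].
#' @param radius required clearance radius (mm, >= 0).
#' @param meshes list of [structure_mesh()] obstacles. An empty list is free
#'   with an infinite clearance sentinel.
#' @return list with `free` (logical), `clearance` (mm; `Inf` sentinel when
#'   `meshes` is empty), `contained` (logical), and `result` (the limiting
#'   `clearance_result`, or `NULL` when `meshes` is empty).
#' @export
capsule_is_free <- function(seg, radius, meshes) {
  seg <- .as_segment(seg)
  if (!is.numeric(radius) || length(radius) != 1 || is.na(radius) || radius < 0)
    stop("radius must be a single non-negative number")
  if (inherits(meshes, "structure_mesh")) meshes <- list(meshes)
  if (length(meshes) == 0)
    return(list(free = TRUE, clearance = Inf, contained = FALSE, result = NULL))
  best <- NULL
  contained <- FALSE
  probe <- rbind(seg$a, seg$b, (seg$a + seg$b) / 2)
  for (mesh in meshes) {
    if (nrow(mesh$faces) == 0) next
    res <- mesh_clearance(seg, mesh)
    if (is.null(best) || res$distance < best$distance) best <- res
    if (!contained) {
      if (mesh_is_closed(mesh)) {
        inside <- cpp_points_in_mesh(probe, mesh$vertices, mesh$faces - 1L)
        if (any(inside)) contained <- TRUE
      } else {
        warning("mesh '", mesh$name,
                "' is not watertight; axis containment test skipped",
                call. = FALSE)
      }
    }
  }
  if (is.null(best))
    return(list(free = TRUE, clearance = Inf, contained = FALSE, result = NULL))
  list(free = (best$distance >= radius) && !contained,
       clearance = best$distance, contained = contained, result = best)
}
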