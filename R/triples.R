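#' Angle between two trajectories sharing a target
#'
#' The angle between the target-to-entry unit direction vectors, in degrees
#' in \[0, 180\], computed as `atan2(|u x v|, u . v)` (the numerically
#' stable form of the clamped arccos, exact at 0 and 180 degrees). With this
#' convention, ports that spread apart on the skull have large angles.
#'
#' @param t1,t2 `trajectory` objects sharing the same target (within 1e-6 mm).
#' @return angle in degrees.
#' @export
pairwise_angle <- function(t1, t2) {
  stopifnot(inherits(t1, "trajectory"), inherits(t2, "trajectory"))
  if (sqrt(sum((t1$target - t2$target)^2)) > 1e-6)
    stop("trajectories do not share a target")
  u <- t1$direction; v <- t2$direction
  atan2(sqrt(sum(.cross3(u, v)^2)), sum(u * v)) * 180 / pi
}

#' Cumulative angle of a trajectory triple
#'
#' Sum of the three pairwise angles (degrees) between a triple of
#' trajectories sharing one target; the benchmark for how far apart the
#' three ports are spread (larger is better, maximum 540).
#'
#' @param x a `trajectory_triple` or a list of three `trajectory` objects.
#' @return cumulative angle in degrees.
#' @export
cumulative_angle <- function(x) {
  if (inherits(x, "trajectory_triple")) return(sum(x$angles))
  stopifnot(is.list(x), length(x) == 3)
  pairwise_angle(x[[1]], x[[2]]) + pairwise_angle(x[[1]], x[[3]]) +
    pairwise_angle(x[[2]], x[[3]])
}

#' Fused-canal (merge) length of two drill cylinders
#'
#' Two cylinders of radii `r1`, `r2` meeting at the shared target with angle
#' `alpha` overlap out to distance `L = (r1 + r2) / (2 sin(alpha / 2))` from
#' the target along each axis. Small `L` means a distal intersection (the
#' canals fuse only near the target, creating working space); large `L`
#' means a proximal fusion that collapses the ports.
#'
#' @param t1,t2 `trajectory` objects sharing a target.
#' @param r1,r2 cylinder radii in mm.
#' @return merge length in mm; `Inf` for parallel axes (`alpha = 0`), where
#'   the overlap never ends.
#' @export
merge_length <- function(t1, t2, r1, r2) {
  merge_length_angle(pairwise_angle(t1, t2), r1, r2)
}

#' @rdname merge_length
#' @param alpha_deg inter-axis angle in degrees.
#' @export
merge_length_angle <- function(alpha_deg, r1, r2) {
  if (r1 <= 0 || r2 <= 0) stop("radii must be > 0")
  if (alpha_deg < 0 || alpha_deg > 180) stop("alpha must be in [0, 180]")
  if (alpha_deg == 0) return(Inf)
  (r1 + r2) / (2 * sin(alpha_deg * pi / 360))
}

#' Three-port trajectory triple
#'
#' Bundles three trajectories sharing one target with their pairwise angles
#' (pairs 1-2, 1-3, 2-3), cumulative angle, and pairwise merge lengths at
#' the drill radius.
#'
#' @param t1,t2,t3 `trajectory` objects sharing one target.
#' @param drill_radius drill radius used for the merge lengths (mm).
#' @return An object of class `trajectory_triple`.
#' @export
trajectory_triple <- function(t1, t2, t3, drill_radius = 0.5) {
  angles <- c(a12 = pairwise_angle(t1, t2),
              a13 = pairwise_angle(t1, t3),
              a23 = pairwise_angle(t2, t3))
  merges <- vapply(angles, merge_length_angle, numeric(1),
                   r1 = drill_radius, r2 = drill_radius)
  names(merges) <- c("m12", "m13", "m23")
  structure(list(trajectories = list(t1, t2, t3),
                 angles = angles,
                 cumulative_angle = sum(angles),
                 merge_lengths = merges,
                 drill_radius = drill_radius,
                 score = NA_real_),
            class = "trajectory_triple")
}

#' @export
print.trajectory_triple <- function(x, ...) {
  cat(sprintf(
    "<trajectory_triple> CA %.1f deg (angles %.1f / %.1f / %.1f)\n  merge lengths %.2f / %.2f / %.2f mm, min clearance %.2f mm%s\n",
    x$cumulative_angle, x$angles[1], x$angles[2], x$angles[3],
    x$merge_lengths[1], x$merge_lengths[2], x$merge_lengths[3],
    min(vapply(x$trajectories, `[[`, numeric(1), "clearance")),
    if (is.na(x$score)) "" else sprintf(", score %.4f", x$score)))
  invisible(x)
}

#' Score a trajectory triple
#'
#' Weighted two-term score implementing the two selection criteria of the
#' planning protocol: maximise the distance of each path to the critical
#' structures, and maximise the spread between the entry points (the
#' cumulative angle). `score = w_clearance * (min clearance / clearance_norm)
#' + w_angle * (CA / 540)`; higher is better.
#'
#' @param triple a [trajectory_triple()].
#' @param w_clearance,w_angle non-negative weights, not both zero.
#' @param clearance_norm normalising clearance (mm); by default the maximum
#'   clearance within the triple, and [select_best_triple()] passes the
#'   maximum over the whole candidate set.
#' @return scalar score.
#' @export
score_triple <- function(triple, w_clearance = 1, w_angle = 1,
                         clearance_norm = NULL) {
  stopifnot(inherits(triple, "trajectory_triple"))
  if (w_clearance < 0 || w_angle < 0 || (w_clearance == 0 && w_angle == 0))
    stop("weights must be >= 0 and not both zero")
  cl <- vapply(triple$trajectories, `[[`, numeric(1), "clearance")
  if (is.null(clearance_norm)) clearance_norm <- max(cl)
  term_c <- if (!is.finite(clearance_norm) || clearance_norm <= 0) {
    # degenerate: all clearances infinite (no critical structures) or zero
    if (min(cl) == clearance_norm) 1 else 0
  } else {
    min(cl) / clearance_norm
  }
  w_clearance * term_c + w_angle * (triple$cumulative_angle / 540)
}

#' Select the best three-port set
#'
#' Exhaustive search over all triples of the `m_cap` highest-clearance CFTs,
#' maximising [score_triple()]. Ties are broken by larger cumulative angle,
#' then by lexicographic entry coordinates, so the result does not depend on
#' the input ordering.
#'
#' @param cfts list of feasible `trajectory` objects (a `trajectory_set`
#'   works); at least three are required.
#' @param w_clearance,w_angle score weights (see [score_triple()]).
#' @param m_cap candidate cap: only the `m_cap` highest-clearance CFTs enter
#'   the exhaustive search (default 40); `Inf` disables the cap and
#'   reproduces full brute force.
#' @param drill_radius drill radius for the triple's merge lengths (mm);
#'   defaults to the attached config's, if any, else 0.5.
#' @return the best-scoring [trajectory_triple()], with `score` set.
#' @export
select_best_triple <- function(cfts, w_clearance = 1, w_angle = 1,
                               m_cap = 40, drill_radius = NULL) {
  cfg <- attr(cfts, "config")
  if (is.null(drill_radius))
    drill_radius <- if (!is.null(cfg)) cfg$drill_radius else 0.5
  cfts <- unclass(cfts)
  if (length(cfts) < 3)
    stop(errorCondition(
      sprintf("need at least 3 collision-free trajectories, got %d",
              length(cfts)),
      class = c("multiport_insufficient_cft_error", "multiport_error")))
  cl <- vapply(cfts, `[[`, numeric(1), "clearance")
  ent <- t(vapply(cfts, `[[`, numeric(3), "entry"))
  # canonical order: clearance desc, then entry lexicographic
  ord <- order(-cl, ent[, 1], ent[, 2], ent[, 3])
  keep <- ord[seq_len(min(length(ord), m_cap))]
  cfts <- cfts[keep]
  cl <- cl[keep]
  norm <- max(cl)
  combs <- combn(length(cfts), 3)
  best <- NULL; best_score <- -Inf; best_ca <- -Inf; best_key <- NULL
  for (j in seq_len(ncol(combs))) {
    idx <- combs[, j]
    tr <- trajectory_triple(cfts[[idx[1]]], cfts[[idx[2]]], cfts[[idx[3]]],
                            drill_radius = drill_radius)
    sc <- score_triple(tr, w_clearance, w_angle, clearance_norm = norm)
    key <- as.vector(t(.canonical_entries(tr)))
    better <- if (sc != best_score) {
      sc > best_score
    } else if (tr$cumulative_angle != best_ca) {
      tr$cumulative_angle > best_ca
    } else {
      .lex_less(key, best_key)
    }
    if (better) {
      best <- tr; best_score <- sc; best_ca <- tr$cumulative_angle
      best_key <- key
    }
  }
  best$score <- best_score
  best
}

.canonical_entries <- function(triple) {
  ent <- t(vapply(triple$trajectories, `[[`, numeric(3), "entry"))
  ent[order(ent[, 1], ent[, 2], ent[, 3]), , drop = FALSE]
}

.lex_less <- function(a, b) {
  for (i in seq_along(a)) {
    if (a[i] < b[i]) return(TRUE)
    if (a[i] > b[i]) return(FALSE)
  }
  FALSE
}
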