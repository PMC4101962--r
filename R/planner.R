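#' Planning configuration for one target
#'
#' Bundles the geometric margins of the drilling model. The clearance a
#' trajectory must reach before it is declared collision-free is the single
#' derived quantity `drill_radius + safety_distance + drill_inaccuracy`
#' ([required_clearance()]); it is used identically everywhere.
#'
#' @param target target point (mm).
#' @param entry_seed seed point for the entry region (mm); it is snapped to
#'   the nearest skull triangle centroid.
#' @param entry_region_radius radius rho (mm) of the candidate entry region
#'   around the snapped seed.
#' @param drill_radius drill radius r_d in mm (> 0; default 0.5, i.e. the
#'   1 mm drill diameter used throughout the planning protocol).
#' @param safety_distance minimum safety distance s to critical structures
#'   (mm, >= 0).
#' @param drill_inaccuracy expected drill/navigation inaccuracy e (mm, >= 0).
#' @param noncritical_names names of structures to exclude from the critical
#'   set for this target (the target structure itself, and e.g. the ossicles
#'   when residual hearing is not relevant).
#' @return An object of class `plan_config`.
#' @export
plan_config <- function(target, entry_seed, entry_region_radius,
                        drill_radius = 0.5, safety_distance = 0,
                        drill_inaccuracy = 0,
                        noncritical_names = character()) {
  target <- as.numeric(target); entry_seed <- as.numeric(entry_seed)
  if (length(target) != 3 || any(!is.finite(target))) stop("invalid target")
  if (length(entry_seed) != 3 || any(!is.finite(entry_seed)))
    stop("invalid entry_seed")
  if (drill_radius <= 0) stop("drill_radius must be > 0")
  if (safety_distance < 0) stop("safety_distance must be >= 0")
  if (drill_inaccuracy < 0) stop("drill_inaccuracy must be >= 0")
  if (entry_region_radius < 0) stop("entry_region_radius must be >= 0")
  structure(list(target = target, entry_seed = entry_seed,
                 entry_region_radius = as.numeric(entry_region_radius),
                 drill_radius = as.numeric(drill_radius),
                 safety_distance = as.numeric(safety_distance),
                 drill_inaccuracy = as.numeric(drill_inaccuracy),
                 noncritical_names = as.character(noncritical_names)),
            class = "plan_config")
}

#' Required axis clearance of a configuration
#' @param config a [plan_config()].
#' @return `drill_radius + safety_distance + drill_inaccuracy`, in mm.
#' @export
required_clearance <- function(config) {
  stopifnot(inherits(config, "plan_config"))
  config$drill_radius + config$safety_distance + config$drill_inaccuracy
}

#' @export
print.plan_config <- function(x, ...) {
  cat(sprintf(
    "<plan_config> target (%.1f, %.1f, %.1f) mm, rho %.1f mm\n  r_d %.2f + s %.2f + e %.2f => required clearance %.2f mm\n",
    x$target[1], x$target[2], x$target[3], x$entry_region_radius,
    x$drill_radius, x$safety_distance, x$drill_inaccuracy,
    required_clearance(x)))
  if (length(x$noncritical_names))
    cat("  noncritical:", paste(x$noncritical_names, collapse = ", "), "\n")
  invisible(x)
}

#' Candidate entry points on the skull surface
#'
#' All triangle centroids of the skull mesh within Euclidean distance `rho`
#' of the seed, after the seed has been snapped to its nearest centroid. The
#' result always contains at least the snapped centroid and is ordered by
#' distance to the snapped seed (ties by triangle index), so downstream
#' output is byte-stable.
#'
#' @param skull non-empty skull [structure_mesh()].
#' @param seed seed point (mm).
#' @param rho entry-region radius (mm, >= 0).
#' @return numeric matrix of candidate points (one per row), with attributes
#'   `face_index` (skull triangle of each candidate) and `snapped_seed`.
#' @export
candidate_entries <- function(skull, seed, rho) {
  stopifnot(inherits(skull, "structure_mesh"))
  if (nrow(skull$faces) == 0) stop("empty skull mesh")
  seed <- as.numeric(seed)
  cent <- mesh_centroids(skull)
  d_seed <- sqrt((cent[, 1] - seed[1])^2 + (cent[, 2] - seed[2])^2 +
                   (cent[, 3] - seed[3])^2)
  snap <- which.min(d_seed) # first minimum = lowest index on ties
  snapped <- cent[snap, ]
  d <- sqrt((cent[, 1] - snapped[1])^2 + (cent[, 2] - snapped[2])^2 +
              (cent[, 3] - snapped[3])^2)
  sel <- which(d <= rho)
  if (!(snap %in% sel)) sel <- c(snap, sel)
  ord <- sel[order(d[sel], sel)]
  out <- cent[ord, , drop = FALSE]
  attr(out, "face_index") <- ord
  attr(out, "snapped_seed") <- snapped
  out
}

.trajectory <- function(entry, config, clearance, closest_structure,
                        contained, face_index = NA_integer_) {
  len <- sqrt(sum((entry - config$target)^2))
  req <- required_clearance(config)
  eff <- if (contained) 0 else clearance
  s_e <- config$safety_distance + config$drill_inaccuracy
  structure(list(
    entry = as.numeric(entry),
    target = config$target,
    direction = (entry - config$target) / len, # target -> entry convention
    length = len,
    clearance = eff,
    closest_structure = closest_structure,
    feasible = (eff >= req) && !contained,
    max_diameter = if (is.infinite(eff)) Inf else max(0, 2 * (eff - s_e)),
    risk_value = NA_real_,
    face_index = as.integer(face_index)),
    class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf(
    "<trajectory> length %.1f mm, clearance %s mm (%s), max diameter %s mm, %s\n",
    x$length, format(x$clearance, digits = 4),
    ifelse(is.na(x$closest_structure), "no critical structures",
           x$closest_structure),
    format(x$max_diameter, digits = 4),
    if (x$feasible) "feasible" else "infeasible"))
  invisible(x)
}

#' Evaluate one straight trajectory against the critical structures
#'
#' Computes the axis clearance (minimum over the critical structures, with an
#' infinite sentinel when there are none), the feasibility flag
#' (`clearance >= required_clearance(config)`), and the largest drill
#' diameter that still keeps the safety and inaccuracy margins,
#' `max(0, 2 * (clearance - s - e))`. Structures listed in
#' `config$noncritical_names` (the target's own structure, optionally the
#' ossicles) are excluded from the critical set. An axis contained in a
#' closed critical structure gets clearance 0.
#'
#' @param entry entry point (mm); must differ from the target.
#' @param config a [plan_config()].
#' @param structures list of [structure_mesh()]; only those flagged critical
#'   and not excluded by name participate.
#' @return an object of class `trajectory`.
#' @export
evaluate_trajectory <- function(entry, config, structures) {
  stopifnot(inherits(config, "plan_config"))
  entry <- as.numeric(entry)
  if (sqrt(sum((entry - config$target)^2)) <= 0)
    stop("entry point equals the target")
  critical <- .critical_set(structures, config)
  seg <- segment(entry, config$target)
  res <- capsule_is_free(seg, required_clearance(config), critical)
  .trajectory(entry, config,
              clearance = res$clearance,
              closest_structure = if (is.null(res$result)) NA_character_
                                  else res$result$structure_name,
              contained = res$contained)
}

.critical_set <- function(structures, config) {
  if (inherits(structures, "structure_mesh")) structures <- list(structures)
  keep <- vapply(structures, function(m) {
    isTRUE(m$critical) && !(m$name %in% config$noncritical_names)
  }, logical(1))
  structures[keep]
}

#' Enumerate all collision-free trajectories (CFTs) for one target
#'
#' Evaluates every candidate entry point in the entry region and returns the
#' feasible trajectories with risk colors assigned by [color_code()]. An
#' empty set is a result, not an error.
#'
#' @param config a [plan_config()].
#' @param skull skull [structure_mesh()] supplying candidate entry points
#'   (the bone is the drilled medium and is never itself an obstacle).
#' @param structures list of [structure_mesh()] obstacles.
#' @return an object of class `trajectory_set` (a list of `trajectory`
#'   objects, ordered like the candidates, with the config attached).
#' @export
find_cfts <- function(config, skull, structures) {
  stopifnot(inherits(config, "plan_config"))
  cand <- candidate_entries(skull, config$entry_seed, config$entry_region_radius)
  faces <- attr(cand, "face_index")
  # drop a candidate that coincides with the target (degenerate axis)
  keep <- sqrt(rowSums(sweep(cand, 2, config$target)^2)) > 0
  cand <- cand[keep, , drop = FALSE]
  faces <- faces[keep]
  critical <- .critical_set(structures, config)
  critical <- critical[vapply(critical, function(m) nrow(m$faces) > 0, logical(1))]
  n <- nrow(cand)
  if (n == 0) return(.trajectory_set(list(), config))
  if (length(critical) == 0) {
    trajs <- lapply(seq_len(n), function(i)
      .trajectory(cand[i, ], config, Inf, NA_character_, FALSE, faces[i]))
    return(.trajectory_set(color_code(trajs), config))
  }
  dist <- rep(Inf, n)
  closest <- rep(NA_character_, n)
  contained <- rep(FALSE, n)
  mids <- sweep(cand, 2, config$target, "+") / 2
  probes <- rbind(cand, mids, matrix(config$target, 1))
  for (mesh in critical) {
    res <- cpp_bvh_clearance_batch(.mesh_bvh(mesh), cand, config$target)
    upd <- res$distance < dist
    dist[upd] <- res$distance[upd]
    closest[upd] <- mesh$name
    if (mesh_is_closed(mesh)) {
      inside <- cpp_points_in_mesh(probes, mesh$vertices, mesh$faces - 1L)
      contained <- contained | inside[seq_len(n)] | inside[n + seq_len(n)] |
        inside[2 * n + 1]
    } else {
      warning("mesh '", mesh$name,
              "' is not watertight; axis containment test skipped",
              call. = FALSE)
    }
  }
  trajs <- lapply(seq_len(n), function(i)
    .trajectory(cand[i, ], config, dist[i], closest[i], contained[i], faces[i]))
  feas <- vapply(trajs, `[[`, logical(1), "feasible")
  .trajectory_set(color_code(trajs[feas]), config)
}

.trajectory_set <- function(trajs, config) {
  structure(trajs, class = "trajectory_set", config = config)
}

#' Color-code trajectories by clearance
#'
#' Linear risk map over the set: the largest clearance maps to risk 0
#' (cold/blue, safest) and the smallest to 1 (hot/red). A single trajectory,
#' or an all-equal set, gets risk 0.
#'
#' @param trajectories list of `trajectory` objects.
#' @return the same list with `risk_value` filled in.
#' @export
color_code <- function(trajectories) {
  n <- length(trajectories)
  if (n == 0) return(trajectories)
  cl <- vapply(trajectories, `[[`, numeric(1), "clearance")
  fin <- cl[is.finite(cl)]
  risk <- if (length(unique(cl)) <= 1 || length(fin) == 0 ||
              max(cl) == min(cl)) {
    rep(0, n)
  } else {
    (max(cl) - cl) / (max(cl) - min(cl))
  }
  for (i in seq_len(n)) trajectories[[i]]$risk_value <- risk[i]
  trajectories
}

#' @export
print.trajectory_set <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf("<trajectory_set> %d collision-free trajectories (required clearance %.2f mm)\n",
              length(x), required_clearance(cfg)))
  if (length(x)) {
    cl <- vapply(x, `[[`, numeric(1), "clearance")
    cat(sprintf("  clearance %.2f - %.2f mm, length %.1f - %.1f mm\n",
                min(cl), max(cl),
                min(vapply(x, `[[`, numeric(1), "length")),
                max(vapply(x, `[[`, numeric(1), "length"))))
  }
  invisible(x)
}

#' @export
as.data.frame.trajectory_set <- function(x, ...) {
  if (length(x) == 0) {
    return(data.frame(entry_x = numeric(0), entry_y = numeric(0),
                      entry_z = numeric(0), length = numeric(0),
                      clearance = numeric(0),
                      closest_structure = character(0),
                      feasible = logical(0), max_diameter = numeric(0),
                      risk_value = numeric(0)))
  }
  ent <- t(vapply(x, `[[`, numeric(3), "entry"))
  data.frame(
    entry_x = ent[, 1], entry_y = ent[, 2], entry_z = ent[, 3],
    length = vapply(x, `[[`, numeric(1), "length"),
    clearance = vapply(x, `[[`, numeric(1), "clearance"),
    closest_structure = vapply(x, `[[`, character(1), "closest_structure"),
    feasible = vapply(x, `[[`, logical(1), "feasible"),
    max_diameter = vapply(x, `[[`, numeric(1), "max_diameter"),
    risk_value = vapply(x, `[[`, numeric(1), "risk_value"))
}
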