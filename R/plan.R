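#' Plan a three-port access to one target
#'
#' The main entry point: enumerates all collision-free trajectories (CFTs)
#' from the entry region to the target ([find_cfts()]), color-codes them by
#' clearance, selects the best-scoring three-port set
#' ([select_best_triple()]), and summarises the achievable drill diameters
#' ([summarize_by_region()]).
#'
#' @param skull skull [structure_mesh()] (candidate entry surface).
#' @param structures list of [structure_mesh()] obstacles.
#' @param config a [plan_config()].
#' @param w_clearance,w_angle triple-selection weights (see
#'   [score_triple()]).
#' @param m_cap candidate cap for the triple search (see
#'   [select_best_triple()]).
#' @param labeling optional [region_labeling()] of the skull faces for the
#'   per-region summary.
#' @return An object of class `multiport_plan`: list with `config`, `cfts`
#'   (a `trajectory_set`), `triple` (a [trajectory_triple()], or `NULL` when
#'   fewer than three CFTs exist), `summary` (region summary data frame) and
#'   `n_cft`.
#' @examples
#' cochlea <- icosphere_mesh(c(0, 7, 20), 3, name = "cochlea", critical = TRUE)
#' skull <- icosphere_mesh(c(0, 0, 0), 40, subdivisions = 3, name = "bone")
#' cfg <- plan_config(target = c(0, 0, 15), entry_seed = c(0, 0, 40),
#'                    entry_region_radius = 12, safety_distance = 1,
#'                    drill_inaccuracy = 0.5)
#' plan <- plan_ports(skull, list(cochlea), cfg)
#' print(plan)
#' @export
plan_ports <- function(skull, structures, config, w_clearance = 1,
                       w_angle = 1, m_cap = 40, labeling = NULL) {
  cfts <- find_cfts(config, skull, structures)
  triple <- NULL
  if (length(cfts) >= 3) {
    triple <- select_best_triple(cfts, w_clearance = w_clearance,
                                 w_angle = w_angle, m_cap = m_cap)
  }
  structure(list(config = config,
                 cfts = cfts,
                 triple = triple,
                 summary = summarize_by_region(cfts, skull, labeling),
                 n_cft = length(cfts),
                 weights = c(clearance = w_clearance, angle = w_angle),
                 m_cap = m_cap),
            class = "multiport_plan")
}

#' @export
print.multiport_plan <- function(x, ...) {
  cat(sprintf("Multiport plan: %d collision-free trajectories\n", x$n_cft))
  cat(sprintf("  required clearance %.2f mm (r_d %.2f + s %.2f + e %.2f)\n",
              required_clearance(x$config), x$config$drill_radius,
              x$config$safety_distance, x$config$drill_inaccuracy))
  if (!is.null(x$triple)) {
    cat(sprintf("  selected triple: CA %.1f deg, min clearance %.2f mm, score %.4f\n",
                x$triple$cumulative_angle,
                min(vapply(x$triple$trajectories, `[[`, numeric(1),
                           "clearance")),
                x$triple$score))
  } else if (x$n_cft > 0) {
    cat("  fewer than 3 CFTs: no triple selected\n")
  }
  invisible(x)
}

#' @export
summary.multiport_plan <- function(object, ...) {
  print(object)
  if (object$n_cft > 0) {
    df <- as.data.frame(object$cfts)
    cat(sprintf("  clearance: median %.2f mm, range %.2f - %.2f mm\n",
                median(df$clearance), min(df$clearance), max(df$clearance)))
    cat(sprintf("  max diameter: median %.2f mm, range %.2f - %.2f mm\n",
                median(df$max_diameter), min(df$max_diameter),
                max(df$max_diameter)))
    if (!is.null(object$triple)) {
      cat(sprintf("  triple angles %.1f / %.1f / %.1f deg, merge lengths %.2f / %.2f / %.2f mm\n",
                  object$triple$angles[1], object$triple$angles[2],
                  object$triple$angles[3], object$triple$merge_lengths[1],
                  object$triple$merge_lengths[2],
                  object$triple$merge_lengths[3]))
    }
  }
  cat("\nDiameter summary (mm):\n")
  print(object$summary, row.names = FALSE)
  invisible(object)
}

#' Plot a multiport plan
#'
#' Projects the CFT entry points onto the tangent plane at the entry seed
#' and colors them by risk (blue = large clearance, red = small), the usual
#' hot/cold risk display of trajectory planners. Selected triple entries are
#' circled.
#'
#' @param x a `multiport_plan`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.multiport_plan <- function(x, ...) {
  if (x$n_cft == 0) {
    plot.new()
    title(main = "no collision-free trajectories")
    return(invisible(x))
  }
  df <- as.data.frame(x$cfts)
  ent <- as.matrix(df[, c("entry_x", "entry_y", "entry_z")])
  ctr <- colMeans(ent)
  w <- ctr - x$config$target
  w <- w / sqrt(sum(w^2))
  u <- .orthonormal_to(w)
  v <- .cross3(w, u)
  rel <- sweep(ent, 2, ctr)
  px <- rel %*% u
  py <- rel %*% v
  ramp <- grDevices::colorRamp(c("#2166ac", "#f7f7f7", "#b2182b"))
  cols <- grDevices::rgb(ramp(df$risk_value), maxColorValue = 255)
  graphics::plot(px, py, pch = 19, col = cols, asp = 1,
                 xlab = "tangent u (mm)", ylab = "tangent v (mm)",
                 main = sprintf("%d CFTs (blue safe, red risky)", x$n_cft),
                 ...)
  if (!is.null(x$triple)) {
    tent <- t(vapply(x$triple$trajectories, `[[`, numeric(3), "entry"))
    trel <- sweep(tent, 2, ctr)
    graphics::points(trel %*% u, trel %*% v, pch = 1, cex = 2, lwd = 2)
  }
  invisible(x)
}
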