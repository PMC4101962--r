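#' Named surface regions on the skull mesh
#'
#' Per-triangle region labels for the skull surface (e.g. the suprameatal,
#' superior-semicircular-canal, retrolabyrinthine, facial-recess and
#' subfacial corridors of the temporal bone). Triangles without a region map
#' to `"unassigned"`.
#'
#' @param region_per_face character vector, one region name per skull face;
#'   `NA` becomes `"unassigned"`.
#' @return An object of class `region_labeling`.
#' @export
region_labeling <- function(region_per_face) {
  region_per_face <- as.character(region_per_face)
  region_per_face[is.na(region_per_face)] <- "unassigned"
  structure(list(region_per_face = region_per_face),
            class = "region_labeling")
}

#' @export
print.region_labeling <- function(x, ...) {
  tab <- table(x$region_per_face)
  cat("<region_labeling>", length(x$region_per_face), "faces:",
      paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' Label skull regions by nearest seed point
#'
#' Convenience parcellation: each skull triangle is assigned the region of
#' the nearest seed point. A stand-in for an anatomically drawn labeling.
#'
#' @param skull skull [structure_mesh()].
#' @param seeds named list (or named 3-column matrix) of region seed points.
#' @return a [region_labeling()].
#' @export
label_regions_by_seeds <- function(skull, seeds) {
  if (is.list(seeds)) seeds <- do.call(rbind, seeds)
  if (is.null(rownames(seeds))) stop("seeds must be named")
  cent <- mesh_centroids(skull)
  d2 <- sapply(seq_len(nrow(seeds)), function(i)
    rowSums(sweep(cent, 2, seeds[i, ])^2))
  region_labeling(rownames(seeds)[max.col(-d2, ties.method = "first")])
}

#' Region of each trajectory entry point
#'
#' Nearest-centroid assignment of entry points to skull triangles, then the
#' triangle's region.
#'
#' @param trajectories list of `trajectory` objects.
#' @param skull skull [structure_mesh()].
#' @param labeling a [region_labeling()] for the skull faces.
#' @return character vector of region names.
#' @export
assign_regions <- function(trajectories, skull, labeling) {
  stopifnot(inherits(labeling, "region_labeling"))
  if (length(labeling$region_per_face) != nrow(skull$faces))
    stop("labeling does not match skull face count")
  cent <- mesh_centroids(skull)
  vapply(trajectories, function(tr) {
    fi <- tr$face_index
    if (is.null(fi) || is.na(fi)) {
      d2 <- rowSums(sweep(cent, 2, tr$entry)^2)
      fi <- which.min(d2)
    }
    labeling$region_per_face[fi]
  }, character(1))
}

#' Per-region summary of achievable drill diameters
#'
#' For each anatomical region (plus a pooled `"all"` row): the number and
#' percentage of trajectories, the median, first and third quartile
#' (quartiles by linear interpolation between order statistics, R's default
#' type 7; stated because SPSS-style conventions differ), minimum and
#' maximum of the maximum achievable diameter, and Tukey outliers (values
#' outside `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]`).
#'
#' @param trajectories list of `trajectory` objects (a `trajectory_set`
#'   works).
#' @param skull optional skull mesh, required with `labeling`.
#' @param labeling optional [region_labeling()]; without it all trajectories
#'   are pooled.
#' @return data.frame with columns `region`, `n`, `pct`, `median`, `q1`,
#'   `q3`, `min`, `max`, `n_outliers`, `outliers` (semicolon-separated
#'   values). Empty input gives an empty table.
#' @export
summarize_by_region <- function(trajectories, skull = NULL, labeling = NULL) {
  trajectories <- unclass(trajectories)
  empty <- data.frame(region = character(0), n = integer(0), pct = numeric(0),
                      median = numeric(0), q1 = numeric(0), q3 = numeric(0),
                      min = numeric(0), max = numeric(0),
                      n_outliers = integer(0), outliers = character(0),
                      stringsAsFactors = FALSE)
  if (length(trajectories) == 0) return(empty)
  diam <- vapply(trajectories, `[[`, numeric(1), "max_diameter")
  regions <- if (is.null(labeling)) {
    rep("all", length(diam))
  } else {
    assign_regions(trajectories, skull, labeling)
  }
  total <- length(diam)
  one_row <- function(region, d) {
    q <- unname(quantile(d, c(0.25, 0.5, 0.75), type = 7, names = FALSE))
    iqr <- q[3] - q[1]
    out <- d[d < q[1] - 1.5 * iqr | d > q[3] + 1.5 * iqr]
    data.frame(region = region, n = length(d), pct = 100 * length(d) / total,
               median = q[2], q1 = q[1], q3 = q[3],
               min = min(d), max = max(d), n_outliers = length(out),
               outliers = paste(format(sort(out), trim = TRUE, digits = 6),
                                collapse = ";"),
               stringsAsFactors = FALSE)
  }
  rows <- lapply(sort(unique(regions)), function(r)
    one_row(r, diam[regions == r]))
  if (is.null(labeling)) {
    do.call(rbind, rows)
  } else {
    rbind(do.call(rbind, rows), one_row("all", diam))
  }
}
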