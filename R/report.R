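# Reporting and command drivers: tie file I/O, planning, selection and
# summaries together behind two commands (`phantom`, `plan`) with
# deterministic, self-contained outputs.

.read_config_file <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                        simplifyMatrix = FALSE)
  } else {
    stop("config must be .yaml/.yml or .json")
  }
}

.phantom_spec_from_list <- function(cfg) {
  phantom_spec(seed = if (is.null(cfg$seed)) 1L else cfg$seed,
               bone_shell = cfg$bone_shell,
               obstacles = lapply(cfg$obstacles, function(o) o),
               targets = lapply(cfg$targets, function(tg) tg),
               spacing = if (is.null(cfg$spacing)) c(0.25, 0.25, 0.25)
                         else unlist(cfg$spacing),
               planning = cfg$planning, selection = cfg$selection)
}

#' Generate phantom files
#'
#' Builds the phantom described by a YAML/JSON spec file and writes it to
#' `out_dir`: the label volume (`phantom.nii.gz`), one binary STL per
#' structure, an analytic registry (`registry.json`, with the label table
#' and criticality flags), and a ready-to-run plan config
#' (`plan_config.yaml`) referencing the generated files.
#'
#' @param spec_path phantom spec file (YAML or JSON), or a [phantom_spec()].
#' @param out_dir output directory (created if missing).
#' @param voxelize write the NIfTI label volume (default `TRUE`).
#' @return invisibly, the list of written files.
#' @export
cmd_phantom <- function(spec_path, out_dir, voxelize = TRUE) {
  spec <- if (inherits(spec_path, "phantom_spec")) spec_path
          else .phantom_spec_from_list(.read_config_file(spec_path))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ph <- build_phantom(spec, voxelize = voxelize)
  files <- character()
  if (!is.null(ph$volume)) {
    vol_path <- file.path(out_dir, "phantom.nii.gz")
    write_label_volume(ph$volume, vol_path)
    files <- c(files, vol_path)
  }
  mesh_files <- list()
  for (m in ph$meshes) {
    p <- file.path(out_dir, paste0(m$name, ".stl"))
    write_stl(m, p)
    files <- c(files, p)
    mesh_files[[m$name]] <- basename(p)
  }
  registry <- list(
    bone_shell = spec$bone_shell,
    structures = lapply(ph$registry, function(o) {
      o$critical <- isTRUE(o$critical)
      o
    }),
    labels = c(list(list(label = 1L, name = "bone", critical = FALSE)),
               lapply(ph$registry, function(o)
                 list(label = o$label, name = o$name,
                      critical = isTRUE(o$critical)))))
  reg_path <- file.path(out_dir, "registry.json")
  jsonlite::write_json(registry, reg_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  files <- c(files, reg_path)
  plan_cfg <- list(
    inputs = list(
      structures = c(
        list(list(name = "bone", file = mesh_files[["bone"]],
                  critical = FALSE)),
        lapply(ph$registry, function(o)
          list(name = o$name, file = mesh_files[[o$name]],
               critical = isTRUE(o$critical)))),
      skull = "bone"),
    planning = if (is.null(spec$planning)) {
      list(drill_radius = 0.5, safety_distance = 1.0,
           drill_inaccuracy = 0.5, entry_region_radius = 8)
    } else {
      spec$planning
    },
    selection = if (is.null(spec$selection)) {
      list(w_clearance = 1, w_angle = 1, m_cap = 40)
    } else {
      spec$selection
    },
    targets = lapply(spec$targets, function(tg)
      list(name = tg$name, point = tg$point, entry_seed = tg$entry_seed,
           noncritical = tg$noncritical)))
  cfg_path <- file.path(out_dir, "plan_config.yaml")
  yaml::write_yaml(plan_cfg, cfg_path)
  files <- c(files, cfg_path)
  invisible(files)
}

.load_structures <- function(cfg, base_dir) {
  inp <- cfg$inputs
  if (is.null(inp)) stop("config lacks an 'inputs' section")
  resolve <- function(p) {
    if (file.exists(p)) p else file.path(base_dir, p)
  }
  if (!is.null(inp$volume)) {
    vol_path <- resolve(inp$volume)
    tab <- inp$structures
    if (is.null(tab)) stop("volume input needs an 'inputs$structures' label table")
    label_names <- stats::setNames(
      vapply(tab, function(s) as.character(s$name), character(1)),
      vapply(tab, function(s) as.character(s$label), character(1)))
    vol <- read_label_volume(vol_path, label_names = label_names)
    meshes <- lapply(tab, function(s)
      extract_surface(vol, s$label, name = s$name,
                      critical = isTRUE(s$critical)))
    list(meshes = meshes, inputs = vol_path)
  } else {
    tab <- inp$structures
    if (is.null(tab)) stop("config needs 'inputs$structures'")
    paths <- vapply(tab, function(s) resolve(s$file), character(1))
    meshes <- mapply(function(s, p) {
      if (grepl("\\.stl$", p, ignore.case = TRUE)) {
        read_stl(p, name = s$name, critical = isTRUE(s$critical))
      } else {
        read_ply(p, name = s$name, critical = isTRUE(s$critical))
      }
    }, tab, paths, SIMPLIFY = FALSE)
    list(meshes = meshes, inputs = paths)
  }
}

#' Run the full planning protocol from a config file
#'
#' For every target in the config: candidate-entry generation, CFT
#' evaluation, clearance color coding, three-port selection, and diameter
#' summaries. Writes `report.json` (config echo, software version, input
#' digests, per-target CFT records and selected triples), `summary.csv`, and
#' optionally one STL cylinder per selected trajectory. Re-running with the
#' same config and inputs reproduces the outputs byte-identically.
#'
#' The config (YAML or JSON) has sections `inputs` (either `volume` plus a
#' `structures` label table, or per-structure mesh `file`s; `skull` names
#' the entry surface), `planning` (`drill_radius`, `safety_distance`,
#' `drill_inaccuracy`, `entry_region_radius`), `selection` (`w_clearance`,
#' `w_angle`, `m_cap`), `targets` (each with `name`, `point`, `entry_seed`,
#' optional `noncritical`), and optional `output` (`cylinders: true`,
#' `regions:` named seed points for a surface parcellation).
#'
#' After writing the report this raises a classed error when any target has
#' no CFT (`multiport_no_cft_error`) or fewer than three
#' (`multiport_insufficient_cft_error`), so a caller can map the outcomes to
#' distinct exit codes.
#'
#' @param config_path plan config file.
#' @param out_dir output directory.
#' @return invisibly, the report list.
#' @export
cmd_plan <- function(config_path, out_dir) {
  cfg <- .read_config_file(config_path)
  base_dir <- dirname(normalizePath(config_path))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  loaded <- .load_structures(cfg, base_dir)
  meshes <- loaded$meshes
  skull_name <- if (is.null(cfg$inputs$skull)) "bone" else cfg$inputs$skull
  skull_idx <- which(vapply(meshes, `[[`, character(1), "name") == skull_name)
  if (length(skull_idx) != 1) stop("skull structure '", skull_name, "' not found")
  skull <- meshes[[skull_idx]]
  pl <- cfg$planning
  sel <- cfg$selection
  if (is.null(sel)) sel <- list()
  if (is.null(sel$w_clearance)) sel$w_clearance <- 1
  if (is.null(sel$w_angle)) sel$w_angle <- 1
  if (is.null(sel$m_cap)) sel$m_cap <- 40
  labeling <- NULL
  if (!is.null(cfg$output$regions)) {
    seeds <- do.call(rbind, lapply(cfg$output$regions, unlist))
    rownames(seeds) <- names(cfg$output$regions)
    labeling <- label_regions_by_seeds(skull, seeds)
  }
  known <- vapply(meshes, `[[`, character(1), "name")
  targets <- cfg$targets
  if (is.null(targets) || length(targets) == 0) stop("config lists no targets")
  per_target <- list()
  plans <- list()
  for (tg in targets) {
    nc <- as.character(unlist(tg$noncritical))
    if (length(nc) && !all(nc %in% known))
      stop("unknown structure name(s) in noncritical list: ",
           paste(setdiff(nc, known), collapse = ", "))
    config <- plan_config(
      target = unlist(tg$point), entry_seed = unlist(tg$entry_seed),
      entry_region_radius = pl$entry_region_radius,
      drill_radius = if (is.null(pl$drill_radius)) 0.5 else pl$drill_radius,
      safety_distance = if (is.null(pl$safety_distance)) 0 else pl$safety_distance,
      drill_inaccuracy = if (is.null(pl$drill_inaccuracy)) 0 else pl$drill_inaccuracy,
      noncritical_names = nc)
    plan <- plan_ports(skull, meshes, config,
                       w_clearance = sel$w_clearance, w_angle = sel$w_angle,
                       m_cap = sel$m_cap, labeling = labeling)
    plans[[tg$name]] <- plan
    df <- as.data.frame(plan$cfts)
    triple_rec <- NULL
    if (!is.null(plan$triple)) {
      tr <- plan$triple
      triple_rec <- list(
        entries = lapply(tr$trajectories, `[[`, "entry"),
        angles_deg = as.list(tr$angles),
        cumulative_angle_deg = tr$cumulative_angle,
        merge_lengths_mm = as.list(tr$merge_lengths),
        min_clearance_mm = min(vapply(tr$trajectories, `[[`, numeric(1),
                                      "clearance")),
        score = tr$score)
    }
    per_target[[tg$name]] <- list(
      target = unlist(tg$point),
      n_cft = plan$n_cft,
      cfts = df,
      triple = triple_rec,
      summary = plan$summary)
  }
  report <- list(
    software = list(package = "multiport",
                    version = as.character(packageVersion("multiport"))),
    config = cfg,
    input_digests = as.list(tools::md5sum(sort(unname(loaded$inputs)))),
    clearance_semantics = "axis clearance (distance from the drill axis, not the cylinder surface, to the structure); quartiles: linear interpolation (type 7)",
    targets = per_target)
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows", na = "null")
  sum_rows <- do.call(rbind, lapply(names(per_target), function(nm) {
    s <- per_target[[nm]]$summary
    if (nrow(s) == 0) return(NULL)
    cbind(data.frame(target = nm, stringsAsFactors = FALSE), s)
  }))
  if (is.null(sum_rows))
    sum_rows <- data.frame(target = character(0))
  utils::write.csv(sum_rows, file.path(out_dir, "summary.csv"),
                   row.names = FALSE)
  if (isTRUE(cfg$output$cylinders)) {
    for (nm in names(plans)) {
      tr <- plans[[nm]]$triple
      if (is.null(tr)) next
      for (i in 1:3) {
        cyl <- cylinder_mesh(tr$trajectories[[i]]$entry,
                             tr$trajectories[[i]]$target,
                             radius = plans[[nm]]$config$drill_radius,
                             name = sprintf("%s_port%d", nm, i))
        write_stl(cyl, file.path(out_dir, sprintf("cylinder_%s_%d.stl", nm, i)))
      }
    }
  }
  n_cfts <- vapply(per_target, `[[`, integer(1), "n_cft")
  if (any(n_cfts == 0))
    stop(errorCondition(
      paste("no collision-free trajectory for target(s):",
            paste(names(n_cfts)[n_cfts == 0], collapse = ", ")),
      class = c("multiport_no_cft_error", "multiport_error")))
  if (any(n_cfts < 3))
    stop(errorCondition(
      paste("fewer than 3 collision-free trajectories for target(s):",
            paste(names(n_cfts)[n_cfts < 3], collapse = ", ")),
      class = c("multiport_insufficient_cft_error", "multiport_error")))
  invisible(report)
}
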