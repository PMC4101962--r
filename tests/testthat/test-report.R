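# End-to-end command drivers on a small phantom written to disk.

write_small_phantom_spec <- function(path, entry_region_radius = 5,
                                     safety_distance = 1) {
  spec <- list(
    seed = 5,
    spacing = c(0.5, 0.5, 0.5),
    bone_shell = list(outer_radius = 20, thickness = 3, center = c(0, 0, 0)),
    obstacles = list(
      list(name = "vessel", kind = "capsule", a = c(5, -3, 6), b = c(7, 4, 12),
           radius = 1.2, critical = TRUE),
      list(name = "cochlea", kind = "sphere", center = c(-4, 2, 8),
           radius = 2, critical = TRUE)),
    targets = list(
      list(name = "T1", point = c(0, 0, 6), entry_seed = c(0, 0, 20),
           noncritical = list())),
    planning = list(drill_radius = 0.5, safety_distance = safety_distance,
                    drill_inaccuracy = 0.5, entry_region_radius = entry_region_radius),
    selection = list(w_clearance = 1, w_angle = 1, m_cap = 40))
  yaml::write_yaml(spec, path)
  path
}

test_that("cmd_phantom writes volume, meshes, registry and a plan config", {
  out <- file.path(tempdir(), "ph_out")
  unlink(out, recursive = TRUE)
  spec_path <- write_small_phantom_spec(tempfile(fileext = ".yaml"))
  files <- cmd_phantom(spec_path, out)
  expect_true(file.exists(file.path(out, "phantom.nii.gz")))
  expect_true(file.exists(file.path(out, "bone.stl")))
  expect_true(file.exists(file.path(out, "vessel.stl")))
  expect_true(file.exists(file.path(out, "registry.json")))
  expect_true(file.exists(file.path(out, "plan_config.yaml")))
  vol <- read_label_volume(file.path(out, "phantom.nii.gz"))
  expect_setequal(unique(as.vector(vol$voxels)), c(0L, 1L, 2L, 3L))
  reg <- jsonlite::read_json(file.path(out, "registry.json"))
  expect_equal(vapply(reg$labels, `[[`, character(1), "name"),
               c("bone", "vessel", "cochlea"))
})

test_that("a phantom spec with a target outside the shell fails before writing", {
  spec_path <- tempfile(fileext = ".yaml")
  spec <- yaml::read_yaml(write_small_phantom_spec(spec_path))
  spec$targets[[1]]$point <- c(0, 0, 30)
  yaml::write_yaml(spec, spec_path)
  out <- file.path(tempdir(), "ph_bad")
  unlink(out, recursive = TRUE)
  expect_error(cmd_phantom(spec_path, out), "inside the bone shell")
  expect_false(file.exists(file.path(out, "phantom.nii.gz")))
})

test_that("cmd_plan runs the protocol and reruns byte-identically", {
  out <- file.path(tempdir(), "ph_e2e")
  unlink(out, recursive = TRUE)
  spec_path <- write_small_phantom_spec(tempfile(fileext = ".yaml"))
  cmd_phantom(spec_path, out)
  plan_dir <- file.path(out, "plan")
  rep1 <- cmd_plan(file.path(out, "plan_config.yaml"), plan_dir)
  expect_true(file.exists(file.path(plan_dir, "report.json")))
  expect_true(file.exists(file.path(plan_dir, "summary.csv")))
  expect_gte(rep1$targets$T1$n_cft, 3)
  expect_false(is.null(rep1$targets$T1$triple))
  expect_equal(rep1$config$planning$drill_radius, 0.5)
  md5_1 <- tools::md5sum(c(file.path(plan_dir, "report.json"),
                           file.path(plan_dir, "summary.csv")))
  plan_dir2 <- file.path(out, "plan2")
  cmd_plan(file.path(out, "plan_config.yaml"), plan_dir2)
  md5_2 <- tools::md5sum(c(file.path(plan_dir2, "report.json"),
                           file.path(plan_dir2, "summary.csv")))
  expect_identical(unname(md5_1), unname(md5_2))

  # report echoes enough to reproduce: config + input digests present
  rep_json <- jsonlite::read_json(file.path(plan_dir, "report.json"))
  expect_true(!is.null(rep_json$config$planning))
  expect_gt(length(rep_json$input_digests), 0)
  expect_equal(rep_json$software$package, "multiport")
})

test_that("cmd_plan distinguishes 'no CFTs' from 'fewer than 3'", {
  out <- file.path(tempdir(), "ph_err")
  unlink(out, recursive = TRUE)
  spec_path <- write_small_phantom_spec(tempfile(fileext = ".yaml"),
                                        safety_distance = 1000)
  cmd_phantom(spec_path, out)
  expect_error(cmd_plan(file.path(out, "plan_config.yaml"),
                        file.path(out, "plan")),
               class = "multiport_no_cft_error")
  # the report is still written before the condition is raised
  expect_true(file.exists(file.path(out, "plan", "report.json")))

  # an entry region of radius 0 keeps a single candidate: 1 CFT -> "fewer than 3"
  out2 <- file.path(tempdir(), "ph_err2")
  unlink(out2, recursive = TRUE)
  spec_path2 <- write_small_phantom_spec(tempfile(fileext = ".yaml"),
                                         entry_region_radius = 0)
  cmd_phantom(spec_path2, out2)
  expect_error(cmd_plan(file.path(out2, "plan_config.yaml"),
                        file.path(out2, "plan")),
               class = "multiport_insufficient_cft_error")
})

test_that("unknown structure names in the noncritical list are rejected", {
  out <- file.path(tempdir(), "ph_unknown")
  unlink(out, recursive = TRUE)
  spec_path <- write_small_phantom_spec(tempfile(fileext = ".yaml"))
  cmd_phantom(spec_path, out)
  cfg <- yaml::read_yaml(file.path(out, "plan_config.yaml"))
  cfg$targets[[1]]$noncritical <- list("no_such_structure")
  cfg_path <- file.path(out, "plan_config_bad.yaml")
  yaml::write_yaml(cfg, cfg_path)
  expect_error(cmd_plan(cfg_path, file.path(out, "plan")),
               "unknown structure")
})

test_that("plan_ports returns a printable, summarisable, plottable object", {
  skull <- icosphere_mesh(c(0, 0, 0), 25, subdivisions = 3, name = "skull")
  obs <- icosphere_mesh(c(4, 0, 12), 2, subdivisions = 2, name = "o",
                        critical = TRUE)
  cfg <- plan_config(c(0, 0, 5), c(0, 0, 25), 7, 0.5, 1, 0.5)
  plan <- plan_ports(skull, list(obs), cfg)
  expect_s3_class(plan, "multiport_plan")
  expect_gte(plan$n_cft, 3)
  expect_s3_class(plan$triple, "trajectory_triple")
  expect_output(print(plan), "collision-free")
  expect_output(summary(plan), "Diameter summary")
  f <- tempfile(fileext = ".png")
  grDevices::png(f)
  plot(plan)
  grDevices::dev.off()
  expect_true(file.exists(f))
  df <- as.data.frame(plan$cfts)
  expect_true(all(df$feasible))
  expect_true(all(df$risk_value >= 0 & df$risk_value <= 1))
})
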