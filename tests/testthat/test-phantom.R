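small_spec <- function(obstacles = list(), spacing = 0.5) {
  phantom_spec(seed = 3,
               bone_shell = list(outer_radius = 20, thickness = 3,
                                 center = c(0, 0, 0)),
               obstacles = obstacles,
               targets = list(list(name = "T1", point = c(0, 0, 6),
                                   entry_seed = c(0, 0, 20))),
               spacing = rep(spacing, 3))
}

test_that("voxelised sphere matches a brute-force digitisation count", {
  sph <- list(name = "ball", kind = "sphere", center = c(2, -1, 8),
              radius = 3, critical = TRUE)
  ph <- build_phantom(small_spec(list(sph)), voxelize = TRUE)
  vol <- ph$volume
  lab <- which(vol$voxels == 2L)
  # independent scan over voxel centres
  idx <- arrayInd(lab, dim(vol$voxels))
  ctr <- sweep((idx - 1) * rep(vol$spacing, each = nrow(idx)), 2,
               vol$origin, "+")
  expect_true(all(rowSums(sweep(ctr, 2, sph$center)^2) <= 9 + 1e-9))
  # count equals the full brute-force scan
  d <- dim(vol$voxels)
  xs <- vol$origin[1] + (seq_len(d[1]) - 1) * vol$spacing[1]
  ys <- vol$origin[2] + (seq_len(d[2]) - 1) * vol$spacing[2]
  zs <- vol$origin[3] + (seq_len(d[3]) - 1) * vol$spacing[3]
  d2 <- outer(outer((xs - 2)^2, (ys + 1)^2, "+"), (zs - 8)^2, "+")
  expect_equal(length(lab), sum(d2 <= 9))
})

test_that("empty obstacle list leaves only bone labels; same spec is reproducible", {
  ph <- build_phantom(small_spec(), voxelize = TRUE)
  expect_setequal(unique(as.vector(ph$volume$voxels)), c(0L, 1L))
  ph2 <- build_phantom(small_spec(), voxelize = TRUE)
  expect_identical(ph$volume$voxels, ph2$volume$voxels)
})

test_that("overlapping primitives are rejected", {
  o1 <- list(name = "a", kind = "sphere", center = c(0, 0, 8), radius = 3,
             critical = TRUE)
  o2 <- list(name = "b", kind = "sphere", center = c(1, 0, 8), radius = 3,
             critical = TRUE)
  expect_error(build_phantom(small_spec(list(o1, o2)), voxelize = TRUE),
               "overlap")
})

test_that("targets must lie strictly inside the shell", {
  expect_error(phantom_spec(
    bone_shell = list(outer_radius = 20, thickness = 3, center = c(0, 0, 0)),
    targets = list(list(name = "bad", point = c(0, 0, 19)))),
    "inside the bone shell")
  expect_error(phantom_spec(
    bone_shell = list(outer_radius = 20, thickness = 3, center = c(0, 0, 0)),
    targets = list(list(name = "below", point = c(0, 0, -1)))),
    "inside the bone shell")
})

test_that("analytic clearances match closed forms and sampling oracles", {
  seg <- segment(c(-20, 0, 0), c(20, 0, 0))
  expect_equal(analytic_clearance(seg, list(name = "s", kind = "sphere",
                                            center = c(0, 7, 0), radius = 3)),
               4.0)
  # capsule whose axis crosses the segment: clamped to 0
  expect_equal(analytic_clearance(seg, list(name = "c", kind = "capsule",
                                            a = c(0, -2, 0), b = c(0, 2, 0),
                                            radius = 1)),
               0)
  expect_error(analytic_clearance(seg, list(name = "x", kind = "cone")),
               "unsupported")
  set.seed(31)
  for (i in 1:10) {
    seg <- random_segment(10)
    a <- runif(3, -8, 8); b <- a + rnorm(3) * 3
    r <- runif(1, 0.3, 1.5)
    prim <- list(name = "c", kind = "capsule", a = a, b = b, radius = r)
    d_samp <- max(0, sampled_segment_segment_distance(seg$a, seg$b, a, b) - r)
    expect_lt(abs(analytic_clearance(seg, prim) - d_samp), 1e-4)
  }
  for (i in 1:6) {
    seg <- random_segment(12)
    prim <- list(name = "t", kind = "torus_arc", center = runif(3, -5, 5),
                 normal = rnorm(3), radius = runif(1, 2, 5),
                 tube_radius = runif(1, 0.3, 1),
                 angle_start = runif(1, 0, 90), angle_end = runif(1, 180, 360))
    prim$tube_radius <- min(prim$tube_radius, prim$radius * 0.4)
    pv <- multiport:::.validate_primitive(prim)
    d_samp <- max(0, sampled_arc_segment_distance(pv, seg$a, seg$b) -
                    pv$tube_radius)
    expect_lt(abs(analytic_clearance(seg, prim) - d_samp), 1e-4)
  }
})

test_that("mesh clearance agrees with analytic clearance within the chord bound", {
  set.seed(41)
  for (i in 1:15) {
    seg <- random_segment(12)
    kind <- sample(c("sphere", "capsule", "torus_arc"), 1)
    prim <- switch(kind,
      sphere = list(name = "s", kind = "sphere", center = runif(3, -6, 6),
                    radius = runif(1, 1, 4)),
      capsule = {
        a <- runif(3, -6, 6)
        list(name = "c", kind = "capsule", a = a, b = a + rnorm(3) * 3,
             radius = runif(1, 0.5, 2))
      },
      torus_arc = list(name = "t", kind = "torus_arc",
                       center = runif(3, -5, 5), normal = rnorm(3),
                       radius = runif(1, 2, 5), tube_radius = runif(1, 0.4, 0.8),
                       angle_start = 0, angle_end = runif(1, 120, 360)))
    mesh <- switch(kind,
      sphere = {
        sub <- 0L
        while (icosphere_chord_dev(sub) * prim$radius > 0.05 && sub < 6L)
          sub <- sub + 1L
        icosphere_mesh(prim$center, prim$radius, subdivisions = sub)
      },
      capsule = capsule_mesh(prim$a, prim$b, prim$radius, tol = 0.05),
      torus_arc = arc_tube_mesh(prim, tol = 0.05, name = "t"))
    d_an <- analytic_clearance(seg, prim)
    d_mesh <- mesh_clearance(seg, mesh)$distance
    # inscribed tessellation: mesh distance in [analytic, analytic + chord]
    expect_gte(d_mesh, d_an - 1e-9)
    expect_lte(d_mesh - d_an, 0.05 + 1e-9)
  }
})

test_that("random scenes are reproducible and honour the corridor guarantee", {
  s1 <- random_scene(99, 5, difficulty = 0)
  s2 <- random_scene(99, 5, difficulty = 0)
  expect_identical(s1, s2)
  expect_gte(s1$corridor$cstar, 4.0)

  ph <- build_phantom(s1, voxelize = FALSE)
  cfg <- plan_config(s1$targets[[1]]$point, s1$targets[[1]]$entry_seed,
                     entry_region_radius = 4, drill_radius = 0.5,
                     safety_distance = 1, drill_inaccuracy = 0.5)
  cfts <- find_cfts(cfg, ph$meshes[[1]], ph$meshes)
  expect_gte(length(cfts), 1)

  # no obstacles: every candidate is feasible
  s0 <- random_scene(7, 0)
  ph0 <- build_phantom(s0, voxelize = FALSE)
  cfg0 <- plan_config(s0$targets[[1]]$point, s0$targets[[1]]$entry_seed,
                      entry_region_radius = 4, drill_radius = 0.5,
                      safety_distance = 1, drill_inaccuracy = 0.5)
  cand <- candidate_entries(ph0$meshes[[1]], s0$targets[[1]]$entry_seed, 4)
  expect_equal(length(find_cfts(cfg0, ph0$meshes[[1]], ph0$meshes)),
               nrow(cand))
})

test_that("voxelised and direct meshes agree on feasibility away from the margin", {
  sph <- list(name = "ball", kind = "sphere", center = c(3, 0, 9),
              radius = 2.5, critical = TRUE)
  cap <- list(name = "vessel", kind = "capsule", a = c(-5, -3, 5),
              b = c(-2, 4, 12), radius = 1.2, critical = TRUE)
  spec <- small_spec(list(sph, cap), spacing = 0.5)
  ph <- build_phantom(spec, voxelize = TRUE)
  direct <- ph$meshes
  vox_meshes <- lapply(ph$registry, function(o)
    extract_surface(ph$volume, o$label, name = o$name, critical = o$critical))
  cfg <- plan_config(spec$targets[[1]]$point, spec$targets[[1]]$entry_seed,
                     entry_region_radius = 5, drill_radius = 0.5,
                     safety_distance = 0.5, drill_inaccuracy = 0.5)
  cand <- candidate_entries(direct[[1]], spec$targets[[1]]$entry_seed, 5)
  diag_mm <- sqrt(sum(spec$spacing^2))
  req <- required_clearance(cfg)
  n_checked <- 0
  for (i in seq_len(min(nrow(cand), 40))) {
    tr_d <- evaluate_trajectory(cand[i, ], cfg, direct)
    if (abs(tr_d$clearance - req) <= diag_mm) next # within the voxel margin
    tr_v <- evaluate_trajectory(cand[i, ], cfg, vox_meshes)
    expect_identical(tr_v$feasible, tr_d$feasible)
    n_checked <- n_checked + 1
  }
  expect_gt(n_checked, 5)
})
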