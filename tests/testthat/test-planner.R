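test_that("candidate_entries: snapping, radius filter and determinism", {
  # unit square as two triangles
  sq <- structure_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0)),
                       rbind(c(1, 2, 3), c(1, 3, 4)), name = "sq")
  cent <- mesh_centroids(sq)
  c0 <- candidate_entries(sq, cent[1, ], 0)
  expect_equal(nrow(c0), 1)
  expect_equal(unname(c0[1, ]), unname(cent[1, ]))
  c2 <- candidate_entries(sq, cent[1, ] + c(0.01, 0, 0.2), 10)
  expect_equal(nrow(c2), 2)

  skull <- icosphere_mesh(c(0, 0, 0), 20, subdivisions = 3, name = "skull")
  seed <- c(0, 0, 25)
  cand <- candidate_entries(skull, seed, 5)
  # brute-force centroid scan oracle
  cc <- mesh_centroids(skull)
  snap <- cc[which.min(colSums((t(cc) - seed)^2)), ]
  n_oracle <- sum(sqrt(colSums((t(cc) - snap)^2)) <= 5)
  expect_equal(nrow(cand), n_oracle)
  # ordered by distance to the snapped seed
  d <- sqrt(colSums((t(cand) - snap)^2))
  expect_true(all(diff(d) >= 0))
  expect_error(candidate_entries(structure_mesh(matrix(0, 0, 3),
                                                matrix(0L, 0, 3)),
                                 seed, 5), "empty")
})

test_that("evaluate_trajectory reproduces the spherical closed form", {
  cfg <- plan_config(target = c(0, 0, 0), entry_seed = c(0, 0, 40),
                     entry_region_radius = 5, drill_radius = 0.5,
                     safety_distance = 1, drill_inaccuracy = 0.5)
  # obstacle: sphere radius 2 at perpendicular distance 4 from the axis,
  # foot interior -> clearance = 4 - 2 = 2, feasible (required 2.0)
  ball <- icosphere_mesh(c(4, 0, 20), 2, subdivisions = 3, name = "ball",
                         critical = TRUE)
  tr <- evaluate_trajectory(c(0, 0, 40), cfg, list(ball))
  chord <- icosphere_chord_dev(3) * 2
  expect_lt(abs(tr$clearance - 2), chord + 1e-9)
  expect_true(tr$feasible)
  expect_equal(tr$closest_structure, "ball")
  expect_equal(tr$length, 40)
  expect_equal(tr$max_diameter, 2 * (tr$clearance - 1.5))
  # direction is the target -> entry unit vector
  expect_equal(unname(tr$direction), c(0, 0, 1))

  # push the sphere closer: clearance 4 - 3 = 1 < 2 -> infeasible
  ball2 <- icosphere_mesh(c(4, 0, 20), 3, subdivisions = 3, name = "ball",
                          critical = TRUE)
  expect_false(evaluate_trajectory(c(0, 0, 40), cfg, list(ball2))$feasible)

  # no critical structures: infinite sentinel, unbounded diameter
  tr0 <- evaluate_trajectory(c(0, 0, 40), cfg, list())
  expect_true(tr0$feasible)
  expect_identical(tr0$clearance, Inf)
  expect_identical(tr0$max_diameter, Inf)

  expect_error(evaluate_trajectory(c(0, 0, 0), cfg, list()), "equals the target")
})

test_that("segment (not infinite line) semantics: obstacle beyond the target", {
  cfg <- plan_config(target = c(0, 0, 10), entry_seed = c(0, 0, 40),
                     entry_region_radius = 5, drill_radius = 0.5,
                     safety_distance = 1, drill_inaccuracy = 0.5)
  # sphere centred on the axis line but 8 mm behind the target:
  # line distance 0 - 2 < 0, segment distance 8 - 2 = 6 > 2 -> feasible
  behind <- icosphere_mesh(c(0, 0, 2), 2, subdivisions = 3, name = "behind",
                           critical = TRUE)
  tr <- evaluate_trajectory(c(0, 0, 40), cfg, list(behind))
  d_true <- sampled_segment_segment_distance(c(0, 0, 40), c(0, 0, 10),
                                             c(0, 0, 2), c(0, 0, 2)) - 2
  expect_lt(abs(tr$clearance - d_true), 0.05)
  expect_true(tr$feasible)
})

test_that("noncritical structures and the bone are excluded from collisions", {
  cfg <- plan_config(target = c(0, 0, 0), entry_seed = c(0, 0, 40),
                     entry_region_radius = 5, drill_radius = 0.5,
                     safety_distance = 1, drill_inaccuracy = 0.5,
                     noncritical_names = "cochlea")
  hit <- icosphere_mesh(c(0, 0, 20), 2, subdivisions = 2, name = "cochlea",
                        critical = TRUE)
  noncrit <- icosphere_mesh(c(0.5, 0, 25), 2, subdivisions = 2,
                            name = "skin", critical = FALSE)
  tr <- evaluate_trajectory(c(0, 0, 40), cfg, list(hit, noncrit))
  expect_true(tr$feasible) # both excluded -> nothing critical left
  expect_identical(tr$clearance, Inf)
})

test_that("find_cfts equals the per-candidate oracle and is antitone in s", {
  skull <- icosphere_mesh(c(0, 0, 0), 30, subdivisions = 3, name = "skull")
  obstacles <- list(
    icosphere_mesh(c(5, 2, 14), 2.5, subdivisions = 2, name = "o1",
                   critical = TRUE),
    capsule_mesh(c(-6, -2, 10), c(-2, 5, 20), 1.5, tol = 0.1, name = "o2",
                 critical = TRUE))
  target <- c(0, 0, 5)
  seed <- c(0, 0, 30)
  counts <- integer(0)
  prev_keys <- NULL
  for (s in c(0, 0.5, 1, 2, 4)) {
    cfg <- plan_config(target, seed, entry_region_radius = 8,
                       drill_radius = 0.5, safety_distance = s,
                       drill_inaccuracy = 0.5)
    cfts <- find_cfts(cfg, skull, obstacles)
    # oracle: direct loop over the candidates
    cand <- candidate_entries(skull, seed, 8)
    oracle <- Filter(function(tr) tr$feasible,
                     lapply(seq_len(nrow(cand)), function(i)
                       evaluate_trajectory(cand[i, ], cfg, obstacles)))
    expect_equal(length(cfts), length(oracle))
    if (length(cfts)) {
      got <- t(vapply(cfts, `[[`, numeric(3), "entry"))
      want <- t(vapply(oracle, `[[`, numeric(3), "entry"))
      expect_equal(got, want)
      expect_equal(vapply(cfts, `[[`, numeric(1), "clearance"),
                   vapply(oracle, `[[`, numeric(1), "clearance"))
    }
    keys <- apply(t(vapply(cfts, `[[`, numeric(3), "entry")), 1, paste,
                  collapse = "|")
    if (!is.null(prev_keys)) expect_true(all(keys %in% prev_keys))
    prev_keys <- keys
    counts <- c(counts, length(cfts))
  }
  expect_true(all(diff(counts) <= 0))

  # required clearance far above the corridor width: empty result, no error
  cfg_wide <- plan_config(target, seed, entry_region_radius = 8,
                          drill_radius = 0.5, safety_distance = 1000,
                          drill_inaccuracy = 0)
  expect_length(find_cfts(cfg_wide, skull, obstacles), 0)
})

test_that("feasibility is invariant under a shared rigid motion", {
  skull <- icosphere_mesh(c(0, 0, 0), 25, subdivisions = 2, name = "skull")
  obs <- icosphere_mesh(c(3, 1, 12), 2, subdivisions = 2, name = "o",
                        critical = TRUE)
  cent <- mesh_centroids(skull)
  # a seed with a unique nearest centroid (a face centroid, nudged outward),
  # and a region radius placed inside a gap of the centroid-distance
  # spectrum, so inclusion cannot flip under floating-point jitter
  snap <- cent[17, ]
  seed <- snap * 1.02
  ds <- sort(sqrt(colSums((t(cent) - snap)^2)))
  ds <- ds[ds > 3 & ds < 10]
  gaps <- diff(ds)
  k <- which.max(gaps)
  rho <- (ds[k] + ds[k + 1]) / 2
  target <- c(0, 0, 4)
  cfg <- plan_config(target, seed, rho, 0.5, 1, 0.5)
  base <- find_cfts(cfg, skull, list(obs))
  expect_gt(length(base), 0)
  set.seed(5)
  R <- random_rotation(); tr <- c(4, -7, 2)
  cfg_r <- plan_config(as.vector(R %*% target + tr),
                       as.vector(R %*% seed + tr), rho, 0.5, 1, 0.5)
  moved <- find_cfts(cfg_r, transform_mesh(skull, R, tr),
                     list(transform_mesh(obs, R, tr)))
  expect_equal(length(moved), length(base))
  expect_equal(sort(vapply(moved, `[[`, numeric(1), "clearance")),
               sort(vapply(base, `[[`, numeric(1), "clearance")),
               tolerance = 1e-6)
})

test_that("every feasible trajectory admits at least the drill diameter", {
  skull <- icosphere_mesh(c(0, 0, 0), 25, subdivisions = 2, name = "skull")
  obs <- icosphere_mesh(c(3, 1, 12), 2.5, subdivisions = 2, name = "o",
                        critical = TRUE)
  cfg <- plan_config(c(0, 0, 4), c(0, 0, 25), 8, 0.7, 1, 0.3)
  cfts <- find_cfts(cfg, skull, list(obs))
  expect_gt(length(cfts), 0)
  expect_true(all(vapply(cfts, `[[`, numeric(1), "max_diameter") >= 2 * 0.7))
})

test_that("color_code maps clearance linearly onto risk", {
  trs <- lapply(c(2, 3, 4), function(cl) fake_trajectory(c(0, 0, 1),
                                                         clearance = cl))
  out <- color_code(trs)
  expect_equal(vapply(out, `[[`, numeric(1), "risk_value"), c(1, 0.5, 0))
  one <- color_code(trs[1])
  expect_equal(one[[1]]$risk_value, 0)
  same <- color_code(lapply(1:3, function(i) fake_trajectory(c(0, 0, 1),
                                                             clearance = 2)))
  expect_equal(vapply(same, `[[`, numeric(1), "risk_value"), rep(0, 3))
})
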