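test_that("pairwise angles follow the target->entry convention", {
  t1 <- fake_trajectory(c(1, 0, 0))
  t2 <- fake_trajectory(c(0, 1, 0))
  t3 <- fake_trajectory(c(-1, 0, 0))
  expect_equal(pairwise_angle(t1, t2), 90)
  expect_equal(pairwise_angle(t1, t1), 0)
  expect_equal(pairwise_angle(t1, t3), 180)
  far <- fake_trajectory(c(1, 0, 0), target = c(0, 0, 1))
  expect_error(pairwise_angle(t1, far), "share a target")
})

test_that("cumulative angle: identities and recomputation oracle", {
  ortho <- list(fake_trajectory(c(1, 0, 0)), fake_trajectory(c(0, 1, 0)),
                fake_trajectory(c(0, 0, 1)))
  expect_equal(cumulative_angle(ortho), 270)
  same <- lapply(1:3, function(i) fake_trajectory(c(1, 1, 0)))
  expect_equal(cumulative_angle(same), 0)
  set.seed(9)
  for (i in 1:20) {
    dirs <- lapply(1:3, function(j) rnorm(3))
    trs <- lapply(dirs, fake_trajectory)
    # independent recomputation: sum of three arccos of normalised dots
    ca_oracle <- 0
    for (pair in list(c(1, 2), c(1, 3), c(2, 3))) {
      u <- dirs[[pair[1]]] / sqrt(sum(dirs[[pair[1]]]^2))
      v <- dirs[[pair[2]]] / sqrt(sum(dirs[[pair[2]]]^2))
      ca_oracle <- ca_oracle + acos(max(-1, min(1, sum(u * v)))) * 180 / pi
    }
    expect_equal(cumulative_angle(trs), ca_oracle, tolerance = 1e-12)
    expect_lte(cumulative_angle(trs), 540)
  }
})

test_that("merge length: closed form, limits, scaling, antitone in alpha", {
  expect_equal(merge_length_angle(60, 1, 1), 2.0)
  expect_equal(merge_length_angle(180, 1, 1), 1.0)
  expect_identical(merge_length_angle(0, 1, 1), Inf)
  expect_equal(merge_length_angle(47, 2, 2), 2 * merge_length_angle(47, 1, 1))
  alphas <- seq(5, 180, by = 5)
  l <- vapply(alphas, merge_length_angle, numeric(1), r1 = 0.5, r2 = 0.5)
  expect_true(all(diff(l) < 0))
  t1 <- fake_trajectory(c(1, 0, 0)); t2 <- fake_trajectory(c(0, 1, 0))
  expect_equal(merge_length(t1, t2, 1, 1), 2 / (2 * sin(pi / 4)))
})

test_that("merge length agrees with a numeric cylinder-overlap search", {
  set.seed(13)
  for (i in 1:20) {
    alpha <- runif(1, 5, 175)
    r1 <- runif(1, 0.3, 2); r2 <- runif(1, 0.3, 2)
    # two unit directions at angle alpha; walk out from the shared target and
    # find the largest depth x where the axis points are closer than r1 + r2
    d1 <- c(1, 0, 0)
    d2 <- c(cos(alpha * pi / 180), sin(alpha * pi / 180), 0)
    gap <- function(x) sqrt(sum((x * d1 - x * d2)^2)) - (r1 + r2)
    lo <- 0; hi <- 1e4
    for (k in 1:60) {
      mid <- (lo + hi) / 2
      if (gap(mid) < 0) lo <- mid else hi <- mid
    }
    expect_lt(abs(merge_length_angle(alpha, r1, r2) - lo), 1e-4)
  }
})

test_that("trajectory_triple records angles, CA and merge lengths", {
  tr <- trajectory_triple(fake_trajectory(c(1, 0, 0)),
                          fake_trajectory(c(0, 1, 0)),
                          fake_trajectory(c(0, 0, 1)), drill_radius = 0.5)
  expect_equal(unname(tr$angles), c(90, 90, 90))
  expect_equal(tr$cumulative_angle, 270)
  expect_equal(unname(tr$merge_lengths), rep(1 / (2 * sin(pi / 4)), 3))
  expect_equal(cumulative_angle(tr), 270)
})

test_that("cumulative angle is invariant under shared rotation", {
  set.seed(17)
  for (i in 1:25) {
    dirs <- lapply(1:3, function(j) rnorm(3))
    trs <- lapply(dirs, fake_trajectory)
    ca <- cumulative_angle(trs)
    R <- random_rotation()
    rot <- lapply(dirs, function(d) fake_trajectory(as.vector(R %*% d)))
    expect_lt(abs(cumulative_angle(rot) - ca), 1e-9)
  }
})

test_that("score_triple is monotone in min clearance and CA", {
  spread <- function(cl3, spread_deg) {
    th <- spread_deg * pi / 180
    list(fake_trajectory(c(0, 0, 1), clearance = cl3[1]),
         fake_trajectory(c(sin(th), 0, cos(th)), clearance = cl3[2]),
         fake_trajectory(c(0, sin(th), cos(th)), clearance = cl3[3]))
  }
  tighter <- do.call(trajectory_triple, spread(c(2, 3, 4), 10))
  wider <- do.call(trajectory_triple, spread(c(2, 3, 4), 30))
  expect_gt(score_triple(wider, 1, 1, clearance_norm = 4),
            score_triple(tighter, 1, 1, clearance_norm = 4))
  low <- do.call(trajectory_triple, spread(c(1, 3, 4), 20))
  high <- do.call(trajectory_triple, spread(c(2, 3, 4), 20))
  expect_gt(score_triple(high, 1, 1, clearance_norm = 4),
            score_triple(low, 1, 1, clearance_norm = 4))
  # w_angle = 0: ranking by min clearance alone
  expect_gt(score_triple(high, 1, 0, clearance_norm = 4),
            score_triple(low, 1, 0, clearance_norm = 4))
  expect_equal(score_triple(high, 1, 0, clearance_norm = 4), 2 / 4)
  expect_error(score_triple(high, 0, 0), "not both zero")
})

random_cft_set <- function(n) {
  lapply(seq_len(n), function(i) {
    d <- rnorm(3); d[3] <- abs(d[3]) + 0.2
    fake_trajectory(d, clearance = runif(1, 1, 6))
  })
}

test_that("select_best_triple equals brute force and ignores input order", {
  set.seed(23)
  for (rep in 1:6) {
    n <- sample(5:10, 1)
    cfts <- random_cft_set(n)
    best <- select_best_triple(cfts, m_cap = n, drill_radius = 0.5)
    # brute-force oracle over all C(n,3) triples
    norm <- max(vapply(cfts, `[[`, numeric(1), "clearance"))
    combs <- combn(n, 3)
    scores <- apply(combs, 2, function(idx) {
      score_triple(trajectory_triple(cfts[[idx[1]]], cfts[[idx[2]]],
                                     cfts[[idx[3]]]),
                   clearance_norm = norm)
    })
    expect_equal(best$score, max(scores))
    # invariance to input ordering
    perm <- sample(n)
    best2 <- select_best_triple(cfts[perm], m_cap = n, drill_radius = 0.5)
    expect_equal(best2$score, best$score)
    expect_equal(multiport:::.canonical_entries(best2),
                 multiport:::.canonical_entries(best))
  }
  # exactly three CFTs: the unique triple
  three <- random_cft_set(3)
  b3 <- select_best_triple(three, drill_radius = 0.5)
  expect_equal(sort(vapply(b3$trajectories, function(x) x$entry[1], numeric(1))),
               sort(vapply(three, function(x) x$entry[1], numeric(1))))
  expect_error(select_best_triple(random_cft_set(2)),
               class = "multiport_insufficient_cft_error")
})
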