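# Shared fixtures and independent oracles, built in code at test time.

# digitised ball label volume (voxel-centre convention)
digitized_ball <- function(radius, spacing, margin = 3) {
  n <- as.integer(ceiling(2 * radius / spacing)) + 2L * margin
  ax <- (seq_len(n) - (n + 1) / 2) * spacing
  vox <- array(0L, c(n, n, n))
  d2 <- outer(outer(ax^2, ax^2, "+"), ax^2, "+")
  vox[d2 <= radius^2] <- 1L
  label_volume(vox, spacing = rep(spacing, 3), origin = rep(ax[1], 3))
}

random_rotation <- function() {
  # QR of a random Gaussian matrix, sign-fixed to a proper rotation
  m <- matrix(rnorm(9), 3, 3)
  q <- qr.Q(qr(m))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

transform_mesh <- function(mesh, R = diag(3), t = c(0, 0, 0)) {
  structure_mesh(mesh$vertices %*% t(R) + rep(t, each = nrow(mesh$vertices)),
                 mesh$faces, name = mesh$name, label = mesh$label,
                 critical = mesh$critical)
}

# a random closed mesh (sphere/capsule/ellipsoidal sphere) under a random
# rigid placement; at most ~1300 faces
random_closed_mesh <- function() {
  kind <- sample(c("sphere", "capsule", "squashed"), 1)
  ctr <- runif(3, -10, 10)
  if (kind == "sphere") {
    icosphere_mesh(ctr, runif(1, 1, 5), subdivisions = sample(1:3, 1))
  } else if (kind == "capsule") {
    ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2)) * runif(1, 2, 8)
    capsule_mesh(ctr - ax / 2, ctr + ax / 2, runif(1, 0.5, 2.5),
                 tol = 0.05)
  } else {
    m <- icosphere_mesh(c(0, 0, 0), runif(1, 1, 4), subdivisions = 2)
    sc <- diag(runif(3, 0.5, 1.5))
    transform_mesh(m, R = random_rotation() %*% sc, t = ctr)
  }
}

random_segment <- function(scale = 20) {
  a <- runif(3, -scale, scale)
  repeat {
    b <- runif(3, -scale, scale)
    if (sum((a - b)^2) > 1) break
  }
  segment(a, b)
}

# ---------------------------------------------------------------------------
# Sampling oracles (independent of the analytic distance kernels): iterative
# grid refinement of the bilinear/trilinear parameterisation.
# ---------------------------------------------------------------------------

# min distance between a segment and a triangle by nested grid refinement
sampled_segment_triangle_distance <- function(a, b, tri, iters = 5, n = 40) {
  s_lo <- 0; s_hi <- 1
  u_lo <- 0; u_hi <- 1
  v_lo <- 0; v_hi <- 1
  best <- Inf
  for (it in seq_len(iters)) {
    s <- seq(s_lo, s_hi, length.out = n)
    u <- seq(u_lo, u_hi, length.out = n)
    v <- seq(v_lo, v_hi, length.out = n)
    g <- expand.grid(s = s, u = u, v = v)
    # barycentric fold: (u, v) with u + v > 1 mirrored into the triangle
    uu <- g$u; vv <- g$v
    over <- uu + vv > 1
    uu[over] <- 1 - uu[over]; vv[over] <- 1 - vv[over]
    P <- cbind(a[1] + g$s * (b[1] - a[1]), a[2] + g$s * (b[2] - a[2]),
               a[3] + g$s * (b[3] - a[3]))
    Q <- cbind(tri[1, 1] + uu * (tri[2, 1] - tri[1, 1]) + vv * (tri[3, 1] - tri[1, 1]),
               tri[1, 2] + uu * (tri[2, 2] - tri[1, 2]) + vv * (tri[3, 2] - tri[1, 2]),
               tri[1, 3] + uu * (tri[2, 3] - tri[1, 3]) + vv * (tri[3, 3] - tri[1, 3]))
    d <- sqrt(rowSums((P - Q)^2))
    i <- which.min(d)
    best <- min(best, d[i])
    shrink <- function(lo, hi, x) {
      w <- (hi - lo) * 2 / n
      c(max(lo, x - w), min(hi, x + w))
    }
    sr <- shrink(s_lo, s_hi, g$s[i]); s_lo <- sr[1]; s_hi <- sr[2]
    ur <- shrink(u_lo, u_hi, g$u[i]); u_lo <- ur[1]; u_hi <- ur[2]
    vr <- shrink(v_lo, v_hi, g$v[i]); v_lo <- vr[1]; v_hi <- vr[2]
  }
  best
}

# min distance between two segments by nested 2-D grid refinement
sampled_segment_segment_distance <- function(p1, q1, p2, q2, iters = 6, n = 200) {
  s_lo <- 0; s_hi <- 1; t_lo <- 0; t_hi <- 1
  best <- Inf
  for (it in seq_len(iters)) {
    s <- seq(s_lo, s_hi, length.out = n)
    tt <- seq(t_lo, t_hi, length.out = n)
    g <- expand.grid(s = s, t = tt)
    P <- cbind(p1[1] + g$s * (q1[1] - p1[1]), p1[2] + g$s * (q1[2] - p1[2]),
               p1[3] + g$s * (q1[3] - p1[3]))
    Q <- cbind(p2[1] + g$t * (q2[1] - p2[1]), p2[2] + g$t * (q2[2] - p2[2]),
               p2[3] + g$t * (q2[3] - p2[3]))
    d <- sqrt(rowSums((P - Q)^2))
    i <- which.min(d)
    best <- min(best, d[i])
    w_s <- (s_hi - s_lo) * 2 / n
    w_t <- (t_hi - t_lo) * 2 / n
    s_lo2 <- max(s_lo, g$s[i] - w_s); s_hi <- min(s_hi, g$s[i] + w_s); s_lo <- s_lo2
    t_lo2 <- max(t_lo, g$t[i] - w_t); t_hi <- min(t_hi, g$t[i] + w_t); t_lo <- t_lo2
  }
  best
}

# min over arc parameter and segment parameter for a torus arc (sampling)
sampled_arc_segment_distance <- function(prim, a, b, iters = 6, n = 300) {
  nrm <- prim$normal / sqrt(sum(prim$normal^2))
  ref <- prim$ref - sum(prim$ref * nrm) * nrm
  ref <- ref / sqrt(sum(ref^2))
  v <- c(nrm[2] * ref[3] - nrm[3] * ref[2],
         nrm[3] * ref[1] - nrm[1] * ref[3],
         nrm[1] * ref[2] - nrm[2] * ref[1])
  th_lo <- prim$angle_start * pi / 180
  th_hi <- prim$angle_end * pi / 180
  s_lo <- 0; s_hi <- 1
  best <- Inf
  for (it in seq_len(iters)) {
    th <- seq(th_lo, th_hi, length.out = n)
    s <- seq(s_lo, s_hi, length.out = n)
    g <- expand.grid(th = th, s = s)
    P <- cbind(prim$center[1] + prim$radius * (cos(g$th) * ref[1] + sin(g$th) * v[1]),
               prim$center[2] + prim$radius * (cos(g$th) * ref[2] + sin(g$th) * v[2]),
               prim$center[3] + prim$radius * (cos(g$th) * ref[3] + sin(g$th) * v[3]))
    Q <- cbind(a[1] + g$s * (b[1] - a[1]), a[2] + g$s * (b[2] - a[2]),
               a[3] + g$s * (b[3] - a[3]))
    d <- sqrt(rowSums((P - Q)^2))
    i <- which.min(d)
    best <- min(best, d[i])
    w_th <- (th_hi - th_lo) * 2 / n
    w_s <- (s_hi - s_lo) * 2 / n
    th_lo2 <- max(th_lo, g$th[i] - w_th); th_hi <- min(th_hi, g$th[i] + w_th)
    th_lo <- th_lo2
    s_lo2 <- max(s_lo, g$s[i] - w_s); s_hi <- min(s_hi, g$s[i] + w_s)
    s_lo <- s_lo2
  }
  best
}

# mesh edge bookkeeping for closedness/Euler checks, independent of
# mesh_is_closed()
edge_face_counts <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  table(key)
}

# a minimal synthetic trajectory for angle/triple tests
fake_trajectory <- function(direction, target = c(0, 0, 0), length = 30,
                            clearance = 5) {
  direction <- direction / sqrt(sum(direction^2))
  entry <- target + direction * length
  structure(list(entry = entry, target = target, direction = direction,
                 length = length, clearance = clearance,
                 closest_structure = "x", feasible = TRUE,
                 max_diameter = 2 * clearance, risk_value = NA_real_,
                 face_index = NA_integer_),
            class = "trajectory")
}
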