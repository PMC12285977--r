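test_that("world-to-pixel projection matches closed forms", {
  K1 <- camera_intrinsics(1, 1, 0, 0)
  expect_equal(world_to_pixel(c(0, 0, 1), K1), c(u = 0, v = 0))
  K2 <- camera_intrinsics(500, 500, 960, 540)
  expect_equal(world_to_pixel(c(0.1, 0, 1), K2), c(u = 1010, v = 540))
  expect_error(world_to_pixel(c(0, 0, -1), K1), "behind the camera")
})

test_that("projection equals an independent homogeneous-matrix product", {
  for (seed in 1:5) {
    R <- random_rotation(seed)
    t <- rnorm(3)
    K <- camera_intrinsics(400 + 100 * seed, 420, 950, 530)
    P <- c(rnorm(2), runif(1, 2, 5))
    Pc <- R %*% P + t
    if (Pc[3] <= 0) next
    M <- K$K %*% cbind(R, t)   # 3x4 projection matrix
    h <- M %*% c(P, 1)
    expect_equal(world_to_pixel(P, K, rigid_transform(R, t)),
                 c(u = h[1] / h[3], v = h[2] / h[3]), tolerance = 1e-10)
  }
})

test_that("gaze mapping recovers known coefficient matrices", {
  grid <- as.matrix(expand.grid(x = c(-1, 0, 1), y = c(-1, 0, 1)))
  # identity-like mapping u = x, v = y
  m <- fit_gaze_mapping(grid, grid)
  truth <- rbind(c(0, 1, 0, 0, 0, 0), c(0, 0, 1, 0, 0, 0))
  expect_equal(m$coefficients, truth, tolerance = 1e-9, ignore_attr = TRUE)

  set.seed(10)
  C <- matrix(rnorm(12), 2, 6)
  pts <- cbind(runif(12, -2, 2), runif(12, -2, 2))
  px <- t(C %*% t(cbind(1, pts[, 1], pts[, 2], pts[, 1]^2, pts[, 2]^2,
                        pts[, 1] * pts[, 2])))
  m2 <- fit_gaze_mapping(pts, px)
  expect_equal(m2$coefficients, C, tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(apply_gaze_mapping(m2, pts), px, tolerance = 1e-6,
               ignore_attr = TRUE)

  expect_error(fit_gaze_mapping(pts[1:5, ], px[1:5, ]), "at least 6")
  col <- cbind(seq(0, 1, length.out = 8), seq(0, 2, length.out = 8))
  expect_error(fit_gaze_mapping(col, col), "degenerate")
})

test_that("pixel back-projection inverts the projection at true depth", {
  K <- camera_intrinsics(500, 480, 960, 540)
  expect_equal(pixel_to_camera(960, 540, K, depth = 2), c(0, 0, 2))
  for (seed in 1:5) {
    set.seed(seed)
    Pc <- c(rnorm(2), runif(1, 1, 4))
    uv <- world_to_pixel(Pc, K)   # identity pose
    back <- pixel_to_camera(uv["u"], uv["v"], K, depth = Pc[3])
    expect_equal(back, Pc, tolerance = 1e-9, ignore_attr = TRUE)
    # direct formula oracle
    u <- runif(1, 0, 1920); v <- runif(1, 0, 1080); z <- runif(1, 0.5, 3)
    expect_equal(pixel_to_camera(u, v, K, z),
                 z * c((u - 960) / 500, (v - 540) / 480, 1))
  }
  expect_error(pixel_to_camera(0, 0, K, depth = 0), "depth")
  expect_error(pixel_to_camera(0, 0, K, depth = NA), "depth")
})

test_that("camera-to-robot transform is the homogeneous product", {
  expect_equal(camera_to_robot(c(1, 2, 3), rigid_transform()), c(1, 2, 3))
  Tt <- rigid_transform(diag(3), c(0, 0, 0.5))
  expect_equal(camera_to_robot(c(1, 1, 1), Tt), c(1, 1, 1.5))
  for (seed in 1:4) {
    R <- random_rotation(seed + 50)
    t <- rnorm(3)
    P <- rnorm(3)
    H <- rbind(cbind(R, t), c(0, 0, 0, 1))
    expect_equal(camera_to_robot(P, rigid_transform(R, t)),
                 as.numeric((H %*% c(P, 1))[1:3]), tolerance = 1e-12)
  }
})

test_that("the full coordinate chain round-trips to 1e-9", {
  for (seed in 1:5) {
    R <- random_rotation(seed); t <- c(0, 0, 2) + rnorm(3, sd = 0.1)
    pose <- rigid_transform(R, t)
    K <- camera_intrinsics(520, 510, 945, 535)
    T_ch <- rigid_transform(random_rotation(seed + 9), rnorm(3))
    P_world <- c(rnorm(2, sd = 0.3), runif(1, 0.5, 1.5))
    Pc <- as.numeric(R %*% P_world + t)
    if (Pc[3] <= 0) next
    uv <- world_to_pixel(P_world, K, pose)
    back <- pixel_to_camera(uv["u"], uv["v"], K, depth = Pc[3])
    expect_equal(camera_to_robot(back, T_ch), camera_to_robot(Pc, T_ch),
                 tolerance = 1e-9, ignore_attr = TRUE)
  }
})

test_that("gaze-pause waypoints come from sufficiently long fixation runs", {
  s <- simulate_gaze(fig4_scenario(), seed = 0)
  wp <- extract_waypoints(s, min_pause = 0.4)
  expect_equal(nrow(wp), 4)   # the four fixation episodes
  expect_true(all(diff(wp$t_start) > 0))
  # waypoints sit at their run centroids
  runs <- rle(as.character(s$label))
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  fix1 <- starts[1]:ends[1]
  expect_equal(wp$u[1], mean(s$x[fix1]))

  all_sac <- labeled_sequence(gaze_sequence((0:9) / 90, 1:10, 1:10),
                              rep("saccade", 10))
  expect_equal(nrow(extract_waypoints(all_sac)), 0)
  # min_pause = 0: one waypoint per fixation run
  wp0 <- extract_waypoints(s, min_pause = 0)
  expect_equal(nrow(wp0), sum(runs$values == "fixation"))
})

test_that("trajectory metrics honour their closed forms", {
  line <- cbind(0:5, 2 * (0:5), 0:5)
  tm <- trajectory_metrics(line)
  expect_equal(tm$curvature, rep(0, 4))
  expect_equal(tm$angular_rate, rep(0, 4))
  expect_true(tm$smooth_feasible)

  # unit steps turning 90 degrees: squared sine of the angle is 1
  corner <- rbind(c(0, 0), c(1, 0), c(1, 1))
  tc <- trajectory_metrics(corner)
  expect_equal(tc$angular_rate, 1)
  expect_equal(tc$curvature, 1)  # ||v1 x v2|| / ||v1||^3 = 1

  # alternative angular-rate reading
  tc2 <- trajectory_metrics(corner, variant = "normalized_cross")
  expect_equal(tc2$angular_rate, 1)
  expect_error(trajectory_metrics(corner[1:2, ]), "3 points")
})

test_that("curvature converges to 1/r on a circle and scales as 1/s", {
  r <- 2
  th <- seq(0, pi / 2, length.out = 400)
  circ <- cbind(r * cos(th), r * sin(th))
  tm <- trajectory_metrics(circ)
  expect_equal(tm$mean_curvature, 1 / r, tolerance = 1e-3)

  set.seed(15)
  P <- cbind(cumsum(rnorm(12)), cumsum(rnorm(12)), cumsum(rnorm(12)))
  t0 <- trajectory_metrics(P)
  # rigid motion invariance
  R <- random_rotation(33)
  Pr <- t(R %*% t(P)) + matrix(c(5, -2, 1), 12, 3, byrow = TRUE)
  t1 <- trajectory_metrics(Pr)
  expect_equal(t1$curvature, t0$curvature, tolerance = 1e-9)
  expect_equal(t1$angular_rate, t0$angular_rate, tolerance = 1e-9)
  # uniform scaling by s divides curvature by s, leaves angles unchanged
  t2 <- trajectory_metrics(P * 4)
  expect_equal(t2$curvature, t0$curvature / 4, tolerance = 1e-9)
  expect_equal(t2$angular_rate, t0$angular_rate, tolerance = 1e-9)
})

test_that("calibration bundles round-trip through structured text", {
  K <- camera_intrinsics(512.25, 498.5, 959.1, 541.9)
  pose <- rigid_transform(random_rotation(3), c(0.1, -0.2, 1.5))
  T_ch <- rigid_transform(random_rotation(8), c(0.4, 0, -0.1))
  grid <- as.matrix(expand.grid(x = -1:1, y = -1:1))
  mp <- fit_gaze_mapping(grid, grid * 100 + 500)
  f <- withr::local_tempfile(fileext = ".yaml")
  write_calibration(K, pose, T_ch, mp, f)
  cal <- read_calibration(f)
  expect_equal(cal$K$K, K$K, tolerance = 1e-12)
  expect_equal(cal$pose$R, pose$R, tolerance = 1e-12)
  expect_equal(cal$T_ch$t, T_ch$t, tolerance = 1e-12)
  expect_equal(cal$mapping$coefficients, mp$coefficients, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("rigid transforms reject improper rotations", {
  expect_error(rigid_transform(diag(c(1, 1, -1))), "proper rotation")
  expect_error(rigid_transform(matrix(1, 3, 3)), "proper rotation")
})
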