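#' Pinhole camera intrinsics
#'
#' @param fx,fy Focal lengths in pixels (> 0).
#' @param cx,cy Principal point offsets in pixels.
#' @return A list of class `camera_intrinsics` with the 3x3 matrix `K`.
#' @export
camera_intrinsics <- function(fx, fy, cx, cy) {
  if (fx <= 0 || fy <= 0) stop("focal lengths must be positive")
  K <- matrix(c(fx, 0, cx,
                0, fy, cy,
                0, 0, 1), 3, 3, byrow = TRUE)
  structure(list(fx = fx, fy = fy, cx = cx, cy = cy, K = K),
            class = "camera_intrinsics")
}

#' Rigid transform (rotation + translation)
#'
#' @param R 3x3 rotation matrix (orthonormal, det +1, tolerance 1e-9).
#' @param t Length-3 translation vector (meters).
#' @return A list of class `rigid_transform`.
#' @export
rigid_transform <- function(R = diag(3), t = c(0, 0, 0)) {
  R <- as.matrix(R)
  if (!all(dim(R) == c(3, 3)) || length(t) != 3)
    stop("R must be 3x3 and t length 3")
  if (max(abs(crossprod(R) - diag(3))) > 1e-9 || abs(det(R) - 1) > 1e-9)
    stop("R must be a proper rotation (R'R = I, det R = 1)")
  structure(list(R = R, t = as.numeric(t)), class = "rigid_transform")
}

#' Project a world point to pixel coordinates
#'
#' Applies the camera pose (`P_camera = R P + t`) and perspective division
#' through the intrinsics.
#'
#' @param P Length-3 world point (meters).
#' @param K A [camera_intrinsics()].
#' @param pose A [rigid_transform()] (world-to-camera).
#' @return Named vector `c(u, v)` in pixels.
#' @export
world_to_pixel <- function(P, K, pose = rigid_transform()) {
  Pc <- as.numeric(pose$R %*% P + pose$t)
  if (Pc[3] <= 0) stop("point is behind the camera (Z <= 0)")
  uvw <- as.numeric(K$K %*% Pc)
  c(u = uvw[1] / uvw[3], v = uvw[2] / uvw[3])
}

#' Fit a second-degree polynomial gaze mapping
#'
#' Least-squares fit of the 2x6 coefficient matrix mapping eye-tracker gaze
#' coordinates (x, y) to pixel coordinates (u, v) through the basis
#' `(1, x, y, x^2, y^2, xy)`. The fit is exact (residual ~ 0) when the data
#' come noiselessly from some coefficient matrix.
#'
#' @param eye_points n x 2 matrix of gaze coordinates (n >= 6).
#' @param pixel_points n x 2 matrix of pixel coordinates.
#' @return A list of class `gaze_mapping` with the 2x6 `coefficients`.
#' @export
fit_gaze_mapping <- function(eye_points, pixel_points) {
  E <- as.matrix(eye_points); P <- as.matrix(pixel_points)
  if (nrow(E) < 6) stop("at least 6 calibration point pairs are required")
  if (nrow(E) != nrow(P)) stop("point lists must have equal length")
  B <- gaze_basis(E[, 1], E[, 2])
  if (qr(B)$rank < 6)
    stop("calibration points are degenerate (rank-deficient basis)")
  coef <- t(qr.solve(B, P))   # 2 x 6
  structure(list(coefficients = coef), class = "gaze_mapping")
}

gaze_basis <- function(x, y) cbind(1, x, y, x^2, y^2, x * y)

#' Apply a fitted gaze mapping
#'
#' @param mapping A [fit_gaze_mapping()] result.
#' @param xy n x 2 matrix (or length-2 vector) of gaze coordinates.
#' @return n x 2 matrix of pixel coordinates (u, v).
#' @export
apply_gaze_mapping <- function(mapping, xy) {
  if (is.null(dim(xy))) xy <- matrix(xy, ncol = 2)
  B <- gaze_basis(xy[, 1], xy[, 2])
  out <- B %*% t(mapping$coefficients)
  colnames(out) <- c("u", "v")
  out
}

#' Back-project a pixel to a camera-frame 3D point at known depth
#'
#' Normalises the pixel through the intrinsics
#' (`x_norm = (u - cx)/fx`, `y_norm = (v - cy)/fy`) and scales the ray by
#' the depth: `P_camera = depth * (x_norm, y_norm, 1)`.
#'
#' @param u,v Pixel coordinates.
#' @param K A [camera_intrinsics()].
#' @param depth Depth along the optical axis in meters (> 0, finite); a
#'   missing or non-positive depth-map value is an error.
#' @return Length-3 camera-frame point.
#' @export
pixel_to_camera <- function(u, v, K, depth) {
  if (!is.finite(depth) || depth <= 0)
    stop("depth must be a positive finite value (missing depth-map value?)")
  c((u - K$cx) / K$fx, (v - K$cy) / K$fy, 1) * depth
}

#' Transform a camera-frame point to the robot frame
#'
#' Homogeneous application of the camera-to-hand calibration transform.
#'
#' @param P Length-3 camera-frame point.
#' @param T_ch A [rigid_transform()] (camera to hand/robot).
#' @return Length-3 robot-frame point.
#' @export
camera_to_robot <- function(P, T_ch) {
  as.numeric(T_ch$R %*% P + T_ch$t)
}

#' Extract gaze-pause waypoints from a labelled sequence
#'
#' Contiguous fixation (pause) runs lasting at least `min_pause` seconds
#' become waypoints at their coordinate centroid, in temporal order. A brief
#' pause on an object is how a gaze trajectory marks a grasp target.
#'
#' @param seq A `labeled_sequence`.
#' @param min_pause Minimum pause duration in seconds (default 0.5).
#' @return Data.frame with columns `u`, `v` (centroids, px), `t_start`,
#'   `t_end`; zero rows when no pause qualifies.
#' @export
extract_waypoints <- function(seq, min_pause = 0.5) {
  if (is.null(seq$label)) stop("a labelled sequence is required")
  runs <- label_runs(as.character(seq$label))
  runs <- runs[runs$value == "fixation", , drop = FALSE]
  out <- data.frame(u = numeric(0), v = numeric(0),
                    t_start = numeric(0), t_end = numeric(0))
  for (r in seq_len(nrow(runs))) {
    idx <- runs$start[r]:runs$end[r]
    dur <- seq$t[runs$end[r]] - seq$t[runs$start[r]]
    if (dur >= min_pause)
      out[nrow(out) + 1L, ] <- c(mean(seq$x[idx]), mean(seq$y[idx]),
                                 seq$t[runs$start[r]], seq$t[runs$end[r]])
  }
  out
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Discrete trajectory smoothness metrics
#'
#' For each interior point `p_i` with `v1 = p_i - p_{i-1}` and
#' `v2 = p_{i+1} - p_i`: curvature
#' `kappa_i = ||v1 x v2|| / ||v1||^3` (0 when `||v1|| = 0`), and the angular
#' variation rate, by default the squared sine of the inter-tangent angle
#' `(||v1 x v2|| / (||v1|| ||v2||))^2`; the alternative reading
#' `||v1 x v2|| / (||v1|| ||v2||^2)` is selectable. 2-D input is lifted to
#' 3-D with Z = 0. The mean curvature is checked against the 3 m^-1
#' smoothness threshold used for feasible robot trajectories.
#'
#' @param points n x 3 (or n x 2) matrix of path points, n >= 3.
#' @param variant `"squared_sine"` (default) or `"normalized_cross"` for the
#'   angular-rate formula.
#' @return A list of class `trajectory_metrics`: `curvature` and
#'   `angular_rate` per interior point, their means and SDs, and
#'   `smooth_feasible` (mean curvature below 3 m^-1).
#' @export
trajectory_metrics <- function(points,
                               variant = c("squared_sine",
                                           "normalized_cross")) {
  variant <- match.arg(variant)
  P <- as.matrix(points)
  if (nrow(P) < 3) stop("at least 3 points are required")
  if (ncol(P) == 2) P <- cbind(P, 0)
  n <- nrow(P)
  kappa <- numeric(n - 2); theta <- numeric(n - 2)
  for (i in 2:(n - 1)) {
    v1 <- P[i, ] - P[i - 1, ]
    v2 <- P[i + 1, ] - P[i, ]
    n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
    cr <- sqrt(sum(cross3(v1, v2)^2))
    kappa[i - 1] <- if (n1 > 0) cr / n1^3 else 0
    theta[i - 1] <- if (n1 > 0 && n2 > 0) {
      if (variant == "squared_sine") (cr / (n1 * n2))^2
      else cr / (n1 * n2^2)
    } else 0
  }
  structure(list(curvature = kappa, angular_rate = theta,
                 mean_curvature = mean(kappa),
                 sd_curvature = stats::sd(kappa),
                 mean_angular_rate = mean(theta),
                 sd_angular_rate = stats::sd(theta),
                 smooth_feasible = mean(kappa) < 3),
            class = "trajectory_metrics")
}

#' Write a calibration bundle (intrinsics, pose, hand-eye transform,
#' gaze mapping) as structured text
#'
#' @param K A [camera_intrinsics()].
#' @param pose,T_ch [rigid_transform()] objects (world-to-camera pose and
#'   camera-to-hand calibration).
#' @param mapping A [fit_gaze_mapping()] result (optional).
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_calibration <- function(K, pose, T_ch, mapping = NULL, path) {
  lst <- list(
    intrinsics = list(fx = K$fx, fy = K$fy, cx = K$cx, cy = K$cy),
    pose = list(R = apply(pose$R, 1, as.numeric, simplify = FALSE),
                t = pose$t),
    hand_eye = list(R = apply(T_ch$R, 1, as.numeric, simplify = FALSE),
                    t = T_ch$t))
  if (!is.null(mapping))
    lst$gaze_mapping <- apply(mapping$coefficients, 1, as.numeric,
                              simplify = FALSE)
  writeLines(yaml::as.yaml(lst, precision = 15), path)
  invisible(path)
}

#' Read a calibration bundle written by [write_calibration()]
#' @param path YAML path.
#' @return List with `K`, `pose`, `T_ch` and optionally `mapping`.
#' @export
read_calibration <- function(path) {
  lst <- yaml::read_yaml(path)
  out <- list(
    K = camera_intrinsics(lst$intrinsics$fx, lst$intrinsics$fy,
                          lst$intrinsics$cx, lst$intrinsics$cy),
    pose = rigid_transform(do.call(rbind, lapply(lst$pose$R, as.numeric)),
                           as.numeric(lst$pose$t)),
    T_ch = rigid_transform(
      do.call(rbind, lapply(lst$hand_eye$R, as.numeric)),
      as.numeric(lst$hand_eye$t)))
  if (!is.null(lst$gaze_mapping))
    out$mapping <- structure(
      list(coefficients = do.call(rbind, lapply(lst$gaze_mapping,
                                                as.numeric))),
      class = "gaze_mapping")
  out
}
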