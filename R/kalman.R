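#' Constant-acceleration Kalman filter configuration
#'
#' State per in-plane axis is `[position, velocity, acceleration]`; the
#' two axes are stacked into a 6-state filter. `F` is the standard
#' constant-acceleration kinematics matrix for time step `dt`, the process
#' noise `Q` is the white-jerk model with spectral density `q`, the
#' observation `H` selects the two positions, and `R` is isotropic
#' observation noise. The dynamics input is zero by default (`G = 0`,
#' `u = 0`).
#'
#' The default `q` (4000 mm^2/s^5) is chosen so that the filter bandwidth,
#' roughly `(q/r)^(1/6)` rad/s for a constant-acceleration tracker, is
#' about 4 rad/s - comfortably above respiratory frequencies (~1.6 rad/s
#' for a 4 s breathing period) while still well below the frame-rate
#' Nyquist limit, so breathing is followed without lag while most
#' measurement noise is rejected.
#'
#' @param dt time between frames in s (> 0).
#' @param q white-jerk process-noise spectral density, mm^2/s^5.
#' @param r_var observation-noise variance per axis, mm^2.
#' @param p0 initial error-covariance diagonal (uninformative start).
#' @param G,u optional input matrix and control vector (defaults zero).
#' @param joseph use the Joseph-form covariance update for extra numerical
#'   robustness (off by default; the plain `(I - KH) P` form is standard).
#' @return A `kf_config` object with elements `F`, `G`, `u`, `Q`, `H`,
#'   `R`, `P0`, `dt`.
#' @export
kf_config <- function(dt = 1 / 15, q = 4000, r_var = 1, p0 = 1e4,
                      G = NULL, u = NULL, joseph = FALSE) {
  if (dt <= 0) stop("dt must be > 0")
  F1 <- matrix(c(1, dt, dt^2 / 2,
                 0, 1, dt,
                 0, 0, 1), 3, 3, byrow = TRUE)
  Q1 <- q * matrix(c(dt^5 / 20, dt^4 / 8, dt^3 / 6,
                     dt^4 / 8,  dt^3 / 3, dt^2 / 2,
                     dt^3 / 6,  dt^2 / 2, dt), 3, 3, byrow = TRUE)
  Fm <- rbind(cbind(F1, matrix(0, 3, 3)), cbind(matrix(0, 3, 3), F1))
  Qm <- rbind(cbind(Q1, matrix(0, 3, 3)), cbind(matrix(0, 3, 3), Q1))
  H <- matrix(0, 2, 6)
  H[1, 1] <- 1
  H[2, 4] <- 1
  if (is.null(G)) G <- matrix(0, 6, 1)
  if (is.null(u)) u <- matrix(0, nrow = ncol(G), ncol = 1)
  cfg <- list(F = Fm, G = G, u = u, Q = Qm, H = H,
              R = diag(r_var, 2), P0 = diag(p0, 6), dt = dt,
              joseph = joseph)
  class(cfg) <- "kf_config"
  validate_kf_config(cfg)
  cfg
}

validate_kf_config <- function(cfg) {
  sym_psd <- function(M) {
    isTRUE(all.equal(M, t(M))) && all(eigen(M, TRUE, TRUE)$values > -1e-10)
  }
  if (!sym_psd(cfg$Q) || !sym_psd(cfg$R) || !sym_psd(cfg$P0))
    stop("Q, R and P0 must be symmetric positive semi-definite")
  invisible(cfg)
}

new_kf_state <- function(x, P, k) {
  structure(list(x = x, P = (P + t(P)) / 2, k = k), class = "kf_state")
}

#' Kalman prediction step
#'
#' The time update: `x_kp = F x_{k-1} + G u` and
#' `P_kp = F P_{k-1} F' + Q`.
#'
#' @param state a `kf_state` (elements `x`, `P`, `k`).
#' @param cfg a [kf_config()].
#' @return List with predicted `x_kp` and `P_kp`.
#' @export
kf_predict <- function(state, cfg) {
  x_kp <- cfg$F %*% state$x + cfg$G %*% cfg$u
  P_kp <- cfg$F %*% state$P %*% t(cfg$F) + cfg$Q
  list(x_kp = x_kp, P_kp = P_kp)
}

#' Kalman measurement update
#'
#' The correction: gain `K = P_kp H' (H P_kp H' + R)^{-1}`, state
#' `x_k = x_kp + K (z_k - H x_kp)`, covariance `P_k = (I - K H) P_kp`
#' (Joseph form optionally). The covariance is symmetrized after the
#' update.
#'
#' @param x_kp,P_kp predicted state and covariance from [kf_predict()].
#' @param z_k measured 2D position, `c(u, v)` in mm.
#' @param cfg a [kf_config()].
#' @param k frame index recorded on the returned state.
#' @return A `kf_state`.
#' @export
kf_update <- function(x_kp, P_kp, z_k, cfg, k = NA_integer_) {
  H <- cfg$H
  S <- H %*% P_kp %*% t(H) + cfg$R
  if (abs(det(S)) < 1e-300) stop("singular innovation covariance")
  K <- P_kp %*% t(H) %*% solve(S)
  x <- x_kp + K %*% (matrix(z_k, ncol = 1) - H %*% x_kp)
  P <- if (isTRUE(cfg$joseph)) {
    A <- diag(nrow(P_kp)) - K %*% H
    A %*% P_kp %*% t(A) + K %*% cfg$R %*% t(K)
  } else {
    (diag(nrow(P_kp)) - K %*% H) %*% P_kp
  }
  new_kf_state(x, P, k)
}

#' Estimate ground-truth positions from a noisy track
#'
#' Forward-filters the tracked positions with the constant-acceleration
#' Kalman filter: the state is initialized at the first non-missing
#' measurement (zero velocity and acceleration, uninformative covariance),
#' and each subsequent frame receives a prediction step followed, when the
#' frame was tracked, by a measurement correction; missing frames are
#' prediction-only. The filtered position sequence is the estimated ground
#' truth. Frames before the first measurement are backfilled with the
#' initial position.
#'
#' @param track a [track_sequence()] result, or any data.frame with
#'   `u_mm`, `v_mm` and `missing` columns.
#' @param cfg a [kf_config()]; when `NULL`, a default configuration with
#'   `dt` from the track's timestamps (if present) or 1/15 s.
#' @return Data.frame `frame_index`, `u_mm`, `v_mm` of the estimated
#'   ground-truth trajectory, with the per-frame state estimates in
#'   attribute `"states"`.
#' @export
estimate_ground_truth <- function(track, cfg = NULL) {
  ok <- !track$missing & is.finite(track$u_mm) & is.finite(track$v_mm)
  if (!any(ok)) stop("all frames missing: cannot estimate ground truth")
  if (is.null(cfg)) {
    dt <- if (!is.null(track$time_s) && nrow(track) > 1)
      stats::median(diff(track$time_s)) else 1 / 15
    cfg <- kf_config(dt = dt)
  }
  n <- nrow(track)
  first <- which(ok)[1]
  x <- matrix(0, 6, 1)
  x[1] <- track$u_mm[first]
  x[4] <- track$v_mm[first]
  state <- new_kf_state(x, cfg$P0, first)
  est <- matrix(NA_real_, n, 2)
  est[seq_len(first), ] <- rep(c(x[1], x[4]), each = first)
  xs <- matrix(NA_real_, n, 6)
  xs[first, ] <- as.numeric(x)
  if (first < n) for (k in (first + 1):n) {
    pr <- kf_predict(state, cfg)
    if (ok[k]) {
      state <- kf_update(pr$x_kp, pr$P_kp,
                         c(track$u_mm[k], track$v_mm[k]), cfg, k)
    } else {
      state <- new_kf_state(pr$x_kp, pr$P_kp, k)
    }
    est[k, ] <- state$x[c(1, 4)]
    xs[k, ] <- as.numeric(state$x)
  }
  out <- data.frame(frame_index = seq_len(n), u_mm = est[, 1],
                    v_mm = est[, 2])
  attr(out, "states") <- xs
  out
}
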