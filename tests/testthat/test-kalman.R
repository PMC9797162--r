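test_that("prediction follows the state-transition equations", {
  # identity dynamics: prediction equals the previous state
  cfg_id <- list(F = diag(2), G = matrix(0, 2, 1), u = matrix(0, 1, 1),
                 Q = matrix(0, 2, 2), H = diag(2), R = diag(2),
                 joseph = FALSE)
  st <- detrack:::new_kf_state(matrix(c(3, -1), 2, 1), diag(2), 1)
  pr <- kf_predict(st, cfg_id)
  expect_equal(pr$x_kp, matrix(c(3, -1), 2, 1))
  expect_equal(pr$P_kp, diag(2))

  # scalar constant-velocity toy: x = (0, 1), dt = 1 -> position 1
  cfg_cv <- list(F = matrix(c(1, 0, 1, 1), 2, 2), G = matrix(0, 2, 1),
                 u = matrix(0, 1, 1), Q = matrix(0, 2, 2),
                 H = matrix(c(1, 0), 1, 2), R = diag(1) * 0.1,
                 joseph = FALSE)
  pr2 <- kf_predict(detrack:::new_kf_state(matrix(c(0, 1)), diag(2), 1),
                    cfg_cv)
  expect_equal(pr2$x_kp[1, 1], 1)

  # exact constant-acceleration motion is predicted with zero error
  cfg <- kf_config(dt = 0.2, q = 0)
  a_u <- 1.5; a_v <- -0.8
  t <- 0
  state <- detrack:::new_kf_state(
    matrix(c(0, 0, a_u, 0, 0, a_v), 6, 1), diag(6) * 0, 1)
  for (k in 1:10) {
    pr <- kf_predict(state, cfg)
    t <- t + 0.2
    expect_equal(pr$x_kp[1, 1], 0.5 * a_u * t^2, tolerance = 1e-12)
    expect_equal(pr$x_kp[4, 1], 0.5 * a_v * t^2, tolerance = 1e-12)
    state <- detrack:::new_kf_state(pr$x_kp, pr$P_kp, k)
  }
})

test_that("measurement update behaves in the R -> 0 and R -> Inf limits", {
  scalar_cfg <- function(r) list(F = matrix(1), G = matrix(0), u = matrix(0),
                                 Q = matrix(0.01), H = matrix(1),
                                 R = matrix(r), joseph = FALSE)
  x_kp <- matrix(2); P_kp <- matrix(1)
  lo <- kf_update(x_kp, P_kp, 5, scalar_cfg(1e-12))
  expect_equal(lo$x[1, 1], 5, tolerance = 1e-9)
  hi <- kf_update(x_kp, P_kp, 5, scalar_cfg(1e12))
  expect_equal(hi$x[1, 1], 2, tolerance = 1e-9)
})

test_that("three scalar steps match a hand-computed trace to 1e-12", {
  # plain scalar filter: F = 1, Q = 0.5, H = 1, R = 2, P0 = 10, x0 = 0
  cfg <- list(F = matrix(1), G = matrix(0), u = matrix(0), Q = matrix(0.5),
              H = matrix(1), R = matrix(2), joseph = FALSE)
  z <- c(1.2, -0.4, 0.9)
  x <- 0; P <- 10
  state <- detrack:::new_kf_state(matrix(x), matrix(P), 0)
  for (k in 1:3) {
    pr <- kf_predict(state, cfg)
    state <- kf_update(pr$x_kp, pr$P_kp, z[k], cfg, k)
    # spreadsheet arithmetic, written out independently
    Pp <- P + 0.5
    K <- Pp / (Pp + 2)
    x <- x + K * (z[k] - x)
    P <- (1 - K) * Pp
    expect_equal(state$x[1, 1], x, tolerance = 1e-12)
    expect_equal(state$P[1, 1], P, tolerance = 1e-12)
  }
  # singular innovation covariance errors
  bad <- list(F = matrix(1), G = matrix(0), u = matrix(0), Q = matrix(0),
              H = matrix(0), R = matrix(0), joseph = FALSE)
  expect_error(kf_update(matrix(1), matrix(1), 0, bad), "singular")
})

test_that("covariance stays symmetric PSD through long filtering", {
  cfg <- kf_config(dt = 1 / 15)
  set.seed(3)
  track <- data.frame(u_mm = cumsum(rnorm(200, 0, 0.3)),
                      v_mm = cumsum(rnorm(200, 0, 0.3)),
                      missing = rep(c(FALSE, FALSE, FALSE, TRUE), 50))
  est <- estimate_ground_truth(track, cfg)
  expect_equal(nrow(est), 200)
  # re-run manually to inspect P at every step
  state <- detrack:::new_kf_state(matrix(c(track$u_mm[1], 0, 0,
                                           track$v_mm[1], 0, 0)),
                                  cfg$P0, 1)
  for (k in 2:200) {
    pr <- kf_predict(state, cfg)
    state <- if (!track$missing[k])
      kf_update(pr$x_kp, pr$P_kp, c(track$u_mm[k], track$v_mm[k]), cfg, k)
    else detrack:::new_kf_state(pr$x_kp, pr$P_kp, k)
    expect_equal(state$P, t(state$P))
    expect_gt(min(eigen(state$P, TRUE, TRUE)$values), -1e-10)
  }
})

test_that("the filter is axis-separable for diagonal Q and R", {
  cfg <- kf_config(dt = 0.1, q = 50, r_var = 0.8)
  set.seed(4)
  track <- data.frame(u_mm = sin(seq(0, 4, 0.1)) * 5 + rnorm(41, 0, 0.5),
                      v_mm = cos(seq(0, 4, 0.1)) * 7 + rnorm(41, 0, 0.5),
                      missing = FALSE)
  joint <- estimate_ground_truth(track, cfg)
  only_u <- estimate_ground_truth(
    data.frame(u_mm = track$u_mm, v_mm = 0 * track$v_mm, missing = FALSE),
    cfg)
  expect_equal(joint$u_mm, only_u$u_mm, tolerance = 1e-10)
})

test_that("ground-truth estimation handles stationary and gappy tracks", {
  # constant measurements converge to the true position
  track <- data.frame(u_mm = rep(3, 30), v_mm = rep(-2, 30),
                      missing = FALSE)
  est <- estimate_ground_truth(track, kf_config(dt = 1 / 15))
  expect_lt(abs(est$u_mm[25] - 3), 1e-6)
  expect_lt(abs(est$v_mm[25] + 2), 1e-6)

  # every second frame missing on a constant-velocity track: predictions
  # interpolate within 10% of the per-step displacement
  n <- 60
  dt <- 0.1
  truth <- 0.8 * dt * (seq_len(n) - 1)
  track2 <- data.frame(u_mm = truth, v_mm = 0, missing = FALSE)
  track2$missing[seq(2, n, by = 2)] <- TRUE
  track2$u_mm[track2$missing] <- NA
  est2 <- estimate_ground_truth(track2, kf_config(dt = dt, q = 1,
                                                  r_var = 1e-4))
  late <- 40:60
  expect_lt(max(abs(est2$u_mm[late] - truth[late])), 0.1 * 0.8 * dt)

  expect_error(estimate_ground_truth(
    data.frame(u_mm = NA_real_, v_mm = NA_real_, missing = TRUE)),
    "all frames missing")
})

test_that("KF estimates beat raw noisy measurements on breathing motion", {
  # sinusoidal trajectory + 1 mm Gaussian noise; the filtered RMSE must
  # undercut the raw-measurement RMSE in nearly all seeded repeats
  n <- 150; dt <- 1 / 15
  t <- (seq_len(n) - 1) * dt
  wins <- 0
  reps <- 30
  for (r in seq_len(reps)) {
    set.seed(1000 + r)
    tru_u <- 2 * cos(2 * pi * t / 4)
    tru_v <- 8 * cos(2 * pi * t / 4)
    track <- data.frame(u_mm = tru_u + rnorm(n), v_mm = tru_v + rnorm(n),
                        missing = FALSE)
    est <- estimate_ground_truth(track, kf_config(dt = dt))
    rmse_kf <- sqrt(mean((est$u_mm - tru_u)^2 + (est$v_mm - tru_v)^2))
    rmse_raw <- sqrt(mean((track$u_mm - tru_u)^2 +
                            (track$v_mm - tru_v)^2))
    if (rmse_kf < rmse_raw) wins <- wins + 1
  }
  expect_gte(wins, ceiling(0.95 * reps))
})

test_that("steady-state posterior variance undercuts measurement variance", {
  cfg <- list(F = matrix(1), G = matrix(0), u = matrix(0), Q = matrix(0.1),
              H = matrix(1), R = matrix(2), joseph = FALSE)
  P <- 10
  state <- detrack:::new_kf_state(matrix(0), matrix(P), 0)
  for (k in 1:100) {
    pr <- kf_predict(state, cfg)
    state <- kf_update(pr$x_kp, pr$P_kp, 0, cfg, k)
  }
  # closed-form steady state of the scalar filter:
  # P* = (-q + sqrt(q^2 + 4 q r)) / 2 with q = 0.1, r = 2
  pstar <- (-0.1 + sqrt(0.1^2 + 4 * 0.1 * 2)) / 2
  expect_equal(state$P[1, 1], pstar, tolerance = 1e-8)
  expect_lt(state$P[1, 1], 2)
})
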