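test_that("the zero-phase Butterworth filter has the stated response", {
  fs <- 1000
  t <- seq(0, 2, by = 1 / fs)
  expect_lt(max(abs(lowpass_filter(rep(3.7, length(t)), fs) - 3.7)), 1e-7)
  # 1 Hz passes essentially unattenuated
  s1 <- sin(2 * pi * 1 * t)
  f1 <- lowpass_filter(s1, fs)
  mid <- t > 0.3 & t < 1.7
  expect_lt(max(abs(f1[mid] - s1[mid])), 0.01)
  # 50 Hz is crushed below 5%
  s50 <- sin(2 * pi * 50 * t)
  f50 <- lowpass_filter(s50, fs)
  expect_lt(max(abs(f50[mid])), 0.05)
  expect_error(lowpass_filter(s1, fs = 15), "twice the cutoff")
})

test_that("movement window crossings are interpolated at 5% of peak", {
  # symmetric triangle peaking at v = 1 at t = 1 over [0, 2]
  t <- seq(0, 2, by = 1e-3)
  v <- 1 - abs(t - 1)
  win <- movement_window(t, v)
  expect_equal(win[["t_on"]], 0.05, tolerance = 1e-9)
  expect_equal(win[["t_off"]], 1.95, tolerance = 1e-9)
  # scale invariance of the relative threshold
  win2 <- movement_window(t, 7.3 * v)
  expect_equal(win, win2, tolerance = 1e-12)
  # saturated profile: whole support
  win3 <- movement_window(t, rep(2, length(t)))
  expect_equal(unname(win3), c(0, 2))
  expect_error(movement_window(t, rep(0, length(t))), "no positive peak")
})

test_that("signed curvature matches circle and line closed forms", {
  dt <- 1e-3
  t <- seq(0, 1, by = dt)
  # straight line at constant speed
  k_line <- signed_curvature(0.3 * t, -0.2 * t, dt)
  expect_lt(max(abs(k_line), na.rm = TRUE), 1e-9)
  # circle of radius R at constant angular rate
  R <- 0.45
  th <- 2 * pi * t
  k_circ <- signed_curvature(R * cos(th), R * sin(th), dt)
  inner <- 5:(length(t) - 5)
  expect_equal(mean(abs(k_circ[inner])), 1 / R, tolerance = 1e-5)
  # reversing traversal flips the sign
  k_rev <- signed_curvature(rev(R * cos(th)), rev(R * sin(th)), dt)
  expect_equal(k_rev[inner], -k_circ[length(t) + 1 - inner],
               tolerance = 1e-6)
})

test_that("velocity skewness is zero for symmetric bells, signed otherwise", {
  t <- seq(0, 1, by = 1e-3)
  s <- t
  v_mj <- 30 * s^2 * (1 - s)^2  # minimum-jerk speed profile, symmetric
  expect_equal(velocity_skewness(t, v_mj), 0, tolerance = 1e-6)
  # triangle peaking at 25% of its own window
  v_tri <- ifelse(t < 0.25, t / 0.25, (1 - t) / 0.75)
  sk <- velocity_skewness(t, v_tri)
  expect_equal(sk, (0.25 - 0.05 * 0.25) / (0.25 * 0.95 + 0.75 * 0.95) - 0.5,
               tolerance = 1e-3)
  expect_lt(sk, 0)
})

test_that("windowing and filtering are idempotent on smooth profiles", {
  fs <- 1000
  t <- seq(0, 2.4, by = 1 / fs)
  v <- 0.85 * exp(-((t - 1.2) / 0.3)^2)
  f1 <- lowpass_filter(v, fs)
  f2 <- lowpass_filter(f1, fs)
  expect_lt(max(abs(f2 - f1)), 1e-6)
  w1 <- movement_window(t, f1)
  w2 <- movement_window(t, f2)
  expect_equal(w1, w2, tolerance = 1e-6)
})

test_that("trajectory metrics vanish on self-comparison and track offsets", {
  ref <- generate_reference_set(n_subjects = 3, seed = 4)
  s <- ref$trajectories[[1]]
  # a pseudo-trajectory built from subject 1's own samples
  traj <- list(t = s$t, dt = s$t[2] - s$t[1], x = s$x, z = s$z,
               x_dot = reachopt:::fd_derivative(s$x, s$t[2] - s$t[1]),
               z_dot = reachopt:::fd_derivative(s$z, s$t[2] - s$t[1]))
  m_self <- trajectory_metrics(traj, list(s), filter = FALSE)
  expect_lt(m_self$endpoint_error, 1e-9)
  expect_lt(m_self$curvature_error, 1e-9)
  expect_lt(m_self$peak_velocity_error, 0.02)
  expect_lt(m_self$skewness_error, 0.02)
  # endpoint shifted by 0.05 m against a singleton reference
  s_shift <- s; s_shift$z <- s$z + 0.05
  traj_shift <- traj; traj_shift$z <- traj$z + 0.05
  m_shift <- trajectory_metrics(traj_shift, list(s), filter = FALSE)
  expect_equal(m_shift$endpoint_error, 0.05, tolerance = 1e-9)
  expect_error(trajectory_metrics(traj, list()), "empty")
})

test_that("best_k selects smallest costs with stable tie-breaking", {
  U <- matrix(runif(36), ncol = 6)
  y <- c(3, 1, 2, 1, 5, 4)
  D <- eval_dataset(U, y)
  bk <- best_k(D, k = 3)
  expect_equal(bk$y, c(1, 1, 2))
  expect_equal(bk$indices, c(2, 4, 3))  # earlier iteration first on ties
  all6 <- best_k(D, k = 6)
  expect_equal(all6$y, sort(y))
  expect_error(best_k(D, k = 7), "exceeds")
})

test_that("compare_runs reproduces the textbook t statistic", {
  a <- c(1.1, 1.3, 0.9)
  b <- c(2.0, 2.2, 1.9)
  res <- compare_runs(a, b)
  # hand-computed Welch statistic
  se <- sqrt(var(a) / 3 + var(b) / 3)
  t_hand <- (mean(a) - mean(b)) / se
  expect_equal(res$t, t_hand, tolerance = 1e-12)
  df_hand <- se^4 / ((var(a) / 3)^2 / 2 + (var(b) / 3)^2 / 2)
  expect_equal(res$df, df_hand, tolerance = 1e-12)
  expect_equal(res$p, 2 * pt(-abs(t_hand), df_hand), tolerance = 1e-12)
  # symmetry
  res_swap <- compare_runs(b, a)
  expect_equal(res_swap$t, -res$t)
  expect_equal(res_swap$p, res$p)
  # degenerate equal constants
  res_const <- compare_runs(c(1, 1), c(1, 1))
  expect_equal(res_const$t, 0)
  expect_equal(res_const$p, 1)
  # clearly separated samples
  res_sep <- compare_runs(c(0, 1e-9, -1e-9), c(1, 1 + 1e-9, 1 - 1e-9))
  expect_lt(res_sep$p, 1e-6)
})

test_that("convergence statistics aggregate running minima", {
  mk <- function(y) reachopt:::bo_result(
    eval_dataset(matrix(runif(length(y) * 6), ncol = 6), y), 1, "bo")
  one <- mk(c(5, 4, 4, 2))
  cs1 <- convergence_stats(list(one))
  expect_equal(cs1$mean, c(5, 4, 4, 2))
  expect_equal(cs1$sd, rep(0, 4))
  two <- convergence_stats(list(mk(c(1, 1, 1)), mk(c(3, 3, 3))))
  expect_equal(two$mean, rep(2, 3))
  expect_equal(two$sd, rep(sqrt(2), 3))
  expect_true(all(diff(two$mean) <= 0))
  expect_error(convergence_stats(list(mk(1:3), mk(1:4))), "ragged")
})
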