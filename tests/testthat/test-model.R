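arm <- arm_parameters()

test_that("forward kinematics matches the stated postures", {
  expect_equal(forward_kinematics(c(0, 0), arm),
               c(x = 0, z = -(arm$l1 + arm$l2)))
  expect_equal(forward_kinematics(c(pi / 2, 0), arm),
               c(x = arm$l2, z = -arm$l1))
  expect_equal(forward_kinematics(c(0, pi / 2), arm),
               c(x = arm$l1 + arm$l2, z = 0))
})

test_that("muscle-tendon kinematics is the linear moment-arm map", {
  path <- muscle_path("MEF", 0, 0.03, l_ref = 0.29,
                      theta_ref = c(pi / 2, 0))
  expect_equal(mtu_kinematics(c(pi / 2, 0), c(0, 0), path),
               c(l_MTU = 0.29, l_MTU_dot = 0))
  expect_equal(mtu_kinematics(c(pi / 2 + 0.1, 0), c(0, 0), path)[["l_MTU"]],
               0.29 - 0.003)
  bi <- muscle_path("BA", 0.04, 0.03, l_ref = 0.32, theta_ref = c(pi / 2, 0))
  dl <- 0.32 - mtu_kinematics(c(pi / 2 + 0.1, 0.1), c(0, 0), bi)[["l_MTU"]]
  expect_equal(dl, 0.1 * 0.04 + 0.1 * 0.03)
  expect_equal(mtu_kinematics(c(pi / 2, 0), c(0.2, -0.1), bi)[["l_MTU_dot"]],
               0.1 * 0.04 - 0.2 * 0.03)
})

test_that("contraction dynamics agrees with a brute-force balance solve", {
  p <- muscle_parameters()
  set.seed(42)
  worst <- 0
  for (i in 1:1000) {
    lce <- runif(1, 0.6, 1.4) * p$l_CE_opt
    lmtu <- lce + p$l_SEE_0 * runif(1, 0.98, 1.06)
    vmtu <- runif(1, -0.8, 0.8)
    a <- runif(1, p$a_min, 1)
    v_cpp <- contraction_dynamics(lce, lmtu, vmtu, a, p)
    v_brute <- oracle_contraction_rate(lce, lmtu, vmtu, a, p)
    worst <- max(worst, abs(v_cpp - v_brute))
  }
  expect_lt(worst, 1e-8)
})

test_that("contraction dynamics has the right signs and fixed point", {
  p <- muscle_parameters()
  lmtu_eq <- p$l_SEE_0 + p$l_CE_opt
  # slack tendon at rest activity: nothing pulls, nothing moves fast
  # lengthened MTU above equilibrium at rest activity: CE is dragged out
  v <- contraction_dynamics(p$l_CE_opt, lmtu_eq + 0.01, 0, p$a_min, p)
  expect_gt(v, 0)
  # full activation with shortened MTU: CE shortens
  v <- contraction_dynamics(p$l_CE_opt, lmtu_eq - 0.005, 0, 1, p)
  expect_lt(v, 0)
  # continuity across the branch point
  lce <- 0.98 * p$l_CE_opt
  vs <- vapply(c(-1e-9, 0, 1e-9), function(dv)
    oracle_balance(dv, lce, lmtu_eq, 0, 0.5, p), numeric(1))
  expect_lt(max(abs(diff(vs))), 1e-4)
})

test_that("MTU force normalization and monotonicity hold", {
  p <- muscle_parameters()
  # slack tendon, static: zero force
  expect_equal(mtu_force(p$l_CE_opt, 0, p$l_CE_opt + 0.9 * p$l_SEE_0, 0, 1, p),
               0)
  # isometric CE force at optimal length and full activation equals F_max
  # (measured on the CE side: SEE stretched to transmit exactly that force)
  cur <- oracle_curves(p)
  lsee_eq <- uniroot(function(l) cur$f_see(l) - p$F_max,
                     c(p$l_SEE_0, 2 * p$l_SEE_0), tol = 1e-13)$root
  F <- mtu_force(p$l_CE_opt, 0, p$l_CE_opt + lsee_eq, 0, 1, p)
  expect_equal(F, p$F_max, tolerance = 1e-9)
  # transmitted force strictly decreases as the imposed shortening speed
  # grows (Hill hyperbola through the solved contraction state)
  vmtus <- seq(0, -0.25, by = -0.01)
  Fs <- vapply(vmtus, function(vm) {
    vce <- contraction_dynamics(p$l_CE_opt, p$l_CE_opt + lsee_eq, vm, 1, p)
    mtu_force(p$l_CE_opt, vce, p$l_CE_opt + lsee_eq, vm, 1, p)
  }, numeric(1))
  expect_true(all(diff(Fs) < 0))
})

test_that("activation dynamics has the Hatze fixed-point structure", {
  p <- muscle_parameters()
  lopt <- p$l_CE_opt
  # rest is a fixed point
  expect_equal(activation_dynamics(p$a_min, lopt, 0, p), 0)
  # stimulation from (slightly above) rest activates; decay de-activates
  expect_gt(activation_dynamics(0.01, lopt, 1, p), 0)
  expect_lt(activation_dynamics(0.5, lopt, 0, p), 0)
  # integrating gamma to steady state reproduces the closed-form a_ss
  u <- 0.5
  g <- 0
  dt <- 1e-4
  for (i in seq_len(50000)) g <- g + dt * p$m_act * (u - g)
  expect_equal(activation_activity(g, lopt, p),
               activation_steady_state(u, lopt, p), tolerance = 1e-6)
  # a_ss is a root of the activity rate
  a_ss <- activation_steady_state(u, lopt, p)
  expect_equal(activation_dynamics(a_ss, lopt, u, p), 0, tolerance = 1e-10)
})

test_that("activation rise is faster than decay at high stimulation", {
  p <- muscle_parameters()
  lopt <- p$l_CE_opt
  dt <- 1e-4
  g <- 0
  t_rise <- NA
  for (i in seq_len(100000)) {
    g <- g + dt * p$m_act * (1 - g)
    if (activation_activity(g, lopt, p) >= 0.9) { t_rise <- i * dt; break }
  }
  g0 <- g
  t_fall <- NA
  for (i in seq_len(100000)) {
    g0 <- g0 - dt * p$m_act * g0
    if (activation_activity(g0, lopt, p) <= 0.1) { t_fall <- i * dt; break }
  }
  expect_lt(t_rise, t_fall)
})

test_that("joint torques sum moment arm times force", {
  paths <- list(muscle_path("MEF", 0, 0.03, 0.29),
                muscle_path("MEE", 0, -0.03, 0.29),
                muscle_path("MSA", 0.05, 0, 0.31))
  expect_equal(joint_torques(c(0, 0, 0), paths), c(elbow = 0, shoulder = 0))
  expect_equal(joint_torques(c(100, 0, 0), paths),
               c(elbow = 3, shoulder = 0))
  # equal antagonist forces with opposite equal arms cancel
  expect_equal(joint_torques(c(50, 50, 0), paths)[["elbow"]], 0)
})

test_that("passive dynamics conserve energy and match the pendulum formula", {
  ps <- simulate_passive(arm, theta0 = c(0.7, 0.4), t_end = 5,
                         rtol = 1e-8, atol = 1e-10)
  drift <- max(abs(ps$energy - ps$energy[1])) / abs(ps$energy[1])
  expect_lt(drift, 1e-6)
  # locked-elbow compound pendulum at 1 degree amplitude
  d <- arm$l1 + arm$c2
  Itot <- arm$I1 + arm$m1 * arm$c1^2 + arm$I2 + arm$m2 * d^2
  w0 <- sqrt((arm$m1 * arm$c1 + arm$m2 * d) * arm$g / Itot)
  pl <- simulate_passive(arm, theta0 = c(0, pi / 180), t_end = 10,
                         lock_elbow = TRUE)
  zc <- which(diff(sign(pl$psi)) != 0)
  w_sim <- 2 * pi / (2 * mean(diff(pl$t[zc])))
  expect_lt(abs(w_sim - w0) / w0, 0.005)
  # hanging rest with no muscles is an equilibrium of the full RHS
  model0 <- arm_model(arm = arm, muscles = list(),
                      limits = list(phi = c(-10, 10), psi = c(-10, 10),
                                    k = 0, w = 0.05))
  dy <- reachopt:::.arm_rhs_cpp(0, c(0, 0, 0, 0),
                                reachopt:::arm_vector(model0),
                                reachopt:::musc_matrix(model0), numeric(0))
  expect_equal(max(abs(dy)), 0)
})

model <- default_model()

test_that("the relaxed initial condition is an equilibrium fixed point", {
  ini <- find_initial_state(model)
  expect_lt(ini$residual, 1e-6)
  d <- state_derivative(ini$state, ini$u, model)
  expect_lt(max(abs(unlist(d))), 1e-6)
  # simulate under u0: the arm holds still
  task2 <- task_spec(x_star = model$task$x_star, duration_mode = "fixed",
                     T_fixed = 2, theta0 = model$task$theta0)
  tr <- simulate_reach(ini$u, model, task = task2)
  p0 <- forward_kinematics(model$task$theta0, model$arm)
  drift <- sqrt((tr$x - p0[["x"]])^2 + (tr$z - p0[["z"]])^2)
  expect_lt(max(drift), 1e-4)
  speed <- sqrt(tr$x_dot^2 + tr$z_dot^2)
  expect_lt(max(speed), model$task$v_stop)
})

test_that("gravity load shapes the minimal holding stimulation", {
  # with gravity off the passive antagonist pairs balance: u0 is (near) zero
  arm0 <- arm_parameters(g = 0)
  m0 <- default_model()
  m0$arm <- arm0
  m0$cache <- new.env(parent = emptyenv())
  ini0 <- find_initial_state(m0)
  expect_lt(sum(ini0$u), 0.02)
  # doubling gravity does not decrease the total holding stimulation
  m2 <- default_model()
  m2$arm <- arm_parameters(g = 2 * 9.81)
  m2$cache <- new.env(parent = emptyenv())
  ini1 <- find_initial_state(default_model())
  ini2 <- find_initial_state(m2)
  expect_gte(sum(ini2$u) + 1e-9, sum(ini1$u))
})

test_that("simulation output is consistent, deterministic and terminates", {
  u <- c(0.6, 0.05, 0.1, 0.3, 0.1, 0.05)
  tr <- simulate_reach(u, model)
  # kinematic consistency at every sample
  xz <- reachopt:::fk_vec(tr$theta, model$arm)
  expect_lt(max(abs(xz[, 1] - tr$x), abs(xz[, 2] - tr$z)), 1e-9)
  # free mode ends at rest or at the cap
  vT <- sqrt(tr$x_dot^2 + tr$z_dot^2)[length(tr$x)]
  expect_true(vT < model$task$v_stop || tr$terminated_by == "cap")
  # velocity features are finite-difference-consistent with their parents
  fd_theta <- apply(tr$theta, 2, reachopt:::fd_derivative, dt = tr$dt)
  inner <- 2:(nrow(tr$theta) - 1)
  expect_lt(max(abs(fd_theta[inner, ] - tr$theta_dot[inner, ])), 5e-3)
  # activities stay in bounds
  expect_true(all(tr$a >= muscle_parameters()$a_min - 1e-9 & tr$a <= 1))
  # bitwise determinism
  tr2 <- simulate_reach(u, model)
  expect_identical(tr$theta, tr2$theta)
  expect_identical(tr$tau, tr2$tau)
  # fixed mode spans exactly T_fixed
  mf <- default_model(duration_mode = "fixed")
  trf <- simulate_reach(u, mf)
  expect_equal(trf$T, 1.0)
  expect_identical(trf$terminated_by, "time_limit")
})
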