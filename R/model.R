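#' Fingertip position from joint angles
#'
#' Shoulder at the origin, x forward, z up: `x = l1 sin(psi) + l2 sin(psi+phi)`,
#' `z = -l1 cos(psi) - l2 cos(psi+phi)`.
#'
#' @param theta joint angles `c(phi, psi)` (rad)
#' @param arm [arm_parameters()]
#' @return named numeric `c(x, z)` (m)
#' @export
forward_kinematics <- function(theta, arm) {
  phi <- theta[1]; psi <- theta[2]
  c(x = arm$l1 * sin(psi) + arm$l2 * sin(psi + phi),
    z = -arm$l1 * cos(psi) - arm$l2 * cos(psi + phi))
}

# vectorized fingertip position/velocity over matrices of states
fk_vec <- function(theta, arm) {
  phi <- theta[, 1]; psi <- theta[, 2]
  cbind(x = arm$l1 * sin(psi) + arm$l2 * sin(psi + phi),
        z = -arm$l1 * cos(psi) - arm$l2 * cos(psi + phi))
}

ftvel_vec <- function(theta, omega, arm) {
  phi <- theta[, 1]; psi <- theta[, 2]
  dq2 <- omega[, 2] + omega[, 1]
  cbind(x_dot = arm$l1 * cos(psi) * omega[, 2] + arm$l2 * cos(psi + phi) * dq2,
        z_dot = arm$l1 * sin(psi) * omega[, 2] + arm$l2 * sin(psi + phi) * dq2)
}

fingertip_velocity <- function(theta, omega, arm) {
  phi <- theta[1]; psi <- theta[2]
  dphi <- omega[1]; dpsi <- omega[2]
  dq2 <- dpsi + dphi
  c(x_dot = arm$l1 * cos(psi) * dpsi + arm$l2 * cos(psi + phi) * dq2,
    z_dot = arm$l1 * sin(psi) * dpsi + arm$l2 * sin(psi + phi) * dq2)
}

#' Muscle-tendon length and lengthening velocity
#'
#' Constant-moment-arm routing: `l_MTU = l_ref - r_sh (psi - psi_ref) -
#' r_el (phi - phi_ref)`; the velocity is the corresponding linear map of the
#' joint velocities.
#'
#' @param theta joint angles `c(phi, psi)` (rad)
#' @param omega joint velocities `c(phi_dot, psi_dot)` (rad/s)
#' @param path [muscle_path()]
#' @return named numeric `c(l_MTU, l_MTU_dot)`
#' @export
mtu_kinematics <- function(theta, omega, path) {
  c(l_MTU = path$l_ref - path$r_shoulder * (theta[2] - path$theta_ref[2]) -
      path$r_elbow * (theta[1] - path$theta_ref[1]),
    l_MTU_dot = -path$r_shoulder * omega[2] - path$r_elbow * omega[1])
}

#' Contraction dynamics of the contractile element
#'
#' Returns the CE velocity that solves the internal force balance
#' CE + PEE = SEE + SDE of the four-element muscle-tendon unit.  Solved in
#' closed form (the balance times the Hill-hyperbola pole term is an exact
#' quadratic in the velocity); concentric and eccentric branches meet
#' continuously at zero velocity.
#'
#' @param l_CE contractile element length (m), > 0
#' @param l_MTU,l_MTU_dot muscle-tendon length (m) and velocity (m/s)
#' @param a muscle activity in `[a_min, 1]`
#' @param p [muscle_parameters()]
#' @return CE velocity `l_CE_dot` (m/s)
#' @export
contraction_dynamics <- function(l_CE, l_MTU, l_MTU_dot, a, p) {
  .contraction_rate_cpp(l_CE, l_MTU, l_MTU_dot, a, musc_row(p, null_path(p)))
}

#' Muscle-tendon force
#'
#' Force transmitted by the serial side (SEE + SDE), clamped at zero so the
#' tendon cannot push.
#'
#' @inheritParams contraction_dynamics
#' @param l_CE_dot CE velocity (m/s)
#' @return force (N)
#' @export
mtu_force <- function(l_CE, l_CE_dot, l_MTU, l_MTU_dot, a, p) {
  .mtu_force_cpp(l_CE, l_CE_dot, l_MTU, l_MTU_dot, a, musc_row(p, null_path(p)))
}

# dummy routing used when evaluating a muscle in isolation
null_path <- function(p) {
  list(r_shoulder = 0, r_elbow = 0, l_ref = p$l_SEE_0 + p$l_CE_opt,
       theta_ref = c(0, 0))
}

#' Activity from the calcium state
#'
#' `a = (a_min + (rho(l_CE) gamma)^nu) / (1 + (rho(l_CE) gamma)^nu)` with a
#' length-dependent sensitivity `rho`.
#'
#' @param gamma normalized free-calcium concentration in `[0, 1]`
#' @param l_CE CE length (m)
#' @param p [muscle_parameters()]
#' @return activity in `[a_min, 1)`
#' @export
activation_activity <- function(gamma, l_CE, p) {
  .activity_cpp(gamma, l_CE, musc_row(p, null_path(p)))
}

# inverse of activation_activity in gamma at fixed l_CE
activation_gamma_of <- function(a, l_CE, p) {
  a <- min(max(a, p$a_min), 1 - 1e-12)
  s <- (a - p$a_min) / (1 - a)
  rho <- .muscle_curves_cpp(l_CE, 0, musc_row(p, null_path(p)))[["rho"]]
  s^(1 / p$nu_act) / rho
}

#' Activation dynamics
#'
#' First-order calcium-like dynamics: the calcium state relaxes toward the
#' stimulation (`gamma_dot = m_act (u - gamma)`), and the activity follows the
#' saturating length-dependent map of [activation_activity()].  The activity
#' rate is the chain rule through that map at the current CE length.  Because
#' the map saturates, high stimulations reach peak activity quickly while
#' deactivation is slower.
#'
#' @param a current activity in `[a_min, 1]`
#' @param l_CE CE length (m)
#' @param u stimulation in `[0, 1]`
#' @param p [muscle_parameters()]
#' @return activity rate `a_dot` (1/s)
#' @export
activation_dynamics <- function(a, l_CE, u, p) {
  if (u < 0 || u > 1) stop("stimulation u must lie in [0, 1]")
  gamma <- activation_gamma_of(a, l_CE, p)
  row <- musc_row(p, null_path(p))
  rho <- .muscle_curves_cpp(l_CE, 0, row)[["rho"]]
  s <- (rho * gamma)^p$nu_act
  dads <- (1 - p$a_min) / (1 + s)^2
  dsdg <- p$nu_act * rho * (rho * gamma)^(p$nu_act - 1)
  dads * dsdg * p$m_act * (u - gamma)
}

#' Steady-state activity for a constant stimulation
#'
#' @inheritParams activation_dynamics
#' @return fixed-point activity `a_ss(u, l_CE)`
#' @export
activation_steady_state <- function(u, l_CE, p) {
  activation_activity(u, l_CE, p)
}

#' Joint torques from muscle forces
#'
#' `tau_joint = sum_i r_{i,joint} F_i` over all muscles.
#'
#' @param F_MTU vector of muscle forces (N), one per muscle
#' @param paths list of [muscle_path()] objects, same order
#' @return named numeric `c(elbow, shoulder)` (N m)
#' @export
joint_torques <- function(F_MTU, paths) {
  stopifnot(length(F_MTU) == length(paths), all(F_MTU >= 0))
  r_el <- vapply(paths, `[[`, numeric(1), "r_elbow")
  r_sh <- vapply(paths, `[[`, numeric(1), "r_shoulder")
  c(elbow = sum(r_el * F_MTU), shoulder = sum(r_sh * F_MTU))
}

# gravity torque expressed in (phi, psi) generalized coordinates
gravity_torque <- function(theta, arm) {
  phi <- theta[1]; psi <- theta[2]
  g_psi <- -((arm$m1 * arm$c1 + arm$m2 * arm$l1) * arm$g * sin(psi) +
               arm$m2 * arm$c2 * arm$g * sin(psi + phi))
  g_phi <- -arm$m2 * arm$c2 * arm$g * sin(psi + phi)
  c(elbow = g_phi, shoulder = g_psi)
}

limit_torque_r <- function(th, lim, k, w) {
  if (k <= 0) return(0)
  k * (exp((lim[1] - th) / w) - exp((th - lim[2]) / w))
}

# pack/unpack of the ODE state vector y = (phi, psi, phidot, psidot, lce, gamma)
pack_state <- function(state, nm) {
  c(state$theta, state$omega, state$l_CE, state$gamma)
}

#' System state constructor
#'
#' @param theta joint angles `c(phi, psi)` (rad)
#' @param omega joint velocities (rad/s)
#' @param l_CE CE lengths (m), one per muscle
#' @param gamma normalized calcium states, one per muscle
#' @param model [arm_model()] (used to derive the activities)
#' @param t time (s)
#' @return object of class `system_state` with derived activities `a`
#' @export
system_state <- function(theta, omega, l_CE, gamma, model, t = 0) {
  stopifnot(all(l_CE > 0), all(is.finite(c(theta, omega, l_CE, gamma))))
  a <- vapply(seq_along(model$muscles), function(i)
    activation_activity(gamma[i], l_CE[i], model$muscles[[i]]$params),
    numeric(1))
  structure(list(t = t, theta = unname(theta), omega = unname(omega),
                 l_CE = unname(l_CE), gamma = unname(gamma), a = a),
            class = "system_state")
}

#' Time derivative of the system state
#'
#' Skeleton accelerations from the planar two-link Euler-Lagrange equations
#' (mass matrix, Coriolis/centrifugal and gravity terms) driven by the summed
#' muscle-tendon torques and soft joint-limit torques; CE and calcium rates
#' from the muscle dynamics.
#'
#' @param state [system_state()]
#' @param u stimulation vector in `[0, 1]^n`
#' @param model [arm_model()]
#' @return list with `theta_dot`, `omega_dot`, `l_CE_dot`, `gamma_dot`, `a_dot`
#' @export
state_derivative <- function(state, u, model) {
  nm <- length(model$muscles)
  y <- pack_state(state, nm)
  dy <- .arm_rhs_cpp(state$t, y, arm_vector(model), musc_matrix(model),
                     as.numeric(u))
  gdot <- if (nm > 0) dy[(4 + nm + 1):(4 + 2 * nm)] else numeric(0)
  adot <- vapply(seq_len(nm), function(i) {
    p <- model$muscles[[i]]$params
    row <- musc_row(p, null_path(p))
    rho <- .muscle_curves_cpp(state$l_CE[i], 0, row)[["rho"]]
    s <- (rho * state$gamma[i])^p$nu_act
    dads <- (1 - p$a_min) / (1 + s)^2
    dsdg <- if (state$gamma[i] > 0)
      p$nu_act * rho * (rho * state$gamma[i])^(p$nu_act - 1) else 0
    dads * dsdg * gdot[i]
  }, numeric(1))
  list(theta_dot = dy[1:2], omega_dot = dy[3:4],
       l_CE_dot = if (nm > 0) dy[5:(4 + nm)] else numeric(0),
       gamma_dot = gdot, a_dot = adot)
}

# isometric CE length and MTU force for a constant stimulation at a posture
static_muscle_state <- function(u, theta, muscle) {
  p <- muscle$params
  lmtu <- mtu_kinematics(theta, c(0, 0), muscle$path)[["l_MTU"]]
  row <- musc_row(p, muscle$path)
  a_of <- function(lce) .activity_cpp(u, lce, row)
  bal <- function(lce) {
    cv <- .muscle_curves_cpp(lce, lmtu - lce, row)
    a_of(lce) * p$F_max * cv[["f_isom"]] + cv[["f_pee"]] - cv[["f_see"]]
  }
  hi <- lmtu - p$l_SEE_0
  lo <- 0.1 * p$l_CE_opt
  if (hi <= lo) stop("muscle geometry leaves no room for the CE at this posture")
  root <- uniroot(bal, c(lo, hi), tol = 1e-13)$root
  cv <- .muscle_curves_cpp(root, lmtu - root, row)
  list(l_CE = root, F = cv[["f_see"]], a = a_of(root), l_MTU = lmtu)
}

# net generalized torque (muscle + passive limits + gravity) at rest
static_net_torque <- function(u, model, theta) {
  forces <- vapply(seq_along(model$muscles), function(i)
    static_muscle_state(u[i], theta, model$muscles[[i]])$F, numeric(1))
  paths <- lapply(model$muscles, `[[`, "path")
  tau <- joint_torques(forces, paths) + gravity_torque(theta, model$arm)
  lim <- model$limits
  tau[1] <- tau[1] + limit_torque_r(theta[1], lim$phi, lim$k, lim$w)
  tau[2] <- tau[2] + limit_torque_r(theta[2], lim$psi, lim$k, lim$w)
  tau
}

#' Relaxed initial condition: minimal stimulation holding the start posture
#'
#' Finds the stimulation vector `u0` minimizing `sum(u)` subject to static
#' equilibrium at `theta0` (net joint torque below tolerance, each CE at its
#' isometric fixed point, each activity at its steady state).  Solved by an
#' escalating quadratic penalty on the torque residual followed by a 2-D
#' Newton polish on the two most torque-effective stimulations.
#'
#' @param model [arm_model()]
#' @param theta0 start posture `c(phi, psi)` (rad); defaults to the task's
#' @param tol torque residual tolerance (N m)
#' @return list with `state` ([system_state()]), `u` and `residual` (N m)
#' @export
find_initial_state <- function(model, theta0 = model$task$theta0, tol = 1e-6) {
  nm <- length(model$muscles)
  # tabulate each muscle's static (isometric-equilibrium) force over u once;
  # the penalty stage then runs on fast monotone spline interpolants and only
  # the final Newton polish evaluates the exact force balance
  ug <- seq(0, 1, length.out = 101)
  fsplines <- lapply(model$muscles, function(m) {
    Fg <- vapply(ug, function(uu) static_muscle_state(uu, theta0, m)$F,
                 numeric(1))
    stats::splinefun(ug, Fg, method = "hyman")
  })
  r_el <- vapply(model$muscles, function(m) m$path$r_elbow, numeric(1))
  r_sh <- vapply(model$muscles, function(m) m$path$r_shoulder, numeric(1))
  lim <- model$limits
  tau0 <- gravity_torque(theta0, model$arm) +
    c(limit_torque_r(theta0[1], lim$phi, lim$k, lim$w),
      limit_torque_r(theta0[2], lim$psi, lim$k, lim$w))
  tau_fast <- function(u) {
    F <- vapply(seq_len(nm), function(i) fsplines[[i]](u[i]), numeric(1))
    c(sum(r_el * F), sum(r_sh * F)) + tau0
  }
  obj <- function(u, mu) sum(u) + mu * sum(tau_fast(u)^2)
  u <- rep(0.05, nm)
  for (mu in c(1e2, 1e4, 1e6, 1e8)) {
    u <- optim(u, obj, mu = mu, method = "L-BFGS-B",
               lower = rep(0, nm), upper = rep(1, nm),
               control = list(maxit = 500, factr = 1e3))$par
  }
  # Newton polish: pick the two stimulations with the strongest independent
  # leverage on the two joints and zero the residual exactly
  jac <- vapply(seq_len(nm), function(i) {
    du <- 1e-5
    up <- u; up[i] <- min(1, up[i] + du)
    um <- u; um[i] <- max(0, um[i] - du)
    (static_net_torque(up, model, theta0) -
       static_net_torque(um, model, theta0)) / (up[i] - um[i])
  }, numeric(2))
  i_el <- which.max(abs(jac[1, ]))
  i_sh <- setdiff(order(abs(jac[2, ]), decreasing = TRUE), i_el)[1]
  idx <- c(i_el, i_sh)
  for (it in 1:50) {
    r <- static_net_torque(u, model, theta0)
    if (max(abs(r)) < tol * 1e-4) break
    J <- vapply(idx, function(i) {
      du <- 1e-6
      up <- u; up[i] <- up[i] + du
      (static_net_torque(up, model, theta0) - r) / du
    }, numeric(2))
    step <- tryCatch(solve(J, -r), error = function(e) NULL)
    if (is.null(step)) break
    u[idx] <- pmin(1, pmax(0, u[idx] + step))
  }
  r <- static_net_torque(u, model, theta0)
  if (max(abs(r)) > tol) {
    stop(sprintf(
      "no static equilibrium at theta0: unbalanced %s torque (%.3g N m)",
      if (abs(r[1]) > abs(r[2])) "elbow" else "shoulder", max(abs(r))))
  }
  lce <- vapply(seq_len(nm), function(i)
    static_muscle_state(u[i], theta0, model$muscles[[i]])$l_CE, numeric(1))
  st <- system_state(theta0, c(0, 0), lce, u, model)
  list(state = st, u = unname(u), residual = max(abs(r)))
}

# cached equilibrium initial state per model instance
initial_state <- function(model) {
  key <- paste0("init_", paste(signif(model$task$theta0, 12), collapse = "_"))
  if (is.null(model$cache[[key]])) {
    model$cache[[key]] <- find_initial_state(model)
  }
  model$cache[[key]]
}

# centered finite differences on a uniform grid, second-order one-sided at
# the ends (first-order boundary stencils visibly bias the jerk integrals)
fd_derivative <- function(x, dt) {
  n <- length(x)
  if (n < 3) return(rep(0, n))
  d <- numeric(n)
  d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / (2 * dt)
  if (n >= 4) {
    # third-order one-sided stencils: a lower-order boundary formula leaves a
    # kink in the error that later difference stages amplify by 1/dt^2
    d[1] <- (-11 * x[1] + 18 * x[2] - 9 * x[3] + 2 * x[4]) / (6 * dt)
    d[n] <- (11 * x[n] - 18 * x[n - 1] + 9 * x[n - 2] - 2 * x[n - 3]) / (6 * dt)
  } else {
    d[1] <- (-3 * x[1] + 4 * x[2] - x[3]) / (2 * dt)
    d[n] <- (3 * x[n] - 4 * x[n - 1] + x[n - 2]) / (2 * dt)
  }
  d
}

# direct second derivative on a uniform grid (second-order stencils); used
# for the jerk features, where two chained first differences lose too much
# accuracy at the boundaries
fd_second_derivative <- function(x, dt) {
  n <- length(x)
  if (n < 4) return(rep(0, n))
  d <- numeric(n)
  d[2:(n - 1)] <- (x[3:n] - 2 * x[2:(n - 1)] + x[1:(n - 2)]) / dt^2
  d[1] <- (2 * x[1] - 5 * x[2] + 4 * x[3] - x[4]) / dt^2
  d[n] <- (2 * x[n] - 5 * x[n - 1] + 4 * x[n - 2] - x[n - 3]) / dt^2
  d
}

#' Forward-dynamics simulation of one reaching movement
#'
#' Integrates the coupled skeleton / muscle / activation ODE for a constant
#' open-loop stimulation vector from the relaxed equilibrium start state, with
#' an adaptive stiff solver, and samples the feature trajectory on a uniform
#' grid.  In free-duration mode the simulation stops once the fingertip speed
#' drops below `v_stop` (after first exceeding `onset_factor * v_stop`), or at
#' `t_cap`; in fixed mode it stops exactly at `T_fixed`.
#'
#' @param u stimulation vector in `[0, 1]^6`
#' @param model [arm_model()]
#' @param task [task_spec()]; defaults to the model's
#' @param dt_out output sample interval (s)
#' @return object of class `arm_trajectory`: uniform-grid arrays `t`, `theta`,
#'   `theta_dot`, `theta_ddot`, `theta_dddot` (n x 2), `x`, `z`, `x_dot`,
#'   `z_dot`, `tau`, `tau_dot` (n x 2, elbow then shoulder, muscle torques),
#'   plus `u`, `T`, `dt`, `terminated_by` and a joint-limit `flagged` marker
#' @export
simulate_reach <- function(u, model, task = model$task,
                           dt_out = model$integrator$dt_out) {
  nm <- length(model$muscles)
  stopifnot(length(u) == nm, all(u >= 0), all(u <= 1))
  init <- initial_state(model)
  y0 <- pack_state(init$state, nm)
  armv <- arm_vector(model)
  muscm <- musc_matrix(model)
  rhs <- function(t, y, parms) list(.arm_rhs_cpp(t, y, armv, muscm, u))
  rtol <- model$integrator$rtol; atol <- model$integrator$atol

  if (task$duration_mode == "fixed") {
    times <- seq(0, task$T_fixed, by = dt_out)
    sol <- deSolve::lsoda(y0, times, rhs, NULL, rtol = rtol, atol = atol)
    terminated <- "time_limit"
  } else {
    chunk <- model$integrator$chunk
    sol <- NULL
    y <- y0
    t0 <- 0
    armed <- FALSE
    terminated <- "cap"
    arm <- model$arm
    repeat {
      t1 <- min(t0 + chunk, task$t_cap)
      times <- seq(t0, t1, by = dt_out)
      piece <- deSolve::lsoda(y, times, rhs, NULL, rtol = rtol, atol = atol)
      vp <- ftvel_vec(piece[, 2:3, drop = FALSE], piece[, 4:5, drop = FALSE],
                      arm)
      vel <- sqrt(vp[, 1]^2 + vp[, 2]^2)
      stop_at <- NA_integer_
      for (k in seq_along(vel)) {
        if (!armed && vel[k] > task$onset_factor * task$v_stop) armed <- TRUE
        else if (armed && vel[k] < task$v_stop) { stop_at <- k; break }
      }
      keep <- if (is.na(stop_at)) piece else piece[seq_len(stop_at), , drop = FALSE]
      sol <- if (is.null(sol)) keep else rbind(sol, keep[-1, , drop = FALSE])
      if (!is.na(stop_at)) { terminated <- "equilibrium"; break }
      if (t1 >= task$t_cap) break
      y <- piece[nrow(piece), -1]
      t0 <- t1
    }
    if (nrow(sol) < 2) {  # never moved and stopped instantly: keep 2 samples
      times <- seq(0, 2 * dt_out, by = dt_out)
      sol <- deSolve::lsoda(y0, times, rhs, NULL, rtol = rtol, atol = atol)
    }
  }

  tgrid <- sol[, 1]
  Y <- unname(sol[, -1, drop = FALSE])
  theta <- Y[, 1:2, drop = FALSE]
  omega <- Y[, 3:4, drop = FALSE]
  xz <- fk_vec(theta, model$arm)
  vxz <- ftvel_vec(theta, omega, model$arm)
  mo <- .muscle_outputs_cpp(Y, muscm, u)
  theta_ddot <- apply(omega, 2, fd_derivative, dt = dt_out)
  theta_dddot <- apply(omega, 2, fd_second_derivative, dt = dt_out)
  tau_dot <- apply(mo$tau, 2, fd_derivative, dt = dt_out)
  lim <- model$limits
  flagged <- any(theta[, 1] < lim$phi[1] | theta[, 1] > lim$phi[2] |
                   theta[, 2] < lim$psi[1] | theta[, 2] > lim$psi[2])
  structure(list(t = tgrid, dt = dt_out,
                 theta = theta, theta_dot = omega,
                 theta_ddot = theta_ddot, theta_dddot = theta_dddot,
                 x = xz[, 1], z = xz[, 2],
                 x_dot = vxz[, 1], z_dot = vxz[, 2],
                 tau = unname(mo$tau), tau_dot = tau_dot,
                 a = unname(mo$a), l_CE = Y[, 5:(4 + nm), drop = FALSE],
                 u = as.numeric(u), T = tgrid[length(tgrid)],
                 terminated_by = terminated, flagged = flagged),
            class = "arm_trajectory")
}

#' Passive pendulum simulation (no muscles, no joint limits)
#'
#' Integrates the bare two-link skeleton, optionally with the elbow rigidly
#' locked (single compound pendulum about the shoulder).  Used for physical
#' validation: energy conservation and small-oscillation frequency.
#'
#' @param arm [arm_parameters()]
#' @param theta0,omega0 initial `c(phi, psi)` angles (rad) and velocities
#' @param t_end,dt simulation horizon and output step (s)
#' @param lock_elbow if `TRUE`, freeze `phi` at `theta0[1]`
#' @param rtol,atol integrator tolerances
#' @return data.frame with `t`, `phi`, `psi`, `phi_dot`, `psi_dot`, `energy`
#' @export
simulate_passive <- function(arm, theta0, omega0 = c(0, 0), t_end = 5,
                             dt = 1e-3, lock_elbow = FALSE,
                             rtol = 1e-10, atol = 1e-12) {
  model <- arm_model(arm = arm, muscles = list(),
                     limits = list(phi = c(-10, 10), psi = c(-10, 10),
                                   k = 0, w = 0.05))
  armv <- arm_vector(model)
  muscm <- musc_matrix(model)
  if (lock_elbow) {
    phi0 <- theta0[1]
    d <- sqrt(arm$l1^2 + arm$c2^2 + 2 * arm$l1 * arm$c2 * cos(phi0))
    # compound-pendulum constants about the shoulder with the elbow frozen
    Itot <- arm$I1 + arm$m1 * arm$c1^2 + arm$I2 + arm$m2 * d^2
    beta <- atan2(arm$c2 * sin(phi0), arm$l1 + arm$c2 * cos(phi0))
    rhs <- function(t, y, parms) {
      # y = (psi, psidot); forearm COM hangs at angle psi + beta
      tq <- -(arm$m1 * arm$c1 * sin(y[1]) +
                arm$m2 * d * sin(y[1] + beta)) * arm$g
      list(c(y[2], tq / Itot))
    }
    sol <- deSolve::lsoda(c(theta0[2], omega0[2]), seq(0, t_end, by = dt),
                          rhs, NULL, rtol = rtol, atol = atol)
    out <- data.frame(t = sol[, 1], phi = phi0, psi = sol[, 2],
                      phi_dot = 0, psi_dot = sol[, 3])
  } else {
    rhs <- function(t, y, parms)
      list(.arm_rhs_cpp(t, y, armv, muscm, numeric(0)))
    y0 <- c(theta0, omega0)
    sol <- deSolve::lsoda(y0, seq(0, t_end, by = dt), rhs, NULL,
                          rtol = rtol, atol = atol)
    out <- data.frame(t = sol[, 1], phi = sol[, 2], psi = sol[, 3],
                      phi_dot = sol[, 4], psi_dot = sol[, 5])
  }
  out$energy <- mechanical_energy(out, arm)
  out
}

#' Total mechanical energy of the bare skeleton
#'
#' @param df data.frame with `phi`, `psi`, `phi_dot`, `psi_dot`
#' @param arm [arm_parameters()]
#' @return numeric vector (J)
#' @export
mechanical_energy <- function(df, arm) {
  q1 <- df$psi; q2 <- df$psi + df$phi
  dq1 <- df$psi_dot; dq2 <- df$psi_dot + df$phi_dot
  M11 <- arm$I1 + arm$m1 * arm$c1^2 + arm$m2 * arm$l1^2
  M22 <- arm$I2 + arm$m2 * arm$c2^2
  M12 <- arm$m2 * arm$l1 * arm$c2 * cos(q1 - q2)
  kin <- 0.5 * (M11 * dq1^2 + 2 * M12 * dq1 * dq2 + M22 * dq2^2)
  pot <- -(arm$m1 * arm$c1 + arm$m2 * arm$l1) * arm$g * cos(q1) -
    arm$m2 * arm$c2 * arm$g * cos(q2)
  kin + pot
}
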