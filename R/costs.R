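#' Trapezoidal integral of a squared signal
#'
#' Realizes the integral terms of the movement cost functions on the uniform
#' output grid.
#'
#' @param signal uniformly sampled numeric vector (>= 2 samples)
#' @param dt sample interval (s)
#' @return `integral of signal(t)^2 dt`, >= 0
#' @export
integrate_squared <- function(signal, dt) {
  if (length(signal) < 2) stop("need at least 2 samples")
  if (length(dt) != 1 || !is.finite(dt) || dt <= 0)
    stop("dt must be a single positive number (uniform grid)")
  s2 <- signal^2
  dt * (sum(s2) - 0.5 * (s2[1] + s2[length(s2)]))
}

trapz <- function(y, dt) dt * (sum(y) - 0.5 * (y[1] + y[length(y)]))

#' Names of the nine optimality principles
#' @return character vector of cost names
#' @export
cost_names <- function() c("ACC", "HJ", "AJ", "T", "TC", "EN", "EFF", "JE", "JEE")

# CLI-friendly aliases
cost_aliases <- c(acc = "ACC", hand_jerk = "HJ", angle_jerk = "AJ",
                  torque = "T", torque_change = "TC", energy = "EN",
                  effort = "EFF", je = "JE", jee = "JEE")

normalize_cost_name <- function(name) {
  if (name %in% cost_names()) return(name)
  lo <- tolower(name)
  if (lo %in% names(cost_aliases)) return(unname(cost_aliases[lo]))
  if (toupper(name) %in% cost_names()) return(toupper(name))
  stop("unknown cost name: ", name)
}

#' Cost specification
#'
#' @param name optimality principle, one of [cost_names()] (CLI aliases such
#'   as `"angle_jerk"` are accepted)
#' @param w_task task-constraint weight on the squared endpoint error
#' @param w_jerk_in_hybrid jerk weight inside the JE/JEE hybrids
#' @param w_terminal_velocity terminal-speed penalty weight (fixed-duration
#'   mode only)
#' @return object of class `cost_spec`
#' @export
cost_spec <- function(name = "JE", w_task = 0.01, w_jerk_in_hybrid = 1e-3,
                      w_terminal_velocity = 1.0) {
  name <- normalize_cost_name(name)
  stopifnot(w_task >= 0, w_jerk_in_hybrid >= 0, w_terminal_velocity >= 0)
  structure(list(name = name, w_task = w_task,
                 w_jerk_in_hybrid = w_jerk_in_hybrid,
                 w_terminal_velocity = w_terminal_velocity),
            class = "cost_spec")
}

# component integrals shared by the principles
cost_components <- function(traj, w_jerk = 1e-3) {
  dt <- traj$dt
  x_dddot <- fd_second_derivative(traj$x_dot, dt)
  z_dddot <- fd_second_derivative(traj$z_dot, dt)
  list(
    ACC = integrate_squared(traj$theta_ddot[, 1], dt) +
          integrate_squared(traj$theta_ddot[, 2], dt),
    HJ  = integrate_squared(x_dddot, dt) + integrate_squared(z_dddot, dt),
    AJ  = integrate_squared(traj$theta_dddot[, 1], dt) +
          integrate_squared(traj$theta_dddot[, 2], dt),
    T   = integrate_squared(traj$tau[, 1], dt) +
          integrate_squared(traj$tau[, 2], dt),
    TC  = integrate_squared(traj$tau_dot[, 1], dt) +
          integrate_squared(traj$tau_dot[, 2], dt),
    EN  = trapz(abs(traj$theta_dot[, 1] * traj$tau[, 1]) +
                  abs(traj$theta_dot[, 2] * traj$tau[, 2]), dt),
    EFF = sum(traj$u^2)
  )
}

#' Evaluate one optimality principle on a trajectory
#'
#' The nine principles: squared angle acceleration (ACC), hand jerk (HJ),
#' angle jerk (AJ), torque (T) and torque change (TC) integrals; absolute
#' mechanical power (EN); squared-stimulation effort (EFF, no time integral);
#' and the hybrids JE = EN + 1e-3 AJ and JEE = JE + EFF.
#'
#' @param name cost name (see [cost_names()])
#' @param traj [simulate_reach()] trajectory carrying the required features
#' @param w_jerk_in_hybrid jerk weight of the hybrids
#' @return scalar cost `J_opt`
#' @export
evaluate_principle <- function(name, traj, w_jerk_in_hybrid = 1e-3) {
  name <- normalize_cost_name(name)
  comp <- cost_components(traj)
  switch(name,
         ACC = comp$ACC, HJ = comp$HJ, AJ = comp$AJ, T = comp$T,
         TC = comp$TC, EN = comp$EN, EFF = comp$EFF,
         JE  = comp$EN + w_jerk_in_hybrid * comp$AJ,
         JEE = comp$EN + w_jerk_in_hybrid * comp$AJ + comp$EFF)
}

#' Task-constrained total cost
#'
#' `J_total = ||x_T - x_star||^2 + w_tv ||v_T||^2 + w_task J_opt`, where the
#' terminal-speed term is active only in fixed-duration mode (in free mode
#' the simulation itself terminates at rest).
#'
#' @param traj [simulate_reach()] trajectory
#' @param task [task_spec()]
#' @param spec [cost_spec()]
#' @return object of class `cost_breakdown` with `J_opt`, `J_task`,
#'   `J_terminal_v`, `J_total` and the hybrid components
#' @export
total_cost <- function(traj, task, spec) {
  comp <- cost_components(traj)
  J_opt <- switch(spec$name,
                  ACC = comp$ACC, HJ = comp$HJ, AJ = comp$AJ, T = comp$T,
                  TC = comp$TC, EN = comp$EN, EFF = comp$EFF,
                  JE  = comp$EN + spec$w_jerk_in_hybrid * comp$AJ,
                  JEE = comp$EN + spec$w_jerk_in_hybrid * comp$AJ + comp$EFF)
  n <- length(traj$x)
  J_task <- (traj$x[n] - task$x_star)^2
  J_tv <- if (task$duration_mode == "fixed")
    traj$x_dot[n]^2 + traj$z_dot[n]^2 else 0
  w_tv <- if (task$duration_mode == "fixed") spec$w_terminal_velocity else 0
  structure(list(J_opt = J_opt, J_task = J_task, J_terminal_v = J_tv,
                 J_total = J_task + w_tv * J_tv + spec$w_task * J_opt,
                 components = comp, name = spec$name),
            class = "cost_breakdown")
}
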