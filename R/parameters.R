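#' Arm segment parameters
#'
#' Rigid-body parameters of the two-segment planar arm (upper arm = segment 1,
#' forearm incl. hand = segment 2), shoulder fixed at the origin.
#'
#' @param l1,l2 segment lengths (m)
#' @param m1,m2 segment masses (kg)
#' @param c1,c2 centre-of-mass distances from the proximal joint (m)
#' @param I1,I2 segment moments of inertia about the centre of mass (kg m^2)
#' @param g gravitational acceleration (m/s^2)
#' @return object of class `arm_parameters`
#' @export
arm_parameters <- function(l1 = 0.34, l2 = 0.46, m1 = 1.9, m2 = 1.6,
                           c1 = 0.15, c2 = 0.21, I1 = 0.018, I2 = 0.030,
                           g = 9.81) {
  p <- list(l1 = l1, l2 = l2, m1 = m1, m2 = m2, c1 = c1, c2 = c2,
            I1 = I1, I2 = I2, g = g)
  stopifnot(l1 > 0, l2 > 0, m1 > 0, m2 > 0, I1 > 0, I2 > 0,
            c1 > 0, c1 < l1, c2 > 0, c2 < l2)
  structure(p, class = "arm_parameters")
}

#' Muscle routing: constant moment arms and reference length
#'
#' Each lumped muscle acts through constant signed moment arms; its
#' muscle-tendon length is the linear map
#' `l_MTU = l_ref - r_shoulder (psi - psi_ref) - r_elbow (phi - phi_ref)`.
#' A positive moment arm means the muscle shortens when that angle increases
#' and pulls the angle in the positive direction.
#'
#' @param name one of MSA, MSR, MEF, MEE, BA, BR
#' @param r_shoulder,r_elbow signed moment arms (m); monoarticular muscles have
#'   exactly one nonzero arm, biarticular muscles two
#' @param l_ref muscle-tendon length at the reference posture (m)
#' @param theta_ref reference posture `c(phi, psi)` (rad)
#' @return object of class `muscle_path`
#' @export
muscle_path <- function(name, r_shoulder, r_elbow, l_ref,
                        theta_ref = c(phi = pi / 2, psi = 0)) {
  stopifnot(name %in% c("MSA", "MSR", "MEF", "MEE", "BA", "BR"),
            length(theta_ref) == 2, l_ref > 0)
  n_arms <- sum(c(r_shoulder, r_elbow) != 0)
  if (name %in% c("BA", "BR")) {
    if (n_arms != 2) stop("biarticular muscle must have two nonzero moment arms")
  } else if (n_arms != 1) {
    stop("monoarticular muscle must have exactly one nonzero moment arm")
  }
  structure(list(name = name, r_shoulder = r_shoulder, r_elbow = r_elbow,
                 l_ref = l_ref, theta_ref = unname(theta_ref)),
            class = "muscle_path")
}

#' Hill-type muscle-tendon unit parameters
#'
#' Parameters of the four-element formulation: a contractile element (CE) with
#' bell-shaped force-length and Hill hyperbola force-velocity characteristics
#' (van-Soest-style eccentric continuation), a parallel elastic element (PEE)
#' with power-law stiffness, a serial elastic element (SEE) with a nonlinear
#' toe region followed by a linear branch, and a serial damping element (SDE)
#' whose coefficient scales with force.  Activation dynamics follow a
#' first-order calcium-like model with length-dependent sensitivity.
#'
#' Default constants carry literature-scale magnitudes for a lumped human arm
#' muscle; they are a reconstruction, not measured values, and every one is
#' overridable (per-muscle) in the model configuration.
#'
#' @param F_max maximum isometric force (N)
#' @param l_CE_opt optimal CE length (m)
#' @param w force-length width (fraction of `l_CE_opt`)
#' @param nu_fl force-length exponent
#' @param a_rel,b_rel Hill constants (dimensionless; `b_rel` in optimal lengths
#'   per second)
#' @param S_ecc eccentric slope factor at zero velocity
#' @param F_ecc eccentric force asymptote (fraction of isometric force)
#' @param l_PEE_0 PEE slack length (fraction of `l_CE_opt`)
#' @param k_PEE PEE force at `l_CE = (1 + w) l_CE_opt` (fraction of `F_max`)
#' @param nu_PEE PEE exponent
#' @param l_SEE_0 SEE rest length (m)
#' @param dU_SEE_nll relative stretch at the end of the nonlinear toe region
#' @param dU_SEE_l relative stretch in the linear branch per `dF_SEE_0`
#' @param dF_SEE_0 force at the end of the toe region (N)
#' @param d_SDE maximum SDE coefficient (dimensionless factor)
#' @param R_SDE minimum SDE coefficient fraction at zero force
#' @param a_min minimum activity
#' @param m_act activation rate constant (1/s)
#' @param nu_act activation exponent
#' @param rho_c calcium-sensitivity scale
#' @param c_gamma length-dependence constant of the sensitivity
#' @return object of class `muscle_parameters`
#' @export
muscle_parameters <- function(F_max = 1000, l_CE_opt = 0.14, w = 0.45,
                              nu_fl = 2, a_rel = 0.2, b_rel = 2.0,
                              S_ecc = 2, F_ecc = 1.5,
                              l_PEE_0 = 0.95, k_PEE = 2, nu_PEE = 2.5,
                              l_SEE_0 = 0.17, dU_SEE_nll = 0.0425,
                              dU_SEE_l = 0.017, dF_SEE_0 = 0.4 * F_max,
                              d_SDE = 0.3, R_SDE = 0.01,
                              a_min = 0.005, m_act = 11.3, nu_act = 3,
                              rho_c = 6, c_gamma = 2.9) {
  p <- list(F_max = F_max, l_CE_opt = l_CE_opt, w = w, nu_fl = nu_fl,
            a_rel = a_rel, b_rel = b_rel, S_ecc = S_ecc, F_ecc = F_ecc,
            l_PEE_0 = l_PEE_0, k_PEE = k_PEE, nu_PEE = nu_PEE,
            l_SEE_0 = l_SEE_0, dU_SEE_nll = dU_SEE_nll, dU_SEE_l = dU_SEE_l,
            dF_SEE_0 = dF_SEE_0, d_SDE = d_SDE, R_SDE = R_SDE,
            a_min = a_min, m_act = m_act, nu_act = nu_act,
            rho_c = rho_c, c_gamma = c_gamma)
  stopifnot(F_max > 0, l_CE_opt > 0, w > 0, a_rel > 0, b_rel > 0,
            S_ecc > 0, F_ecc > 1, l_SEE_0 > 0, a_min > 0, a_min < 1,
            m_act > 0, nu_act >= 1, rho_c > 0, c_gamma > 1, R_SDE > 0)
  structure(p, class = "muscle_parameters")
}

#' Reaching task specification
#'
#' Point-to-manifold task: reach from a fixed start posture to a vertical bar
#' at horizontal distance `x_star`; the terminal height on the bar is free.
#'
#' @param x_star bar x-position (m)
#' @param duration_mode `"free"` (simulate until the fingertip comes to rest)
#'   or `"fixed"` (stop exactly at `T_fixed`, with a terminal-speed penalty in
#'   the total cost)
#' @param T_fixed movement duration in fixed mode (s)
#' @param v_stop equilibrium fingertip-speed threshold (m/s)
#' @param t_cap hard simulation cap in free mode (s)
#' @param theta0 start posture `c(phi, psi)` (rad)
#' @param endpoint_velocity_weight weight of the terminal-speed penalty
#'   (fixed mode only)
#' @param onset_factor the sub-threshold stop test only arms after the
#'   fingertip speed first exceeds `onset_factor * v_stop`
#' @return object of class `task_spec`
#' @export
task_spec <- function(x_star = 0.85 * 0.80, duration_mode = c("free", "fixed"),
                      T_fixed = 1.0, v_stop = 1e-4, t_cap = 5.0,
                      theta0 = c(phi = pi / 2, psi = 0),
                      endpoint_velocity_weight = 1.0, onset_factor = 10) {
  duration_mode <- match.arg(duration_mode)
  stopifnot(x_star > 0, v_stop > 0, t_cap > T_fixed, T_fixed > 0,
            length(theta0) == 2, endpoint_velocity_weight >= 0)
  structure(list(x_star = x_star, duration_mode = duration_mode,
                 T_fixed = T_fixed, v_stop = v_stop, t_cap = t_cap,
                 theta0 = unname(theta0),
                 endpoint_velocity_weight = endpoint_velocity_weight,
                 onset_factor = onset_factor),
            class = "task_spec")
}

# flatten muscle parameters + path into the row layout the C++ side expects
musc_row <- function(p, path) {
  c(p$F_max, p$l_CE_opt, p$w, p$nu_fl, p$a_rel, p$b_rel, p$S_ecc, p$F_ecc,
    p$l_PEE_0, p$k_PEE, p$nu_PEE, p$l_SEE_0, p$dU_SEE_nll, p$dU_SEE_l,
    p$dF_SEE_0, p$d_SDE, p$R_SDE, p$a_min, p$m_act, p$nu_act, p$rho_c,
    p$c_gamma, path$r_shoulder, path$r_elbow, path$l_ref,
    path$theta_ref[1], path$theta_ref[2])
}

musc_matrix <- function(model) {
  if (length(model$muscles) == 0) {
    return(matrix(numeric(0), nrow = 0, ncol = 27))
  }
  t(vapply(model$muscles, function(m) musc_row(m$params, m$path),
           numeric(27)))
}

arm_vector <- function(model) {
  a <- model$arm
  lim <- model$limits
  c(a$l1, a$l2, a$m1, a$m2, a$c1, a$c2, a$I1, a$I2, a$g,
    lim$phi[1], lim$phi[2], lim$psi[1], lim$psi[2], lim$k, lim$w)
}

#' Assemble an arm model
#'
#' Bundles segment parameters, muscles (parameters + routing), task and
#' integrator settings into one model object.  Soft exponential joint-limit
#' torques engage near the configured bounds; excursions beyond the bounds are
#' flagged on the trajectory, not raised as errors.
#'
#' @param arm [arm_parameters()]
#' @param muscles list of `list(params = muscle_parameters(), path =
#'   muscle_path())` entries
#' @param task [task_spec()]
#' @param limits list with `phi`, `psi` (length-2 bounds, rad), `k` (torque
#'   scale, N m) and `w` (width, rad) of the soft joint limits
#' @param integrator list with `rtol`, `atol`, `dt_out` (s) and `chunk` (s)
#' @return object of class `arm_model`
#' @export
arm_model <- function(arm = arm_parameters(), muscles = list(),
                      task = task_spec(x_star = 0.85 * (arm$l1 + arm$l2)),
                      limits = list(phi = c(-0.3, 3.0), psi = c(-1.5, 3.0),
                                    k = 5, w = 0.05),
                      integrator = list(rtol = 1e-8, atol = 1e-10,
                                        dt_out = 1e-3, chunk = 0.5)) {
  m <- list(arm = arm, muscles = muscles, task = task, limits = limits,
            integrator = integrator, cache = new.env(parent = emptyenv()))
  structure(m, class = "arm_model")
}
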