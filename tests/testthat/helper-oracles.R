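# Independent R-side re-derivations of the muscle element curves, used as
# brute-force oracles against the closed-form compiled implementation.

oracle_curves <- function(p) {
  lopt <- p$l_CE_opt
  f_isom <- function(lce) exp(-(abs(lce / lopt - 1) / p$w)^p$nu_fl)
  Kp <- p$k_PEE * p$F_max / (lopt * (p$w + 1 - p$l_PEE_0))^p$nu_PEE
  f_pee <- function(lce) {
    L0 <- p$l_PEE_0 * lopt
    ifelse(lce > L0, Kp * (lce - L0)^p$nu_PEE, 0)
  }
  nu_see <- p$dU_SEE_nll / p$dU_SEE_l
  lnll <- (1 + p$dU_SEE_nll) * p$l_SEE_0
  Knl <- p$dF_SEE_0 / (p$dU_SEE_nll * p$l_SEE_0)^nu_see
  Kl <- p$dF_SEE_0 / (p$dU_SEE_l * p$l_SEE_0)
  f_see <- function(lsee) {
    ifelse(lsee <= p$l_SEE_0, 0,
           ifelse(lsee < lnll, Knl * (lsee - p$l_SEE_0)^nu_see,
                  p$dF_SEE_0 + Kl * (lsee - lnll)))
  }
  list(f_isom = f_isom, f_pee = f_pee, f_see = f_see)
}

# force-balance residual CE + PEE - SEE - SDE at CE velocity v (zero-clamped
# CE force), independent of the compiled quadratic solution
oracle_balance <- function(v, lce, lmtu, vmtu, a, p) {
  cur <- oracle_curves(p)
  Fi <- a * cur$f_isom(lce)
  Fpee <- cur$f_pee(lce)
  Fsee <- cur$f_see(lmtu - lce)
  b <- p$b_rel * p$l_CE_opt
  A <- p$a_rel
  if (v <= 0) {
    bb <- b; AA <- A
  } else {
    AA <- -p$F_ecc * Fi
    bb <- b * Fi * (1 - p$F_ecc) / (p$S_ecc * (Fi + A))
  }
  C0 <- (Fi + AA) * bb
  Fce <- max(p$F_max * (C0 / (bb - v) - AA), 0)
  Dmax <- p$d_SDE * p$F_max * p$a_rel / (p$l_CE_opt * p$b_rel)
  D <- Dmax * ((1 - p$R_SDE) * (Fce + Fpee) / p$F_max + p$R_SDE)
  Fce + Fpee - Fsee - D * (vmtu - v)
}

oracle_contraction_rate <- function(lce, lmtu, vmtu, a, p) {
  uniroot(oracle_balance, c(-5, 5), lce = lce, lmtu = lmtu, vmtu = vmtu,
          a = a, p = p, tol = 1e-13, extendInt = "upX")$root
}

# dense direct implementation of the GP posterior equations
oracle_gp <- function(U, y, u_star, alpha, gamma, eps2) {
  k <- function(a, b) alpha * exp(-gamma * sum((a - b)^2))
  n <- nrow(U)
  K <- outer(seq_len(n), seq_len(n),
             Vectorize(function(i, j) k(U[i, ], U[j, ])))
  kk <- vapply(seq_len(n), function(i) k(U[i, ], u_star), numeric(1))
  Ki <- solve(K + diag(eps2, n))
  list(mu = drop(kk %*% Ki %*% y),
       var = k(u_star, u_star) - drop(kk %*% Ki %*% kk))
}

# minimum-jerk quintic joint path over [0, T]
quintic_path <- function(theta0, dtheta, Tdur, dt = 1e-3) {
  t <- seq(0, Tdur, by = dt)
  s <- t / Tdur
  theta0 + dtheta * (10 * s^3 - 15 * s^4 + 6 * s^5)
}

quintic_vel <- function(dtheta, Tdur, dt = 1e-3) {
  t <- seq(0, Tdur, by = dt)
  s <- t / Tdur
  dtheta * (30 * s^2 - 60 * s^3 + 30 * s^4) / Tdur
}

# build a synthetic trajectory object from joint paths (for cost tests);
# velocities default to finite differences but can be given in closed form,
# matching the package's own data flow where velocities are solver-exact
traj_from_joint_paths <- function(phi, psi, dt, arm = arm_parameters(),
                                  tau1 = NULL, tau2 = NULL,
                                  u = rep(0, 6),
                                  phi_dot = NULL, psi_dot = NULL) {
  n <- length(phi)
  theta <- cbind(phi, psi)
  fd <- function(x) reachopt:::fd_derivative(x, dt)
  fd2 <- function(x) reachopt:::fd_second_derivative(x, dt)
  if (is.null(phi_dot)) phi_dot <- fd(phi)
  if (is.null(psi_dot)) psi_dot <- fd(psi)
  theta_dot <- cbind(phi_dot, psi_dot)
  theta_ddot <- cbind(fd(theta_dot[, 1]), fd(theta_dot[, 2]))
  theta_dddot <- cbind(fd2(theta_dot[, 1]), fd2(theta_dot[, 2]))
  xz <- reachopt:::fk_vec(theta, arm)
  vxz <- reachopt:::ftvel_vec(theta, theta_dot, arm)
  if (is.null(tau1)) tau1 <- rep(0, n)
  if (is.null(tau2)) tau2 <- rep(0, n)
  tau <- cbind(tau1, tau2)
  structure(list(t = seq(0, by = dt, length.out = n), dt = dt,
                 theta = theta, theta_dot = theta_dot,
                 theta_ddot = theta_ddot, theta_dddot = theta_dddot,
                 x = xz[, 1], z = xz[, 2],
                 x_dot = vxz[, 1], z_dot = vxz[, 2],
                 tau = tau, tau_dot = cbind(fd(tau1), fd(tau2)),
                 u = u, T = (n - 1) * dt, terminated_by = "time_limit",
                 flagged = FALSE),
            class = "arm_trajectory")
}
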