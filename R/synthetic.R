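#' Default reconstructed arm model
#'
#' A fully consistent six-muscle fixture: two monoarticular shoulder muscles
#' (MSA anteversion, MSR retroversion), two monoarticular elbow muscles (MEF
#' flexor, MEE extensor) and two biarticular muscles (BA anteflexor, BR
#' retroextensor), on a 0.80 m arm with the bar at 85% of arm length and the
#' start posture phi = 90 deg, psi = 0 deg.  Magnitudes are literature-scale
#' reconstructions (maximum isometric forces 600-1000 N, optimal fiber
#' lengths 0.12-0.15 m, constant moment arms 2.5-5 cm); every value can be
#' overridden through the YAML configuration.
#'
#' @param duration_mode task duration mode, `"free"` or `"fixed"`
#' @param ... overrides forwarded to [task_spec()]
#' @return [arm_model()] object
#' @export
default_model <- function(duration_mode = "free", ...) {
  arm <- arm_parameters()
  theta_ref <- c(phi = pi / 2, psi = 0)
  spec <- list(
    MSA = list(F_max = 1000, l_opt = 0.14, r_sh = +0.05, r_el = 0),
    MSR = list(F_max = 1000, l_opt = 0.14, r_sh = -0.05, r_el = 0),
    MEF = list(F_max = 800,  l_opt = 0.12, r_sh = 0,     r_el = +0.03),
    MEE = list(F_max = 800,  l_opt = 0.12, r_sh = 0,     r_el = -0.03),
    BA  = list(F_max = 600,  l_opt = 0.15, r_sh = +0.04, r_el = +0.03),
    BR  = list(F_max = 600,  l_opt = 0.15, r_sh = -0.04, r_el = -0.03))
  muscles <- lapply(names(spec), function(nm) {
    s <- spec[[nm]]
    p <- muscle_parameters(F_max = s$F_max, l_CE_opt = s$l_opt)
    list(params = p,
         path = muscle_path(nm, s$r_sh, s$r_el,
                            l_ref = p$l_SEE_0 + p$l_CE_opt,
                            theta_ref = theta_ref))
  })
  names(muscles) <- names(spec)
  task <- task_spec(x_star = 0.85 * (arm$l1 + arm$l2),
                    duration_mode = duration_mode, theta0 = theta_ref, ...)
  arm_model(arm = arm, muscles = muscles, task = task)
}

#' Synthetic reference reaching data
#'
#' Generates per-subject fingertip paths and tangential velocity profiles
#' emulating the headline features of experimental point-to-manifold reaches:
#' every path starts at the model start point and ends on the bar
#' `x = x_star` with a normally distributed endpoint height, paths are warped
#' by a concave curvature bulge, and speed profiles are bell-shaped
#' (minimum-jerk time course) with peak speed around 0.85 m/s and duration
#' around 1 s.  This is a synthetic surrogate, not recorded human data.
#'
#' @param n_subjects number of synthetic subjects
#' @param seed RNG seed (the set is deterministic per seed)
#' @param model [arm_model()] providing the start point and bar position
#' @param cfg generator configuration: `endpoint_z_mean`, `endpoint_z_sd` (m),
#'   `bulge` concave-warp amplitude (m), `bulge_sd`, `v_peak_mean`,
#'   `v_peak_sd` (m/s), `duration_range` admissible durations (s), `skew`
#'   peak-time warp (0 = symmetric), `dt` sample interval (s)
#' @return object of class `reference_set`: list `trajectories` of subject
#'   records (`t`, `x`, `z`, `v`), plus `n_subjects`, `seed` and `cfg`
#' @export
generate_reference_set <- function(n_subjects = 17, seed = 1,
                                   model = default_model(),
                                   cfg = list()) {
  defaults <- list(endpoint_z_mean = -0.05, endpoint_z_sd = 0.05,
                   bulge = 0.08, bulge_sd = 0.015,
                   v_peak_mean = 0.85, v_peak_sd = 0.08,
                   duration_range = c(0.6, 1.6), skew = 0, dt = 1e-3)
  unknown <- setdiff(names(cfg), names(defaults))
  if (length(unknown) > 0)
    stop("unknown reference-generator keys: ", paste(unknown, collapse = ", "))
  cfg <- modifyList(defaults, cfg)
  stopifnot(cfg$dt > 0, cfg$v_peak_mean > 0, cfg$bulge >= 0)
  p0 <- forward_kinematics(model$task$theta0, model$arm)
  x_star <- model$task$x_star
  reach <- model$arm$l1 + model$arm$l2
  set.seed(seed)
  trajectories <- lapply(seq_len(n_subjects), function(i) {
    z_end <- rnorm(1, cfg$endpoint_z_mean, cfg$endpoint_z_sd)
    if (sqrt(x_star^2 + z_end^2) >= reach)
      stop("sampled endpoint beyond arm reach; tighten endpoint config")
    b <- max(rnorm(1, cfg$bulge, cfg$bulge_sd), 0)
    v_pk <- max(rnorm(1, cfg$v_peak_mean, cfg$v_peak_sd), 0.2)
    # geometric path: straight chord plus a perpendicular concave bulge
    ns <- 2001
    s <- seq(0, 1, length.out = ns)
    chord <- c(x_star - p0[["x"]], z_end - p0[["z"]])
    L_chord <- sqrt(sum(chord^2))
    nrm <- c(chord[2], -chord[1]) / L_chord  # points downward-forward: concave
    px <- p0[["x"]] + s * chord[1] + b * sin(pi * s) * nrm[1]
    pz <- p0[["z"]] + s * chord[2] + b * sin(pi * s) * nrm[2]
    seg <- sqrt(diff(px)^2 + diff(pz)^2)
    arc <- c(0, cumsum(seg))
    L <- arc[ns]
    # minimum-jerk time course along the arc, duration set by the sampled peak
    Tdur <- min(max(1.875 * L / v_pk, cfg$duration_range[1]),
                cfg$duration_range[2])
    t <- seq(0, Tdur, by = cfg$dt)
    tau <- t / Tdur
    warp <- if (cfg$skew != 0) tau^(1 + cfg$skew) else tau
    sigma <- 10 * warp^3 - 15 * warp^4 + 6 * warp^5
    xs <- approx(arc / L, px, xout = sigma, rule = 2)$y
    zs <- approx(arc / L, pz, xout = sigma, rule = 2)$y
    v <- sqrt(fd_derivative(xs, cfg$dt)^2 + fd_derivative(zs, cfg$dt)^2)
    list(t = t, x = xs, z = zs, v = v, T = Tdur, z_end = z_end)
  })
  structure(list(trajectories = trajectories, n_subjects = n_subjects,
                 seed = seed, cfg = cfg),
            class = "reference_set")
}

#' Analytic toy cost functions on the stimulation box
#'
#' Smooth 6-D test functions with known minima for validating the optimizer:
#' an isotropic sphere, an anisotropic quadratic and a three-mode Gaussian
#' mixture valley whose global minimum is strictly below both local minima.
#' Each entry carries its true `minimizer` and `minimum`.
#'
#' @return named list of entries `list(f, minimizer, minimum)`
#' @export
toy_costs <- function() {
  sphere_min <- rep(0.3, 6)
  aniso_scale <- c(1, 2, 4, 8, 16, 32)
  aniso_min <- rep(0.7, 6)
  centers <- rbind(rep(0.2, 6), rep(0.8, 6), c(0.5, 0.2, 0.8, 0.5, 0.2, 0.8))
  depths <- c(1.0, 0.6, 0.4)
  width2 <- 0.05
  mixture <- function(u) {
    1 - sum(depths * exp(-colSums((t(centers) - u)^2) / width2))
  }
  list(
    sphere = list(f = function(u) sum((u - sphere_min)^2),
                  minimizer = sphere_min, minimum = 0),
    aniso = list(f = function(u) sum(aniso_scale * (u - aniso_min)^2),
                 minimizer = aniso_min, minimum = 0),
    mixture = list(f = mixture, minimizer = rep(0.2, 6),
                   minimum = mixture(rep(0.2, 6))))
}
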