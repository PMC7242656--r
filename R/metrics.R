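#' Zero-phase Butterworth low-pass filter
#'
#' Forward-backward application of a digital fifth-order Butterworth filter
#' (default cutoff 10 Hz), the post-processing applied to kinematic signals
#' before metric computation.  DC gain is 1.
#'
#' @param x signal (uniformly sampled)
#' @param fs sampling frequency (Hz), must exceed `2 * fc`
#' @param order filter order
#' @param fc cutoff frequency (Hz)
#' @return filtered signal, same length
#' @export
lowpass_filter <- function(x, fs, order = 5, fc = 10) {
  if (fs <= 2 * fc) stop("sampling frequency must exceed twice the cutoff")
  n <- length(x)
  if (n < 3 * (order + 1))
    stop("signal too short for stable zero-phase filtering")
  bf <- signal::butter(order, fc / (fs / 2), type = "low")
  # odd-reflection padding long enough for the slowest pole to decay; the
  # forward-backward pass otherwise starts from zero state and leaves large
  # edge transients
  L <- min(n - 1, ceiling(30 * fs / fc))
  xp <- c(2 * x[1] - x[(L + 1):2], x, 2 * x[n] - x[(n - 1):(n - L)])
  y <- as.numeric(signal::filtfilt(bf, xp))
  y[(L + 1):(L + n)]
}

# linear-interpolated crossing time of a threshold between samples i and i+1
cross_time <- function(t, v, i, thr, up = TRUE) {
  if (i < 1) return(t[1])
  dv <- v[i + 1] - v[i]
  if (dv == 0) return(t[i])
  t[i] + (thr - v[i]) / dv * (t[i + 1] - t[i])
}

#' Movement on/offset from the tangential velocity profile
#'
#' Onset is the first up-crossing of 5% of the peak velocity, offset the last
#' down-crossing after the peak (linearly interpolated between samples).
#'
#' @param t time vector (s)
#' @param v tangential speed (m/s), non-negative with a strict positive peak
#' @param threshold relative threshold (fraction of the peak)
#' @return named numeric `c(t_on, t_off)`
#' @export
movement_window <- function(t, v, threshold = 0.05) {
  if (max(v) <= 0) stop("velocity profile has no positive peak: window undefined")
  ipk <- which.max(v)
  thr <- threshold * v[ipk]
  above <- v >= thr
  if (all(above)) return(c(t_on = t[1], t_off = t[length(t)]))
  first_above <- which(above)[1]
  t_on <- if (first_above == 1) t[1]
    else cross_time(t, v, first_above - 1, thr)
  after <- which(!above & seq_along(v) > ipk)
  t_off <- if (length(after) == 0) t[length(t)]
    else cross_time(t, v, after[1] - 1, thr)
  c(t_on = t_on, t_off = t_off)
}

#' Signed curvature of a planar path
#'
#' `kappa = (x' z'' - z' x'') / (x'^2 + z'^2)^(3/2)` with derivatives from
#' centered finite differences; samples where the speed falls below a
#' numerical floor are masked with `NA`.
#'
#' @param x,z path coordinates on a uniform time grid (m)
#' @param dt sample interval (s)
#' @param v_floor speed floor below which curvature is masked (m/s)
#' @return curvature series (1/m)
#' @export
signed_curvature <- function(x, z, dt, v_floor = 1e-6) {
  xd <- fd_derivative(x, dt); zd <- fd_derivative(z, dt)
  xdd <- fd_derivative(xd, dt); zdd <- fd_derivative(zd, dt)
  sp2 <- xd^2 + zd^2
  k <- (xd * zdd - zd * xdd) / sp2^1.5
  k[sqrt(sp2) < v_floor] <- NA_real_
  k
}

#' Relative-peak-time skewness of a velocity profile
#'
#' `(t_peak - t_on) / (t_off - t_on) - 0.5`: zero for time-symmetric
#' (bell-shaped) profiles, positive when the peak comes late (right-skew).
#'
#' @param t time vector (s)
#' @param v tangential speed (m/s)
#' @param window optional precomputed `c(t_on, t_off)`
#' @return scalar skewness
#' @export
velocity_skewness <- function(t, v, window = movement_window(t, v)) {
  span <- window[2] - window[1]
  if (!is.finite(span) || span <= 0) stop("degenerate movement window")
  t_peak <- t[which.max(v)]
  unname((t_peak - window[1]) / span - 0.5)
}

#' Post-processed velocity profile of a trajectory
#'
#' Tangential fingertip speed, low-pass filtered (zero-phase 5th-order
#' Butterworth at 10 Hz), with the movement window and peak annotated.
#'
#' @param traj [simulate_reach()] trajectory (or any list with `t`, `x_dot`,
#'   `z_dot`)
#' @param filter apply the Butterworth filter
#' @param fc cutoff frequency (Hz)
#' @return list with `t`, `v`, `t_on`, `t_off`, `v_peak`, `t_peak`, `skewness`
#' @export
velocity_profile <- function(traj, filter = TRUE, fc = 10) {
  v <- sqrt(traj$x_dot^2 + traj$z_dot^2)
  if (filter) {
    fs <- 1 / traj$dt
    v <- pmax(lowpass_filter(v, fs, fc = fc), 0)
  }
  win <- movement_window(traj$t, v)
  ipk <- which.max(v)
  list(t = traj$t, v = v, t_on = unname(win[1]), t_off = unname(win[2]),
       v_peak = v[ipk], t_peak = traj$t[ipk],
       skewness = velocity_skewness(traj$t, v, win))
}

# single-trajectory summary used for metric comparison
trajectory_features <- function(traj, filter = TRUE) {
  prof <- velocity_profile(traj, filter = filter)
  n <- length(traj$x)
  dt <- traj$dt
  xf <- if (filter) lowpass_filter(traj$x, 1 / dt) else traj$x
  zf <- if (filter) lowpass_filter(traj$z, 1 / dt) else traj$z
  inwin <- traj$t >= prof$t_on & traj$t <= prof$t_off
  k <- signed_curvature(xf, zf, dt)[inwin]
  k <- k[is.finite(k)]
  kmax <- if (length(k) > 0) k[which.max(abs(k))] else 0
  list(endpoint_z = zf[n], max_signed_curvature = kmax,
       v_peak = prof$v_peak, skewness = prof$skewness)
}

#' Trajectory metrics against a reference set
#'
#' Absolute errors of the simulated endpoint height on the bar, the maximum
#' signed curvature (concavity/convexity), the peak tangential velocity and
#' the velocity skewness, each against the aggregate (mean by default, median
#' optional) over the reference subjects.
#'
#' @param traj [simulate_reach()] trajectory
#' @param reference [generate_reference_set()] (or a compatible list of
#'   subject records)
#' @param aggregate `"mean"` or `"median"` over subjects
#' @param filter low-pass filter the simulated signals first
#' @return object of class `trajectory_metrics` with the four errors and the
#'   simulated/reference feature values
#' @export
trajectory_metrics <- function(traj, reference, aggregate = c("mean", "median"),
                               filter = TRUE) {
  aggregate <- match.arg(aggregate)
  subjects <- if (inherits(reference, "reference_set"))
    reference$trajectories else reference
  if (length(subjects) == 0) stop("reference set is empty")
  agg <- if (aggregate == "mean") mean else stats::median
  feats <- trajectory_features(traj, filter = filter)
  ref_feats <- lapply(subjects, function(s) {
    dt <- s$t[2] - s$t[1]
    win <- movement_window(s$t, s$v)
    inwin <- s$t >= win[1] & s$t <= win[2]
    k <- signed_curvature(s$x, s$z, dt)[inwin]
    k <- k[is.finite(k)]
    list(endpoint_z = s$z[length(s$z)],
         max_signed_curvature = if (length(k)) k[which.max(abs(k))] else 0,
         v_peak = max(s$v), skewness = velocity_skewness(s$t, s$v, win))
  })
  ref <- lapply(c("endpoint_z", "max_signed_curvature", "v_peak", "skewness"),
                function(f) agg(vapply(ref_feats, `[[`, numeric(1), f)))
  names(ref) <- c("endpoint_z", "max_signed_curvature", "v_peak", "skewness")
  structure(list(
    endpoint_error = abs(feats$endpoint_z - ref$endpoint_z),
    curvature_error = abs(feats$max_signed_curvature - ref$max_signed_curvature),
    peak_velocity_error = abs(feats$v_peak - ref$v_peak),
    skewness_error = abs(feats$skewness - ref$skewness),
    simulated = feats, reference = ref),
    class = "trajectory_metrics")
}

#' Best-k records of an evaluation dataset
#'
#' The k records with smallest cost, ties broken by iteration order, returned
#' in ascending cost.
#'
#' @param D [eval_dataset()]
#' @param k number of records
#' @return list with `U` (k rows), `y`, and the original `indices`
#' @export
best_k <- function(D, k = 5) {
  n <- length(D$y)
  if (k > n) stop("k exceeds the number of records")
  ord <- order(D$y, seq_len(n))[seq_len(k)]
  list(U = D$U[ord, , drop = FALSE], y = D$y[ord], indices = ord)
}

#' Two-sample t-test between run cost observations
#'
#' Welch (unequal-variance) two-sample t-test by default, with a pooled
#' (classic Student) toggle; two-sided p-value.  Degenerate zero-variance
#' samples with equal means return `t = 0, p = 1`.
#'
#' @param costs_a,costs_b numeric samples (>= 2 values each)
#' @param var_equal use the pooled-variance test
#' @return list with `t`, `p`, `df`, and per-sample means
#' @export
compare_runs <- function(costs_a, costs_b, var_equal = FALSE) {
  stopifnot(length(costs_a) >= 2, length(costs_b) >= 2)
  if (stats::var(costs_a) == 0 && stats::var(costs_b) == 0) {
    if (mean(costs_a) == mean(costs_b))
      return(list(t = 0, p = 1, df = NA_real_,
                  mean_a = mean(costs_a), mean_b = mean(costs_b)))
    return(list(t = sign(mean(costs_a) - mean(costs_b)) * Inf, p = 0,
                df = NA_real_, mean_a = mean(costs_a), mean_b = mean(costs_b)))
  }
  tt <- stats::t.test(costs_a, costs_b, var.equal = var_equal)
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter), mean_a = mean(costs_a),
       mean_b = mean(costs_b))
}

#' Mean and standard deviation of convergence curves
#'
#' Per-iteration mean and standard deviation of the running-minimum curves of
#' repeated optimization runs.
#'
#' @param runs list of `bo_result` objects with equal-length `best_so_far`
#' @return list with `iteration`, `mean`, `sd`
#' @export
convergence_stats <- function(runs) {
  curves <- lapply(runs, `[[`, "best_so_far")
  lens <- vapply(curves, length, integer(1))
  if (length(unique(lens)) != 1) stop("best_so_far curves have ragged lengths")
  M <- do.call(rbind, curves)
  list(iteration = seq_len(ncol(M)), mean = colMeans(M),
       sd = apply(M, 2, function(col) if (nrow(M) > 1) stats::sd(col) else 0))
}

# boxplot summary with the 1.5 IQR whisker/outlier rule
boxplot_summary <- function(x) {
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  iqr <- q[3] - q[1]
  lo <- q[1] - 1.5 * iqr
  hi <- q[3] + 1.5 * iqr
  list(median = q[2], q1 = q[1], q3 = q[3], iqr = iqr,
       whisker_low = lo, whisker_high = hi,
       outliers = x[x < lo | x > hi])
}
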